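#' Construct an annotation set
#'
#' An annotation set maps function-label identifiers (for instance GO term
#' accessions) to the sets of genes they annotate, optionally carrying a
#' branch tag (`bp`, `cc`, `mf`) per term.
#'
#' @param terms Named list; each element a character vector of gene
#'   identifiers. Gene sets are canonicalized and deduplicated.
#' @param branch Optional named character vector mapping term id to one of
#'   `bp`, `cc`, `mf`.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(terms, branch = NULL) {
  if (is.null(names(terms)) || anyDuplicated(names(terms))) {
    stop("terms must be uniquely named by term id", call. = FALSE)
  }
  terms <- lapply(terms, function(g) unique(canonical_id(g)))
  if (!is.null(branch)) {
    bad <- setdiff(unique(branch), c("bp", "cc", "mf"))
    if (length(bad)) {
      stop("unknown branch tag(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(terms = terms, branch = branch), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms, sizes %s\n", length(x$terms),
              paste(range(term_sizes(x)), collapse = "-")))
  invisible(x)
}

#' @export
length.annotation_set <- function(x) length(x$terms)

#' Term sizes of an annotation set
#'
#' @param annotations An `annotation_set`.
#' @return Named integer vector of gene counts per term.
#' @export
term_sizes <- function(annotations) {
  vapply(annotations$terms, length, integer(1))
}
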