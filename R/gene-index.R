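#' Canonicalize gene identifiers
#'
#' Identifiers are trimmed of surrounding whitespace and case-folded to upper
#' case so that `BRCA1`, `brca1 ` and `Brca1` resolve to the same gene. The
#' transformation is idempotent.
#'
#' @param x Character vector of raw identifiers.
#' @return Character vector of canonical identifiers.
#' @export
canonical_id <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a gene index
#'
#' A `gene_index` is a bidirectional mapping between canonical gene
#' identifiers and dense integer indices `1..n` over the gene universe of a
#' run. All networks and annotation sets in an assessment are aligned to one
#' shared index.
#'
#' @param symbols Character vector of identifiers; canonicalized and
#'   deduplicated preserving first occurrence.
#' @return An object of class `gene_index`.
#' @export
gene_index <- function(symbols) {
  syms <- unique(canonical_id(symbols))
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0L) {
    stop("gene universe is empty", call. = FALSE)
  }
  structure(
    list(symbols = syms,
         lookup = stats::setNames(seq_along(syms), syms)),
    class = "gene_index"
  )
}

#' @export
length.gene_index <- function(x) length(x$symbols)

#' @export
print.gene_index <- function(x, ...) {
  cat("<gene_index> ", length(x$symbols), " genes\n", sep = "")
  invisible(x)
}

#' Look up gene positions in an index
#'
#' @param index A `gene_index`.
#' @param ids Character vector of identifiers (canonicalized internally).
#' @return Integer vector of positions; `NA` for unknown identifiers.
#' @export
gene_position <- function(index, ids) {
  stopifnot(inherits(index, "gene_index"))
  unname(index$lookup[canonical_id(ids)])
}
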