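#' Read an association network file
#'
#' Parses a tab-delimited network file with two or three columns. The first
#' two columns are the identifiers of the interactors; an optional third
#' column carries the interaction weight (rows without it get weight 1.0).
#' Tabs must not be surrounded by spaces; surrounding whitespace inside a
#' field is removed by identifier canonicalization. Duplicate undirected
#' edges (in either orientation) are collapsed to the maximum weight, and
#' self-loops are dropped with a warning.
#'
#' @param path Path to the network file.
#' @param index Optional `gene_index` fixing the gene universe. When given,
#'   rows mentioning an unknown identifier are skipped and counted in the
#'   `skipped_rows` attribute of the result; when `NULL`, the universe is
#'   taken from the file itself.
#' @param name,group Network name and group; default to the file stem and
#'   `"user"`.
#' @return A [gba_network()]. Attribute `skipped_rows` holds the number of
#'   rows dropped because of unknown identifiers.
#' @export
read_network_file <- function(path, index = NULL, name = NULL,
                              group = "user") {
  if (is.null(name)) {
    name <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("network file '", path, "' is empty", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 2L | nf > 3L
  if (any(bad)) {
    stop("network file '", path, "': expected 2 or 3 tab-separated fields ",
         "at line(s) ", paste(lineno[bad], collapse = ", "), call. = FALSE)
  }
  a <- canonical_id(vapply(fields, `[[`, character(1), 1L))
  b <- canonical_id(vapply(fields, `[[`, character(1), 2L))
  w <- rep(1.0, length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    wtxt <- vapply(fields[has_w], `[[`, character(1), 3L)
    wnum <- suppressWarnings(as.numeric(wtxt))
    bad <- is.na(wnum) | wnum <= 0
    if (any(bad)) {
      stop("network file '", path, "': non-numeric or non-positive weight ",
           "at line(s) ", paste(lineno[has_w][bad], collapse = ", "),
           call. = FALSE)
    }
    w[has_w] <- wnum
  }
  loops <- a == b
  if (any(loops)) {
    warning("network file '", path, "': dropped ", sum(loops),
            " self-loop(s)", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; w <- w[!loops]
  }
  skipped <- 0L
  if (is.null(index)) {
    if (length(a) == 0L) {
      stop("network file '", path, "' has no usable edges", call. = FALSE)
    }
    index <- gene_index(c(rbind(a, b)))
  } else {
    ia <- gene_position(index, a)
    ib <- gene_position(index, b)
    known <- !is.na(ia) & !is.na(ib)
    skipped <- sum(!known)
    a <- a[known]; b <- b[known]; w <- w[known]
  }
  adj <- edges_to_adjacency(gene_position(index, a), gene_position(index, b),
                            w, length(index))
  net <- gba_network(name, group, adj, index)
  attr(net, "skipped_rows") <- skipped
  net
}

#' Write a network to a tab-delimited file
#'
#' Inverse of [read_network_file()]: each undirected edge is written once as
#' `from TAB to TAB weight` with full double precision, so that reading the
#' file back reproduces the adjacency matrix exactly.
#'
#' @param net A `gba_network`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_network_file <- function(net, path) {
  e <- network_edges(net)
  writeLines(sprintf("%s\t%s\t%.17g", e$from, e$to, e$weight), path)
  invisible(path)
}

#' Read a gold-standard annotation file
#'
#' Each line is a term: the term identifier followed by one gene identifier
#' per tab-separated field. Lines repeating a term id are merged by union.
#' Blank lines are skipped; a line with no genes yields a term with an empty
#' gene set and a warning.
#'
#' @param path Path to the annotation file.
#' @param branch_path Optional path to a 2-column `term TAB branch` side
#'   file tagging terms with `bp`/`cc`/`mf`.
#' @return An [annotation_set()].
#' @export
read_annotation_file <- function(path, branch_path = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("annotation file '", path, "' is empty", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  genes <- lapply(fields, function(f) canonical_id(f[-1][nzchar(trimws(f[-1]))]))
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    warning("annotation file '", path, "': ", sum(empty),
            " term line(s) list no genes", call. = FALSE)
  }
  terms <- lapply(split(genes, ids), function(gs) unique(unlist(gs)))
  terms <- lapply(terms, function(g) if (is.null(g)) character() else g)
  terms <- terms[unique(ids)]  # preserve first-occurrence order
  branch <- NULL
  if (!is.null(branch_path)) {
    bl <- utils::read.delim(branch_path, header = FALSE,
                            col.names = c("term", "branch"),
                            stringsAsFactors = FALSE)
    branch <- stats::setNames(tolower(trimws(bl$branch)), bl$term)
  }
  annotation_set(terms, branch = branch)
}

#' Read a synonym table
#'
#' A 2-column tab-delimited file mapping alternate identifiers to canonical
#' ones. Any alternate that maps to more than one distinct canonical
#' identifier is ambiguous and is discarded entirely: edges and annotations
#' mentioning it are dropped during [resolve_inputs()].
#'
#' @param path Path to the synonym file.
#' @return A list with `map` (named character vector alternate -> canonical)
#'   and `ambiguous` (character vector of discarded alternates).
#' @export
read_synonym_file <- function(path) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("alternate", "canonical"),
                           stringsAsFactors = FALSE)
  alt <- canonical_id(tab$alternate)
  can <- canonical_id(tab$canonical)
  n_targets <- vapply(split(can, alt), function(x) length(unique(x)),
                      integer(1))
  ambiguous <- names(n_targets)[n_targets > 1L]
  keep <- !(alt %in% ambiguous) & !duplicated(alt)
  list(map = stats::setNames(can[keep], alt[keep]), ambiguous = ambiguous)
}

# Report column order; the first four names follow the assessment tool's
# printed output, the remaining six extend the same pattern to AUPR and
# precision-at-10%-recall.
report_columns <- c(
  "QUERY",
  "BASELINE-AUC-ROC", "SUBJECT-AUC-ROC", "%ERR-AUC-ROC",
  "BASELINE-AUC-PR", "SUBJECT-AUC-PR", "%ERR-AUC-PR",
  "BASELINE-PREC-AT-10-RECALL", "SUBJECT-PREC-AT-10-RECALL",
  "%ERR-PREC-AT-10-RECALL"
)

internal_report_columns <- c(
  "term_id",
  "baseline_auroc", "subject_auroc", "err_auroc",
  "baseline_aupr", "subject_aupr", "err_aupr",
  "baseline_p10r", "subject_p10r", "err_p10r"
)

#' Write an assessment report
#'
#' Writes the per-term assessment table produced by [assess()] as
#' tab-delimited text with a fixed header. Floating values are printed with
#' nine significant digits; undefined values print as `NA`.
#'
#' @param records Data frame of term assessments (rows already sorted).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(records, path) {
  fmt <- function(x) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- "NA"
    out
  }
  body <- cbind(records$term_id,
                do.call(cbind, lapply(internal_report_columns[-1],
                                      function(cl) fmt(records[[cl]]))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(report_columns, collapse = "\t"), con)
  if (nrow(records) > 0L) {
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an assessment report
#'
#' Parses a file written by [write_report()] back into the internal
#' data-frame representation.
#'
#' @param path Path to a report file.
#' @return Data frame with the columns of [assess()] output.
#' @export
read_report <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c("character", rep("numeric", 9L)))
  if (!identical(names(tab), report_columns)) {
    stop("file '", path, "' is not an assessment report", call. = FALSE)
  }
  names(tab) <- internal_report_columns
  tab
}
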