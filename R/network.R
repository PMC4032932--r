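#' Construct an association network
#'
#' A network is a named, grouped, undirected, non-negatively weighted sparse
#' graph over a [gene_index()]. The adjacency matrix is stored exactly
#' symmetric with a zero diagonal; all stored weights are strictly positive.
#'
#' @param name Network name (e.g. the source file stem).
#' @param group Network group (e.g. `coexp`, `pi`, `gi`, or user-defined).
#' @param edges Sparse symmetric adjacency matrix (`Matrix::dgCMatrix` or
#'   coercible), aligned to `index`.
#' @param index The `gene_index` the matrix rows/columns refer to.
#' @return An object of class `gba_network`.
#' @export
gba_network <- function(name, group, edges, index) {
  stopifnot(inherits(index, "gene_index"))
  edges <- methods::as(methods::as(edges, "generalMatrix"), "CsparseMatrix")
  n <- length(index)
  if (!all(dim(edges) == c(n, n))) {
    stop("adjacency matrix does not match gene index dimension", call. = FALSE)
  }
  if (!Matrix::isSymmetric(edges, tol = 0)) {
    stop("network '", name, "': adjacency matrix is not symmetric",
         call. = FALSE)
  }
  if (any(Matrix::diag(edges) != 0)) {
    stop("network '", name, "': self-loops are not allowed", call. = FALSE)
  }
  if (any(edges@x < 0)) {
    stop("network '", name, "': negative edge weights", call. = FALSE)
  }
  edges <- Matrix::drop0(edges)
  dimnames(edges) <- list(index$symbols, index$symbols)
  structure(
    list(name = as.character(name), group = as.character(group),
         edges = edges, index = index),
    class = "gba_network"
  )
}

#' @export
print.gba_network <- function(x, ...) {
  cat(sprintf("<gba_network> %s/%s: %d genes, %d edges\n",
              x$group, x$name, length(x$index), network_edge_count(x)))
  invisible(x)
}

#' Number of undirected edges in a network
#'
#' @param net A `gba_network`.
#' @return Integer edge count (each undirected edge counted once).
#' @export
network_edge_count <- function(net) {
  length(net$edges@x) %/% 2L
}

#' Extract the undirected edge list of a network
#'
#' Returns each edge once with `from < to` in index order.
#'
#' @param net A `gba_network`.
#' @return A data.frame with columns `from`, `to` (identifiers) and `weight`.
#' @export
network_edges <- function(net) {
  tr <- methods::as(Matrix::triu(net$edges, k = 1L), "TsparseMatrix")
  ord <- order(tr@i, tr@j)
  data.frame(
    from = net$index$symbols[tr@i[ord] + 1L],
    to = net$index$symbols[tr@j[ord] + 1L],
    weight = tr@x[ord],
    stringsAsFactors = FALSE
  )
}

# Build a symmetric adjacency matrix from 1-based endpoint indices,
# collapsing duplicate undirected edges to the maximum weight (deterministic
# and order-free; direction and row order in the input are irrelevant).
edges_to_adjacency <- function(i, j, w, n) {
  if (length(i) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  }
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- (lo - 1) * as.double(n) + hi
  w <- vapply(split(w, key), max, numeric(1))
  key <- as.double(names(w))
  lo <- as.integer((key - 1) %/% n + 1)
  hi <- as.integer(key - (lo - 1) * as.double(n))
  Matrix::sparseMatrix(i = c(lo, hi), j = c(hi, lo), x = c(w, w),
                       dims = c(n, n))
}
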