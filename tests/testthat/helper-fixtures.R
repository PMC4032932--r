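# Shared fixture builders. Everything is generated in code; no stored data.

# Build a gba_network from an edge table over an explicit gene universe.
edge_network <- function(edges, genes = NULL, name = "net", group = "user") {
  if (is.null(genes)) {
    genes <- sort(unique(c(edges$from, edges$to)))
  }
  idx <- gene_index(genes)
  adj <- netgba:::edges_to_adjacency(gene_position(idx, edges$from),
                                     gene_position(idx, edges$to),
                                     edges$weight, length(idx))
  gba_network(name, group, adj, idx)
}

edge_table <- function(...) {
  rows <- list(...)
  data.frame(from = vapply(rows, `[[`, character(1), 1L),
             to = vapply(rows, `[[`, character(1), 2L),
             weight = vapply(rows, function(r) as.numeric(r[[3L]]),
                             numeric(1)),
             stringsAsFactors = FALSE)
}

write_network_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A random symmetric non-negative adjacency over n genes (positions).
random_network <- function(n, p = 0.2, name = "net", group = "user",
                           genes = sprintf("g%03d", seq_len(n))) {
  idx <- gene_index(genes)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- stats::runif(nrow(ut)) < p
  if (!any(hit)) hit[sample(nrow(ut), 1L)] <- TRUE
  adj <- netgba:::edges_to_adjacency(ut[hit, 1L], ut[hit, 2L],
                                     stats::runif(sum(hit), 0.1, 1), n)
  gba_network(name, group, adj, idx)
}

# Dense oracle for the propagation system (I + D - W) f = y.
dense_propagation_oracle <- function(W, y) {
  W <- unname(as.matrix(W))
  A <- diag(1 + rowSums(W)) - W
  unname(solve(A, y))
}

# Brute-force AUROC: fraction of concordant (positive, negative) pairs.
pairwise_auroc_oracle <- function(ranking, positives) {
  is_pos <- ranking %in% positives
  P <- sum(is_pos); N <- length(ranking) - P
  if (P == 0 || N == 0) return(NA_real_)
  conc <- 0
  for (p in which(is_pos)) conc <- conc + sum(which(!is_pos) > p)
  conc / (P * N)
}

# Dense normal-equation oracle for the weight regression, replicating the
# non-positive-weight elimination rule.
dense_weight_oracle <- function(nets, target_fn) {
  nets <- nets[order(vapply(nets, `[[`, character(1), "name"))]
  norm <- lapply(nets, normalize_network)
  union_mask <- Reduce(`+`, lapply(norm, function(n) abs(as.matrix(n$edges))))
  sel <- upper.tri(union_mask) & union_mask > 0
  ij <- which(sel, arr.ind = TRUE)
  X <- vapply(norm, function(n) as.matrix(n$edges)[sel], numeric(sum(sel)))
  X <- matrix(X, ncol = length(norm),
              dimnames = list(NULL, vapply(norm, `[[`, character(1), "name")))
  keep <- !duplicated(lapply(seq_len(ncol(X)), function(k) X[, k]))
  X <- X[, keep, drop = FALSE]
  y <- target_fn(ij[, 1L], ij[, 2L])
  active <- colnames(X)
  while (length(active) > 0L) {
    D <- cbind(1, X[, active, drop = FALSE])
    beta <- tryCatch(solve(crossprod(D), crossprod(D, y)),
                     error = function(e) NULL)
    if (is.null(beta)) return(NULL)
    w <- beta[-1L, 1L]
    if (all(w > 0)) return(stats::setNames(w, active))
    active <- active[w > 0]
  }
  NULL
}

centered_target_fn <- function(n, pos_positions) {
  ybar <- rep(-length(pos_positions) / n, n)
  ybar[pos_positions] <- (n - length(pos_positions)) / n
  function(i, j) ybar[i] * ybar[j]
}

# Small synthetic assessment shared by determinism/CLI tests.
small_benchmark <- function(seed = 11) {
  spec <- synthetic_spec(n_genes = 100, n_terms = 10,
                         term_size_range = c(4, 8), p_in = 0.7,
                         p_out = 0.03, seed = seed)
  ann <- make_annotations(spec)
  noise_spec <- spec; noise_spec$p_in <- noise_spec$p_out
  list(spec = spec, ann = ann,
       noise = make_coannotation_network(ann, noise_spec, name = "noise1"),
       info = make_coannotation_network(ann, spec, name = "informative"))
}
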