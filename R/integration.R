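#' Symmetric degree normalization of a network
#'
#' Rescales edge weights as `w'_ij = w_ij / sqrt(d_i d_j)` where `d_i` is
#' the weighted degree of gene i. Isolated genes are untouched. This is the
#' standard preprocessing applied to every network before integration, and
#' makes composites invariant to rescaling any input network's raw weights.
#'
#' @param net A `gba_network` with at least one edge.
#' @return A `gba_network` with normalized weights.
#' @export
normalize_network <- function(net) {
  if (network_edge_count(net) == 0L) {
    stop("cannot normalize an edgeless network", call. = FALSE)
  }
  d <- Matrix::rowSums(net$edges)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  # rescale each undirected edge once and mirror, so the result is exactly
  # symmetric (chained matrix products can round the two triangles apart)
  tr <- methods::as(Matrix::triu(net$edges, k = 1L), "TsparseMatrix")
  i <- tr@i + 1L
  j <- tr@j + 1L
  x <- tr@x * s[i] * s[j]
  adj <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(x, x),
                              dims = dim(net$edges))
  gba_network(net$name, net$group, adj, net$index)
}

#' Construct a combined (composite) network
#'
#' @param weights Named numeric vector of per-network weights (>= 0, at
#'   least one positive). Networks absent from the fit carry weight 0.
#' @param composite Sparse symmetric composite adjacency matrix.
#' @param index Shared `gene_index`.
#' @param algorithm Label of the integration algorithm that produced it.
#' @return An object of class `combined_network`.
#' @export
combined_network <- function(weights, composite, index,
                             algorithm = "equal") {
  stopifnot(all(weights >= 0), any(weights > 0))
  structure(
    list(weights = weights, composite = Matrix::drop0(composite),
         index = index, algorithm = algorithm),
    class = "combined_network"
  )
}

#' @export
print.combined_network <- function(x, ...) {
  cat(sprintf("<combined_network> %s over %d genes\n", x$algorithm,
              length(x$index)))
  print(round(x$weights, 6))
  invisible(x)
}

# Weighted sum of pre-normalized adjacency matrices.
weighted_composite <- function(weights, norm_nets) {
  comp <- NULL
  for (k in seq_along(norm_nets)) {
    w <- weights[[norm_nets[[k]]$name]]
    if (is.null(w) || w <= 0) next
    term <- w * norm_nets[[k]]$edges
    comp <- if (is.null(comp)) term else comp + term
  }
  comp
}

#' Combine networks with equal weights
#'
#' Each of the k networks receives weight 1/k; the composite is the weighted
#' sum of the degree-normalized adjacency matrices.
#'
#' @param nets Non-empty list of `gba_network` objects over one index.
#' @return A [combined_network()].
#' @export
combine_equal <- function(nets) {
  if (length(nets) == 0L) stop("no networks to combine", call. = FALSE)
  norm <- lapply(nets, normalize_network)
  w <- stats::setNames(rep(1 / length(nets), length(nets)),
                       vapply(nets, `[[`, character(1), "name"))
  combined_network(w, weighted_composite(as.list(w), norm),
                   nets[[1L]]$index, algorithm = "equal")
}

#' Label vector under auto-negatives
#'
#' Every gene is labeled: training positives get +1, all other genes -1.
#' With every gene labeled, ranking is invariant to affine changes of the
#' label values, so the +1/-1 convention is canonical.
#'
#' @param train_pos Non-empty character vector of training-positive genes,
#'   all present in `universe`.
#' @param universe The run's `gene_index`.
#' @return An object of class `label_vector` with fields `y`, `n_pos`,
#'   `n_neg` and the positions of the positives.
#' @export
make_bias <- function(train_pos, universe) {
  pos <- gene_position(universe, train_pos)
  if (length(pos) == 0L || anyNA(pos)) {
    stop("training positives empty or outside the gene universe",
         call. = FALSE)
  }
  pos <- sort(unique(pos))
  y <- rep(-1, length(universe))
  y[pos] <- 1
  structure(
    list(y = y, n_pos = length(pos), n_neg = length(universe) - length(pos),
         positive_positions = pos),
    class = "label_vector"
  )
}

# Centered label vector used as the regression target: n_neg/n for
# positives, -n_pos/n for negatives. The target for a gene pair (i, j) is
# the product ybar_i * ybar_j.
centered_labels <- function(n, positive_positions) {
  n_pos <- length(positive_positions)
  n_neg <- n - n_pos
  if (n_pos < 1L || n_neg < 1L) {
    stop("labels must contain at least one positive and one negative",
         call. = FALSE)
  }
  ybar <- rep(-n_pos / n, n)
  ybar[positive_positions] <- n_neg / n
  ybar
}

#' Regression target for network-weight fitting
#'
#' @param labels A `label_vector`.
#' @param pairs List with integer vectors `i`, `j` (i < j): the upper-
#'   triangle gene pairs used as regression rows (pairs where at least one
#'   network has a nonzero entry).
#' @return Numeric vector of target values `ybar_i * ybar_j` per pair.
#' @export
build_target <- function(labels, pairs) {
  ybar <- centered_labels(length(labels$y), labels$positive_positions)
  ybar[pairs$i] * ybar[pairs$j]
}

# Upper-triangle (i < j) pairs where at least one normalized network has a
# nonzero entry, plus the per-network predictor columns at those pairs.
regression_design <- function(norm_nets) {
  union_adj <- NULL
  for (net in norm_nets) {
    part <- abs(net$edges)
    union_adj <- if (is.null(union_adj)) part else union_adj + part
  }
  tr <- methods::as(Matrix::triu(union_adj, k = 1L), "TsparseMatrix")
  ord <- order(tr@i, tr@j)
  i <- tr@i[ord] + 1L
  j <- tr@j[ord] + 1L
  X <- vapply(norm_nets, function(net) net$edges[cbind(i, j)],
              numeric(length(i)))
  X <- matrix(X, nrow = length(i),
              dimnames = list(NULL, vapply(norm_nets, `[[`, character(1),
                                           "name")))
  list(pairs = list(i = i, j = j), X = X)
}

# Drop networks whose predictor column duplicates an earlier one; with
# names pre-sorted lexicographically the first name is kept (deterministic
# tie rule for degenerate inputs).
drop_duplicate_columns <- function(X) {
  keep <- !duplicated(lapply(seq_len(ncol(X)), function(k) X[, k]))
  X[, keep, drop = FALSE]
}

# Non-negative iterated OLS: solve with an intercept, remove ALL networks
# with weight <= 0, re-solve, until every remaining weight is positive.
# Returns NULL on failure (singular design or no survivor) so callers can
# fall back to equal weights.
fit_network_weights <- function(X, target) {
  active <- colnames(X)
  while (length(active) > 0L) {
    design <- cbind(`(intercept)` = 1, X[, active, drop = FALSE])
    qr_d <- qr(design)
    if (qr_d$rank < ncol(design)) {
      return(NULL)
    }
    beta <- qr.coef(qr_d, target)
    w <- beta[-1L]
    if (all(w > 0)) {
      return(stats::setNames(as.numeric(w), active))
    }
    active <- active[w > 0]
  }
  NULL
}

# Shared machinery behind the unregularized and simultaneous algorithms:
# `targets` is a list of per-term target vectors over the same pair rows.
# Stacked OLS with an identical design per term equals OLS against the mean
# target, which is what we solve.
combine_by_regression <- function(nets, targets, algorithm) {
  names(nets) <- vapply(nets, `[[`, character(1), "name")
  nets <- nets[order(names(nets))]
  norm <- lapply(nets, normalize_network)
  design <- regression_design(norm)
  X <- drop_duplicate_columns(design$X)
  target <- Reduce(`+`, targets) / length(targets)
  w <- fit_network_weights(X, target)
  if (is.null(w)) {
    warning("network-weight regression degenerate; ",
            "falling back to equal weights", call. = FALSE)
    out <- combine_equal(nets)
    out$algorithm <- paste0(algorithm, "-fallback-equal")
    return(out)
  }
  weights <- stats::setNames(rep(0, length(nets)), names(nets))
  weights[names(w)] <- w
  combined_network(weights, weighted_composite(as.list(weights), norm),
                   nets[[1L]]$index, algorithm = algorithm)
}

#' Unregularized network integration
#'
#' Fits per-network weights by ordinary least squares of the pairwise label
#' target (see [build_target()]) on the corresponding entries of each
#' degree-normalized network, with an intercept. Networks receiving
#' non-positive weights are removed and the system re-solved until all
#' remaining weights are positive; if none survive (or the design is
#' singular) the combination falls back to equal weights with a warning.
#'
#' @param nets Non-empty list of `gba_network` objects over one index.
#' @param labels A `label_vector` from [make_bias()].
#' @return A [combined_network()]; eliminated networks carry weight 0.
#' @export
combine_unregularized <- function(nets, labels) {
  if (length(nets) == 0L) stop("no networks to combine", call. = FALSE)
  names(nets) <- vapply(nets, `[[`, character(1), "name")
  nets <- nets[order(names(nets))]
  design <- regression_design(lapply(nets, normalize_network))
  target <- build_target(labels, design$pairs)
  combine_by_regression(nets, list(target), "unregularized")
}

#' Simultaneous-weights network integration
#'
#' Fits one shared weight vector over all terms of an annotation collection
#' at once: each term contributes its pairwise label-target rows (the
#' predictor columns — the network entries — are identical across terms),
#' and the stacked least-squares problem is solved with the same
#' non-positive-weight elimination and fallback as
#' [combine_unregularized()]. Terms whose resolved gene sets are duplicated
#' are counted once, and terms with no positives or no negatives in the
#' universe are skipped.
#'
#' @param nets Non-empty list of `gba_network` objects over one index.
#' @param sw_annotations An `annotation_set` playing the role of the GO
#'   Biological Process collection.
#' @return A [combined_network()].
#' @export
combine_simultaneous <- function(nets, sw_annotations) {
  if (length(nets) == 0L) stop("no networks to combine", call. = FALSE)
  if (length(sw_annotations$terms) == 0L) {
    stop("simultaneous weighting needs a non-empty annotation collection",
         call. = FALSE)
  }
  names(nets) <- vapply(nets, `[[`, character(1), "name")
  nets <- nets[order(names(nets))]
  index <- nets[[1L]]$index
  n <- length(index)
  design <- regression_design(lapply(nets, normalize_network))

  gene_sets <- lapply(sw_annotations$terms, function(g) {
    sort(unique(gene_position(index, g)[!is.na(gene_position(index, g))]))
  })
  gene_sets <- gene_sets[!duplicated(gene_sets)]
  usable <- vapply(gene_sets, function(p) {
    length(p) >= 1L && length(p) < n
  }, logical(1))
  gene_sets <- gene_sets[usable]
  if (length(gene_sets) == 0L) {
    warning("no usable terms for simultaneous weighting; ",
            "falling back to equal weights", call. = FALSE)
    out <- combine_equal(nets)
    out$algorithm <- "simultaneous-fallback-equal"
    return(out)
  }
  targets <- lapply(gene_sets, function(p) {
    ybar <- centered_labels(n, p)
    ybar[design$pairs$i] * ybar[design$pairs$j]
  })
  combine_by_regression(nets, targets, "simultaneous")
}

#' Automatic integration-algorithm selection
#'
#' Dispatches on the size of the training query: fewer than five training
#' positives selects the annotation-collection-based simultaneous-weights
#' algorithm, five or more selects the unregularized algorithm. This mirrors
#' the default behavior of the underlying prediction server's integrator.
#'
#' @param nets Non-empty list of `gba_network` objects over one index.
#' @param labels A `label_vector` for the training query.
#' @param sw_annotations Annotation collection for the simultaneous branch.
#' @return A [combined_network()].
#' @export
combine_automatic <- function(nets, labels, sw_annotations) {
  if (labels$n_pos < 5L) {
    combine_simultaneous(nets, sw_annotations)
  } else {
    combine_unregularized(nets, labels)
  }
}
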