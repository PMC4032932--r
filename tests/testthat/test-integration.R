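test_that("degree normalization matches hand-computed values", {
  single <- edge_network(edge_table(list("A", "B", 4)))
  expect_equal(network_edges(normalize_network(single))$weight, 1)

  triangle <- edge_network(edge_table(list("A", "B", 1), list("B", "C", 1),
                                      list("A", "C", 1)))
  expect_equal(network_edges(normalize_network(triangle))$weight,
               rep(0.5, 3))

  star <- edge_network(edge_table(list("HUB", "L1", 1), list("HUB", "L2", 1),
                                  list("HUB", "L3", 1)))
  expect_equal(network_edges(normalize_network(star))$weight,
               rep(1 / sqrt(3), 3))
})

test_that("normalization absorbs rescaling of raw weights", {
  withr::local_seed(5)
  net <- random_network(12, p = 0.3, name = "n1")
  scaled <- gba_network("n1", "user", 7.3 * net$edges, net$index)
  expect_equal(as.matrix(normalize_network(scaled)$edges),
               as.matrix(normalize_network(net)$edges), tolerance = 1e-12)
})

test_that("equal combination averages normalized networks", {
  net <- edge_network(edge_table(list("A", "B", 2), list("B", "C", 3)))
  one <- combine_equal(list(net))
  expect_equal(as.matrix(one$composite),
               as.matrix(normalize_network(net)$edges))

  two <- combine_equal(list(net, net))
  expect_equal(as.matrix(two$composite),
               as.matrix(normalize_network(net)$edges))

  genes <- c("A", "B", "C", "D")
  n1 <- edge_network(edge_table(list("A", "B", 5)), genes, name = "n1")
  n2 <- edge_network(edge_table(list("C", "D", 2)), genes, name = "n2")
  both <- combine_equal(list(n1, n2))
  m <- as.matrix(both$composite)
  expect_equal(m["A", "B"], 0.5)
  expect_equal(m["C", "D"], 0.5)
  expect_error(combine_equal(list()), "no networks")
})

test_that("pairwise regression targets follow the centered-label formula", {
  idx <- gene_index(c("a", "b", "c", "d"))
  labels <- make_bias(c("a", "b"), idx)
  pairs <- list(i = c(1L, 1L, 3L), j = c(2L, 3L, 4L))
  expect_equal(build_target(labels, pairs), c(0.25, -0.25, 0.25))

  # equal class sizes: |target| constant across all pairs
  idx6 <- gene_index(letters[1:6])
  labels6 <- make_bias(c("a", "b", "c"), idx6)
  all_pairs <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  tgt <- build_target(labels6, list(i = all_pairs[, 1], j = all_pairs[, 2]))
  expect_equal(abs(tgt), rep(0.25, nrow(all_pairs)))

  # flipping which genes are positive permutes but preserves the multiset
  labels_flip <- make_bias(c("d", "e", "f"), idx6)
  tgt_flip <- build_target(labels_flip,
                           list(i = all_pairs[, 1], j = all_pairs[, 2]))
  expect_equal(sort(tgt_flip), sort(tgt))

  expect_error(make_bias(character(), idx), "empty")
  expect_error(netgba:::centered_labels(4, 1:4), "at least one")
})

test_that("a network affinely aligned with the target is recovered exactly", {
  # full graph on 6 genes, 3 positives: raw weight 0.5 + c * target gives
  # every node the same degree d0 = 2.5 - 0.25 c, so the normalized entry
  # is (0.5 + c t) / d0 and OLS must recover slope d0 / c exactly
  n <- 6L
  genes <- sprintf("g%02d", 1:n)
  idx <- gene_index(genes)
  pos <- 1:3
  labels <- make_bias(genes[pos], idx)
  tgt <- centered_target_fn(n, pos)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (c_true in c(1, 0.4)) {
    w <- 0.5 + c_true * tgt(ut[, 1], ut[, 2])
    net <- gba_network("n1", "user",
                       netgba:::edges_to_adjacency(ut[, 1], ut[, 2], w, n),
                       idx)
    comb <- combine_unregularized(list(net), labels)
    d0 <- 2.5 - 0.25 * c_true
    expect_equal(comb$weights[["n1"]], d0 / c_true, tolerance = 1e-10)
    expect_equal(as.matrix(comb$composite),
                 (d0 / c_true) * as.matrix(normalize_network(net)$edges),
                 tolerance = 1e-10)
  }
})

test_that("unregularized weights match the dense normal-equation oracle", {
  withr::local_seed(101)
  agreements <- 0L
  for (k in 1:25) {
    n <- 10L
    genes <- sprintf("h%02d", 1:n)
    nets <- lapply(1:3, function(m) {
      random_network(n, p = 0.4, name = paste0("net", m), genes = genes)
    })
    pos <- sample(n, 5L)
    labels <- make_bias(genes[pos], nets[[1]]$index)
    oracle <- dense_weight_oracle(nets, centered_target_fn(n, sort(pos)))
    comb <- suppressWarnings(combine_unregularized(nets, labels))
    if (is.null(oracle)) {
      expect_match(comb$algorithm, "fallback")
    } else {
      got <- comb$weights[names(oracle)]
      expect_equal(unname(got), unname(oracle), tolerance = 1e-8)
      agreements <- agreements + 1L
    }
  }
  expect_gte(agreements, 5L)  # the oracle comparison actually exercised
})

test_that("uninformative networks are eliminated, aligned ones kept", {
  withr::local_seed(202)
  n <- 10L
  genes <- sprintf("g%02d", 1:n)
  idx <- gene_index(genes)
  pos <- c(1L, 2L, 3L, 4L, 5L)
  labels <- make_bias(genes[pos], idx)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  within <- (ut[, 1] %in% pos) == (ut[, 2] %in% pos)

  # full graphs with jittered weights: "aligned" is heavy on within-class
  # pairs, "anti" heavy on cross-class pairs (reversed signal)
  full_net <- function(name, heavy_rows) {
    w <- stats::runif(nrow(ut), 0.3, 0.7)
    w[heavy_rows] <- stats::runif(sum(heavy_rows), 1.5, 2.5)
    gba_network(name, "user",
                netgba:::edges_to_adjacency(ut[, 1], ut[, 2], w, n), idx)
  }
  aligned <- full_net("aligned", within)
  anti <- full_net("anti", !within)

  comb <- suppressWarnings(
    combine_unregularized(list(anti, aligned), labels))
  expect_gt(comb$weights[["aligned"]], 0)
  expect_equal(comb$weights[["anti"]], 0)
  expect_equal(comb$algorithm, "unregularized")

  # an anti-aligned network alone gets a negative coefficient and is
  # eliminated -> fallback to equal weights with a warning
  expect_warning(
    fb <- combine_unregularized(list(anti), labels),
    "falling back to equal")
  expect_equal(unname(fb$weights), 1)
  expect_match(fb$algorithm, "fallback-equal")
})

test_that("combination weights are non-negative and order-invariant", {
  withr::local_seed(303)
  for (k in 1:10) {
    n <- 12L
    genes <- sprintf("g%02d", 1:n)
    nets <- lapply(1:3, function(m) {
      random_network(n, p = 0.35, name = paste0("net", m), genes = genes)
    })
    labels <- make_bias(genes[sample(n, 5L)], nets[[1]]$index)
    a <- suppressWarnings(combine_unregularized(nets, labels))
    b <- suppressWarnings(combine_unregularized(rev(nets), labels))
    expect_true(all(a$weights >= 0))
    expect_true(any(a$weights > 0))
    expect_equal(a$weights[sort(names(a$weights))],
                 b$weights[sort(names(b$weights))], tolerance = 1e-12)
    expect_equal(as.matrix(a$composite), as.matrix(b$composite),
                 tolerance = 1e-12)
  }
})

test_that("simultaneous weighting degenerates to unregularized for one term", {
  withr::local_seed(404)
  n <- 12L
  genes <- sprintf("g%02d", 1:n)
  nets <- lapply(1:2, function(m) {
    random_network(n, p = 0.4, name = paste0("net", m), genes = genes)
  })
  pos <- genes[sample(n, 6L)]
  labels <- make_bias(pos, nets[[1]]$index)
  sw <- annotation_set(list(only = pos))
  a <- suppressWarnings(combine_simultaneous(nets, sw))
  b <- suppressWarnings(combine_unregularized(nets, labels))
  expect_equal(a$weights[order(names(a$weights))],
               b$weights[order(names(b$weights))], tolerance = 1e-10)
})

test_that("simultaneous weighting favors a network aligned with all terms", {
  n <- 12L
  genes <- sprintf("g%02d", 1:n)
  idx <- gene_index(genes)
  terms <- list(t1 = genes[1:4], t2 = genes[3:6])
  # aligned: cliques on both terms plus a clique on the shared complement
  within <- rbind(t(combn(1:4, 2)), t(combn(3:6, 2)), t(combn(7:12, 2)))
  aligned <- gba_network("aligned", "user", netgba:::edges_to_adjacency(
    within[, 1], within[, 2], rep(1, nrow(within)), n), idx)
  noise <- local({
    withr::local_seed(9)
    random_network(n, p = 0.5, name = "noise", genes = genes)
  })
  comb <- combine_simultaneous(list(noise, aligned), annotation_set(terms))
  expect_gt(comb$weights[["aligned"]],
            10 * max(comb$weights[["noise"]], 1e-12))

  # duplicated term (identical resolved gene set) leaves weights unchanged
  dup <- annotation_set(list(t1 = terms$t1, t2 = terms$t2,
                             t3 = terms$t1))
  comb_dup <- combine_simultaneous(list(noise, aligned), dup)
  expect_equal(comb_dup$weights, comb$weights, tolerance = 1e-12)
})

test_that("simultaneous weighting matches a stacked dense OLS oracle", {
  withr::local_seed(505)
  n <- 12L
  genes <- sprintf("g%02d", 1:n)
  nets <- lapply(1:2, function(m) {
    random_network(n, p = 0.45, name = paste0("net", m), genes = genes)
  })
  sets <- list(sort(sample(n, 4L)), sort(sample(n, 5L)), sort(sample(n, 3L)))
  ann <- annotation_set(stats::setNames(
    lapply(sets, function(p) genes[p]), paste0("t", 1:3)))
  comb <- suppressWarnings(combine_simultaneous(nets, ann))

  # independent oracle: literally stack the per-term rows and solve
  norm <- lapply(nets, normalize_network)
  mask <- Reduce(`+`, lapply(norm, function(x) abs(as.matrix(x$edges))))
  sel <- upper.tri(mask) & mask > 0
  ij <- which(sel, arr.ind = TRUE)
  X1 <- vapply(norm, function(x) as.matrix(x$edges)[sel],
               numeric(sum(sel)))
  Xs <- do.call(rbind, replicate(length(sets), cbind(1, X1),
                                 simplify = FALSE))
  ys <- unlist(lapply(sets, function(p) {
    centered_target_fn(n, p)(ij[, 1], ij[, 2])
  }))
  active <- c(1L, 2L)
  repeat {
    beta <- solve(crossprod(Xs[, c(1L, active + 1L), drop = FALSE]),
                  crossprod(Xs[, c(1L, active + 1L), drop = FALSE], ys))
    w <- beta[-1L, 1L]
    if (all(w > 0) || length(active[w > 0]) == 0L) break
    active <- active[w > 0]
  }
  if (all(w > 0)) {
    oracle <- stats::setNames(rep(0, 2), paste0("net", 1:2))
    oracle[paste0("net", active)] <- w
    expect_equal(comb$weights[names(oracle)], oracle, tolerance = 1e-8)
  } else {
    expect_match(comb$algorithm, "fallback")
  }
})

test_that("automatic selection dispatches on training-query size", {
  withr::local_seed(606)
  n <- 20L
  genes <- sprintf("g%02d", 1:n)
  nets <- lapply(1:2, function(m) {
    random_network(n, p = 0.3, name = paste0("net", m), genes = genes)
  })
  sw <- annotation_set(list(t1 = genes[1:6], t2 = genes[7:12]))
  idx <- nets[[1]]$index

  four <- suppressWarnings(
    combine_automatic(nets, make_bias(genes[1:4], idx), sw))
  expect_match(four$algorithm, "simultaneous")
  five <- suppressWarnings(
    combine_automatic(nets, make_bias(genes[1:5], idx), sw))
  expect_match(five$algorithm, "unregularized")
  expect_error(make_bias(character(), idx))
})
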