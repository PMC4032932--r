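#' Specification for synthetic benchmark data
#'
#' Describes a gene universe, an annotation set and co-annotation networks
#' with controllable guilt-by-association signal: within-term gene pairs
#' receive edges with probability `p_in`, all other pairs with probability
#' `p_out`. With `p_in > p_out` the network is informative for recovering
#' the annotations; with `p_in = p_out` it is pure noise. Defaults match
#' the desk-scale signal-recovery scenario used throughout the test suite:
#' 300 genes, 30 terms of 5-10 genes, `p_in = 0.8`, `p_out = 0.02`, edge
#' weights uniform on (0.1, 1) to exercise normalization.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_terms Number of annotation terms.
#' @param term_size_range Inclusive `c(lo, hi)` bounds on term sizes.
#' @param p_in Within-term edge probability.
#' @param p_out Background edge probability (`0 <= p_out <= p_in <= 1`).
#' @param weight_law `"uniform"` or `"constant"` edge-weight law.
#' @param weight_range `c(lo, hi)` for the uniform law; `lo` is the value
#'   used by the constant law.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 300L, n_terms = 30L,
                           term_size_range = c(5L, 10L), p_in = 0.8,
                           p_out = 0.02,
                           weight_law = c("uniform", "constant"),
                           weight_range = c(0.1, 1.0), seed = 1L) {
  stopifnot(n_genes >= 3L, n_terms >= 1L,
            term_size_range[1L] >= 1L,
            term_size_range[1L] <= term_size_range[2L],
            term_size_range[2L] <= n_genes,
            p_out >= 0, p_out <= p_in, p_in <= 1,
            weight_range[1L] > 0, weight_range[1L] <= weight_range[2L])
  structure(
    list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
         term_size_range = as.integer(term_size_range), p_in = p_in,
         p_out = p_out, weight_law = match.arg(weight_law),
         weight_range = weight_range, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

synthetic_genes <- function(spec) {
  sprintf("G%04d", seq_len(spec$n_genes))
}

draw_weights <- function(spec, k) {
  if (spec$weight_law == "constant") {
    rep(spec$weight_range[1L], k)
  } else {
    stats::runif(k, spec$weight_range[1L], spec$weight_range[2L])
  }
}

#' Generate a synthetic annotation set
#'
#' Terms have sizes uniform on the configured range and members sampled
#' without replacement from the gene universe; terms may overlap, as GO
#' terms do. Deterministic given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return An `annotation_set` whose `genes` attribute carries the full
#'   gene universe.
#' @export
make_annotations <- function(spec) {
  genes <- synthetic_genes(spec)
  ann <- with_local_seed(term_seed(spec$seed, "annotations"), {
    lo <- spec$term_size_range[1L]
    hi <- spec$term_size_range[2L]
    sizes <- lo + sample.int(hi - lo + 1L, spec$n_terms,
                             replace = TRUE) - 1L
    terms <- lapply(sizes, function(s) sort(sample(genes, s)))
    names(terms) <- sprintf("T:%07d", seq_len(spec$n_terms))
    annotation_set(terms)
  })
  attr(ann, "genes") <- genes
  ann
}

# Bernoulli edges over the pair sets implied by the annotations.
coannotation_edges <- function(annotations, spec) {
  genes <- synthetic_genes(spec)
  n <- spec$n_genes
  idx <- function(g) match(g, genes)
  within <- matrix(FALSE, n, n)
  for (members in annotations$terms) {
    p <- idx(members)
    within[p, p] <- TRUE
  }
  ut <- which(upper.tri(within), arr.ind = TRUE)
  p_edge <- ifelse(within[ut], spec$p_in, spec$p_out)
  hit <- stats::runif(nrow(ut)) < p_edge
  list(i = ut[hit, 1L], j = ut[hit, 2L],
       w = draw_weights(spec, sum(hit)))
}

#' Generate a co-annotation network
#'
#' Each within-term gene pair receives an edge with probability `p_in`,
#' every other pair with probability `p_out`; weights follow the spec's
#' weight law. With `p_in = p_out` the edge set is independent of the
#' annotations (a pure-noise network).
#'
#' @param annotations Annotation set from [make_annotations()].
#' @param spec A [synthetic_spec()].
#' @param name,group Network name and group.
#' @param seed_tag String mixed into the RNG stream so several networks
#'   can be drawn independently from one spec.
#' @return A `gba_network` over the spec's full gene universe.
#' @export
make_coannotation_network <- function(annotations, spec, name = "synthetic",
                                      group = "user", seed_tag = name) {
  genes <- synthetic_genes(spec)
  e <- with_local_seed(term_seed(spec$seed, paste0("net:", seed_tag)),
                       coannotation_edges(annotations, spec))
  index <- gene_index(genes)
  gba_network(name, group, edges_to_adjacency(e$i, e$j, e$w, length(index)),
              index)
}

# A connected random graph on the given vertex positions: a random
# recursive tree guarantees connectivity, plus independent extra edges with
# probability p.
connected_random_edges <- function(verts, p, spec) {
  m <- length(verts)
  ti <- verts[seq(2L, m)]
  tj <- verts[vapply(seq(2L, m), function(k) sample(k - 1L, 1L), integer(1))]
  extra <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  hit <- stats::runif(nrow(extra)) < p
  i <- c(ti, verts[extra[hit, 1L]])
  j <- c(tj, verts[extra[hit, 2L]])
  list(i = i, j = j, w = draw_weights(spec, length(i)))
}

#' Generate an overlapping network trio
#'
#' Produces three connected networks A, B and C such that A and B have
#' disjoint gene supports (hence A ∪ B is disconnected between them) while
#' C straddles both supports, so paths between A-genes and B-genes exist
#' only when C is included. This is the canonical synergy scenario for
#' label-propagation predictors that exploit indirect connections.
#'
#' @param spec A [synthetic_spec()]; `n_genes` must be at least 9.
#' @param p Extra-edge probability within each component (default 0.3).
#' @return Named list of three `gba_network` objects `A`, `B`, `C` over the
#'   spec's gene universe.
#' @export
make_overlap_trio <- function(spec, p = 0.3) {
  stopifnot(spec$n_genes >= 9L)
  genes <- synthetic_genes(spec)
  n <- spec$n_genes
  third <- n %/% 3L
  blk_a <- seq_len(third)
  blk_b <- seq(third + 1L, 2L * third)
  index <- gene_index(genes)
  with_local_seed(term_seed(spec$seed, "trio"), {
    ea <- connected_random_edges(blk_a, p, spec)
    eb <- connected_random_edges(blk_b, p, spec)
    straddle <- c(blk_a[seq(length(blk_a) %/% 2L + 1L, length(blk_a))],
                  blk_b[seq(length(blk_b) %/% 2L + 1L, length(blk_b))])
    ec <- connected_random_edges(straddle, p, spec)
    list(
      A = gba_network("A", "user", edges_to_adjacency(ea$i, ea$j, ea$w, n),
                      index),
      B = gba_network("B", "user", edges_to_adjacency(eb$i, eb$j, eb$w, n),
                      index),
      C = gba_network("C", "user", edges_to_adjacency(ec$i, ec$j, ec$w, n),
                      index)
    )
  })
}

#' Write a synthetic benchmark to disk
#'
#' Materializes a noise network, an informative co-annotation network, a
#' second noise network and the gold standard in the package's file
#' dialects, laid out as `networks/<group>/<name>.txt` plus
#' `go-terms.txt`, so the command-line interface can be exercised on files
#' alone.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()].
#' @return Invisibly, a list with the paths written.
#' @export
write_synthetic_fixtures <- function(dir, spec = synthetic_spec()) {
  ann <- make_annotations(spec)
  noise_spec <- spec
  noise_spec$p_in <- spec$p_out
  nets <- list(
    make_coannotation_network(ann, noise_spec, name = "noise1",
                              group = "baseline"),
    make_coannotation_network(ann, noise_spec, name = "noise2",
                              group = "candidate"),
    make_coannotation_network(ann, spec, name = "informative",
                              group = "candidate")
  )
  paths <- character()
  for (net in nets) {
    gdir <- file.path(dir, "networks", net$group)
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(gdir, paste0(net$name, ".txt"))
    write_network_file(net, p)
    paths <- c(paths, p)
  }
  gold <- file.path(dir, "go-terms.txt")
  writeLines(vapply(names(ann$terms), function(id) {
    paste(c(id, ann$terms[[id]]), collapse = "\t")
  }, character(1)), gold)
  invisible(list(networks = paths, gold_standard = gold))
}
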