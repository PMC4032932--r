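# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps per-term fold plans independent of
# global RNG use, thread count and term processing order.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

# Deterministic 31-bit seed derived from the run seed and a term id.
term_seed <- function(seed, term_id) {
  h <- 0
  for (ch in utf8ToInt(term_id)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.double(seed) * 2654435) %% 2147483647)
}

#' Filter terms by resolved size and branch
#'
#' Keeps terms whose resolved gene count c satisfies
#' `min_annotations <= c <= max_annotations` (inclusive); when the
#' configuration names a branch and the annotation set carries branch tags,
#' terms of other branches are removed first. Small terms are excluded by
#' default because binary classifiers generally perform worse on them.
#'
#' @param annotations An `annotation_set`, already resolved against the
#'   run's gene universe.
#' @param cfg A [run_config()].
#' @return The filtered `annotation_set`.
#' @export
filter_terms <- function(annotations, cfg) {
  terms <- annotations$terms
  branch <- annotations$branch
  if (!is.null(cfg$branch) && !is.null(branch)) {
    keep <- names(terms)[names(terms) %in%
                           names(branch)[branch == cfg$branch]]
    terms <- terms[keep]
  }
  sizes <- lengths(terms)
  keep <- sizes >= cfg$min_annotations & sizes <= cfg$max_annotations
  if (!any(keep)) {
    dist <- table(sizes)
    stop("no terms with between ", cfg$min_annotations, " and ",
         cfg$max_annotations, " annotations; size distribution: ",
         paste(sprintf("%s genes x%d", names(dist), as.integer(dist)),
               collapse = ", "), call. = FALSE)
  }
  annotation_set(terms[keep],
                 branch = if (is.null(branch)) NULL else
                   branch[names(branch) %in% names(terms)[keep]])
}

#' Partition a term's positives into K folds
#'
#' The positives are shuffled by an RNG seeded from the run seed and the
#' term id, then dealt round-robin into K subsets. The plan is a function
#' of `(seed, term_id, K)` only, so the baseline and subject rounds of an
#' assessment — and re-runs at any thread count or term order — partition
#' identically. Folds may be empty when there are fewer positives than K.
#'
#' @param positives Character vector of annotated genes (>= 1).
#' @param K Number of folds (>= 2).
#' @param seed Run seed.
#' @param term_id Term identifier keying the per-term RNG stream.
#' @return List of K character vectors partitioning `positives`.
#' @export
make_folds <- function(positives, K, seed, term_id) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("folds must be >= 2", call. = FALSE)
  positives <- sort(unique(positives))
  if (length(positives) == 0L) stop("no positives to fold", call. = FALSE)
  shuffled <- with_local_seed(term_seed(seed, term_id), sample(positives))
  fold_of <- factor(((seq_along(shuffled) - 1L) %% K) + 1L,
                    levels = seq_len(K))
  unname(split(shuffled, fold_of))
}

#' Cross-validate one term against a network set
#'
#' For each fold with at least one held-out positive (and at least one
#' training positive), the remaining positives form the training query:
#' the networks are integrated on the training labels, labels propagated,
#' and all genes except the training positives ranked. Held-out positives
#' are then evaluated against all non-term genes, and the three ranking
#' metrics averaged over the evaluated folds.
#'
#' @param nets List of resolved `gba_network` objects (one network set).
#' @param positives Character vector of the term's resolved genes.
#' @param cfg A [run_config()].
#' @param term_id Term identifier (keys the fold plan).
#' @param index The run's `gene_index`.
#' @param sw_annotations Annotation collection for the simultaneous-weights
#'   branch of [combine_automatic()].
#' @param sw_combined Optional precomputed [combined_network()] to use for
#'   queries with fewer than five training positives. The simultaneous
#'   weighting depends only on the annotation collection, not on the fold,
#'   so callers may compute it once per network set.
#' @return Named numeric vector `auroc`, `aupr`, `p10r`, `n_folds`.
#' @export
cross_validate_term <- function(nets, positives, cfg, term_id, index,
                                sw_annotations = NULL, sw_combined = NULL) {
  positives <- unique(canonical_id(positives))
  plan <- make_folds(positives, cfg$folds, cfg$seed, term_id)
  per_fold <- list()
  for (held in plan) {
    if (length(held) == 0L) next
    train <- setdiff(positives, held)
    if (length(train) == 0L) next
    labels <- make_bias(train, index)
    comb <- if (cfg$integration == "equal") {
      combine_equal(nets)
    } else if (labels$n_pos < 5L && !is.null(sw_combined)) {
      sw_combined
    } else {
      combine_automatic(nets, labels, sw_annotations)
    }
    scores <- propagate(comb, labels)
    ranking <- rank_candidates(scores, index, exclude = train)
    per_fold[[length(per_fold) + 1L]] <- fold_metrics(ranking, held)
  }
  if (length(per_fold) == 0L) {
    return(c(auroc = NA_real_, aupr = NA_real_, p10r = NA_real_,
             n_folds = 0))
  }
  m <- do.call(rbind, per_fold)
  c(colMeans(m), n_folds = nrow(m))
}

#' Relative change of a metric (%ERR)
#'
#' `subject / baseline - 1`: the relative improvement of the subject round
#' over the baseline round. Undefined (NA) when the baseline value is
#' missing or non-positive.
#'
#' @param baseline_value,subject_value Mean fold metrics of the two rounds.
#' @return Numeric; `NA` when undefined.
#' @export
percent_err <- function(baseline_value, subject_value) {
  ifelse(!is.na(baseline_value) & !is.na(subject_value) &
           baseline_value > 0,
         subject_value / baseline_value - 1, NA_real_)
}

# Run one closure per term, serially or via forked workers. Results are
# bitwise identical across thread counts because every term carries its own
# RNG stream; a failed term is recorded and does not abort the run.
run_term_tasks <- function(term_ids, task, threads) {
  worker <- function(id) {
    tryCatch(task(id), error = function(e) {
      structure(list(term_id = id, message = conditionMessage(e)),
                class = "term_failure")
    })
  }
  if (threads > 1L) {
    res <- parallel::mclapply(term_ids, worker, mc.cores = threads,
                              mc.preschedule = TRUE)
  } else {
    res <- lapply(term_ids, worker)
  }
  names(res) <- term_ids
  res
}

#' Assess subject networks against a baseline
#'
#' The five-step differential assessment: (1) integrate the baseline
#' networks, (2) cross-validate every surviving term against the baseline
#' composite, (3) repeat both steps for the subject networks using the
#' identical fold plans, (4) compute the per-term %ERR of AUROC, AUPR and
#' precision-at-10%-recall, and (5) sort the table by descending
#' %ERR-AUC-ROC (ties by ascending term id) so the terms most helped or
#' hurt by the subject selection stand out.
#'
#' @param baseline_nets,subject_nets Non-empty lists of `gba_network`
#'   objects. Both are resolved against the common gene universe (the union
#'   over all networks of both sets).
#' @param annotations The gold-standard `annotation_set`.
#' @param cfg A [run_config()].
#' @param synonyms Optional synonym table from [read_synonym_file()].
#' @param sw_annotations Annotation collection for simultaneous weighting;
#'   defaults to the run's own gold standard restricted to terms with 3-300
#'   resolved genes.
#' @return Data frame with one row per assessed term: `term_id`,
#'   `n_annotations`, baseline/subject/err columns for the three metrics,
#'   and `n_folds`. Attribute `failed_terms` lists per-term failures.
#' @export
assess <- function(baseline_nets, subject_nets, annotations, cfg,
                   synonyms = NULL, sw_annotations = NULL) {
  if (length(baseline_nets) == 0L || length(subject_nets) == 0L) {
    stop("baseline and subject selections must both be non-empty",
         call. = FALSE)
  }
  pool <- c(baseline_nets, subject_nets)
  pool_names <- vapply(pool, `[[`, character(1), "name")
  base_names <- vapply(baseline_nets, `[[`, character(1), "name")
  subj_names <- vapply(subject_nets, `[[`, character(1), "name")
  res <- resolve_inputs(pool[!duplicated(pool_names)], annotations,
                        synonyms = synonyms)
  index <- res$index
  base_nets <- res$networks[unique(base_names)]
  subj_nets <- res$networks[unique(subj_names)]
  ann <- filter_terms(res$annotations, cfg)

  if (is.null(sw_annotations)) {
    sizes <- term_sizes(res$annotations)
    sw_annotations <- annotation_set(
      res$annotations$terms[sizes >= 3L & sizes <= 300L])
    if (length(sw_annotations$terms) == 0L) sw_annotations <- ann
  }
  sw_base <- combine_simultaneous(base_nets, sw_annotations)
  sw_subj <- combine_simultaneous(subj_nets, sw_annotations)

  task <- function(id) {
    positives <- ann$terms[[id]]
    b <- cross_validate_term(base_nets, positives, cfg, id, index,
                             sw_annotations, sw_combined = sw_base)
    s <- cross_validate_term(subj_nets, positives, cfg, id, index,
                             sw_annotations, sw_combined = sw_subj)
    data.frame(
      term_id = id, n_annotations = length(positives),
      baseline_auroc = b[["auroc"]], subject_auroc = s[["auroc"]],
      err_auroc = percent_err(b[["auroc"]], s[["auroc"]]),
      baseline_aupr = b[["aupr"]], subject_aupr = s[["aupr"]],
      err_aupr = percent_err(b[["aupr"]], s[["aupr"]]),
      baseline_p10r = b[["p10r"]], subject_p10r = s[["p10r"]],
      err_p10r = percent_err(b[["p10r"]], s[["p10r"]]),
      n_folds = b[["n_folds"]],
      stringsAsFactors = FALSE
    )
  }
  results <- run_term_tasks(names(ann$terms), task, cfg$threads)
  failed <- Filter(function(r) inherits(r, "term_failure"), results)
  rows <- results[!vapply(results, inherits, logical(1), "term_failure")]
  if (length(rows) == 0L) {
    stop("every term failed; first error: ", failed[[1L]]$message,
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- sort_assessment(out)
  rownames(out) <- NULL
  attr(out, "failed_terms") <- lapply(failed, `[[`, "message")
  attr(out, "gene_universe") <- length(index)
  attr(out, "dropped_edges") <- res$dropped_edges
  out
}

# Descending %ERR-AUC-ROC, NA last, ties by ascending term id.
sort_assessment <- function(records) {
  records[order(-xtfrm(records$err_auroc), records$term_id,
                method = "radix"), , drop = FALSE]
}

#' Summarize an assessment by term-size bin
#'
#' Groups terms by annotation count and reports, per bin and per metric
#' column, the median and a 95% interval half-width — half the spread
#' between the 2.5th and 97.5th percentiles of the per-term values — in the
#' style of release-over-release quality-control summaries.
#'
#' @param records Assessment data frame from [assess()] (or
#'   [read_report()]; then `n_annotations` must be supplied separately in a
#'   column of that name).
#' @param size_bins List of `c(lo, hi)` inclusive annotation-count bins;
#'   default `list(c(3, 10), c(11, 300))`.
#' @param metrics Character vector of metric columns to summarize.
#' @return Data frame with columns `bin`, `metric`, `median`,
#'   `ci95_halfwidth`, `n_terms`. Empty bins are omitted with a warning.
#' @export
summarize_assessment <- function(records,
                                 size_bins = list(c(3, 10), c(11, 300)),
                                 metrics = c("baseline_auroc",
                                             "subject_auroc",
                                             "baseline_aupr",
                                             "subject_aupr",
                                             "baseline_p10r",
                                             "subject_p10r")) {
  if (nrow(records) == 0L) stop("no records to summarize", call. = FALSE)
  if (is.null(records$n_annotations)) {
    stop("records lack an n_annotations column", call. = FALSE)
  }
  rows <- list()
  for (bin in size_bins) {
    label <- paste0(bin[1L], "-", bin[2L])
    in_bin <- records$n_annotations >= bin[1L] &
      records$n_annotations <= bin[2L]
    if (!any(in_bin)) {
      warning("no terms in size bin ", label, call. = FALSE)
      next
    }
    for (m in metrics) {
      v <- records[[m]][in_bin]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        bin = label, metric = m, median = stats::median(v),
        ci95_halfwidth = (q[2L] - q[1L]) / 2, n_terms = length(v),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("all size bins are empty", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a bin-by-metric summary table
#'
#' @param summary Data frame from [summarize_assessment()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
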