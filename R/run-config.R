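#' Assessment run configuration
#'
#' Bundles the cross-validation and filtering parameters of an assessment
#' run.
#'
#' @param folds Number of cross-validation folds K (>= 2).
#' @param min_annotations,max_annotations Inclusive bounds on the resolved
#'   gene count of a term for it to be assessed.
#' @param seed Integer seed controlling fold partitioning. `0` (or `NA`)
#'   draws a time-based seed, which is reported via a message; using the
#'   same non-zero seed guarantees identical fold plans across runs and
#'   across the baseline and subject rounds.
#' @param threads Number of worker processes for per-term cross-validation.
#' @param auto_negatives Logical; every gene not annotated to the term under
#'   evaluation is treated as a negative example. This is the only supported
#'   labeling scheme.
#' @param integration `"automatic"` (regression-based weighting chosen by
#'   training-query size) or `"equal"` (uniform network weights).
#' @param branch Optional branch filter (`bp`, `cc` or `mf`), applied only
#'   when the annotation set carries branch tags.
#' @return An object of class `run_config`.
#' @export
run_config <- function(folds = 5L, min_annotations = 3L,
                       max_annotations = 300L, seed = 0L, threads = 1L,
                       auto_negatives = TRUE,
                       integration = c("automatic", "equal"),
                       branch = NULL) {
  folds <- as.integer(folds)
  min_annotations <- as.integer(min_annotations)
  max_annotations <- as.integer(max_annotations)
  threads <- as.integer(threads)
  if (is.na(folds) || folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (is.na(min_annotations) || min_annotations < 1L ||
      min_annotations > max_annotations) {
    stop("need 1 <= min_annotations <= max_annotations", call. = FALSE)
  }
  if (is.na(threads) || threads < 1L) {
    stop("threads must be >= 1", call. = FALSE)
  }
  if (!isTRUE(auto_negatives)) {
    stop("only auto-negatives labeling is supported", call. = FALSE)
  }
  if (is.na(seed) || seed == 0L) {
    seed <- as.integer(as.numeric(Sys.time()) %% 2147483646) + 1L
    message("no seed given; using time-based seed ", seed)
  }
  structure(
    list(folds = folds, min_annotations = min_annotations,
         max_annotations = max_annotations, seed = as.integer(seed),
         threads = threads, auto_negatives = TRUE,
         integration = match.arg(integration), branch = branch),
    class = "run_config"
  )
}
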