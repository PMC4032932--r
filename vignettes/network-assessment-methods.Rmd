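---
title: "Methods: differential assessment of association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential assessment of association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgba)
```

## The question the package answers

Guilt-by-association (GBA) function prediction ranks genes by their network
proximity to genes already annotated with a function. How useful a given
association network is for this task depends on the function: a network can
be decisive for some terms and irrelevant — or harmful — for others. A
single network-level score therefore hides most of the picture.

`netgba` quantifies a network's predictive potential *per function label*.
Two network selections are compared: a **baseline** set with known
predictive behavior, and a **subject** set, typically the baseline with one
or more candidate networks added (or removed). Each set is integrated into
a composite graph, a GBA classifier is cross-validated against a gold
standard (e.g. GO terms and their gene lists), and for every term the
relative change

$$\%\mathrm{ERR} = \frac{\text{SUBJECT metric}}{\text{BASELINE metric}} - 1$$

is reported for AUROC, AUPR and precision-at-10%-recall. Sorting by
%ERR-AUC-ROC surfaces the functions most helped or hurt by the candidate
networks. Measuring a network *in combination* rather than in isolation
matters because network data are synergistic: a network C overlapping two
otherwise disjoint networks A and B creates indirect paths that label
propagation exploits, so C's value is only visible in the union
(`make_overlap_trio()` generates exactly this scenario for testing).

## The pipeline

1. **Resolution.** Identifiers are trimmed and case-folded; an optional
   two-column synonym table maps alternates to canonical identifiers, and
   any alternate mapping to more than one canonical identifier is discarded
   outright, together with its edges — the conservative rule used by
   production pipelines to avoid ambiguity. The gene universe is the union
   of genes on edges of any input network; annotation genes outside it are
   dropped.
2. **Term filtering.** Terms with fewer than `min_annotations` or more than
   `max_annotations` *resolved* genes are excluded (bounds inclusive).
   Small terms are excluded by default because binary classifiers behave
   erratically on them.
3. **Integration.** Every network is first degree-normalized,
   $w'_{ij} = w_{ij} / \sqrt{d_i d_j}$, which makes composites invariant to
   rescaling any input network. Per-network weights are then fitted by
   regressing pairwise label targets on network entries (below), and the
   composite is the weighted sum of normalized networks.
4. **Cross-validation.** Per term, positives are split into K folds; each
   fold is held out in turn, the networks are re-integrated on the training
   labels, labels are propagated, and held-out positives are evaluated
   against all non-term genes. Per-term metrics are the unweighted mean
   over folds with at least one held-out positive.
5. **Differencing and reporting.** The two rounds share byte-identical fold
   plans, %ERR is computed per term and metric, and the table is written
   sorted by descending %ERR-AUC-ROC with ties broken by term id.

## Label propagation

With auto-negatives, every gene is labeled: training positives $y_i = +1$,
all others $-1$. Scores minimize
$\sum_i (f_i - y_i)^2 + \sum_{ij} w_{ij} (f_i - f_j)^2$, i.e. solve
$(I + L)f = y$ with $L = D - W$ the combinatorial Laplacian of the
composite. The system is symmetric positive definite, so the solution is
unique; isolated genes get $f_i = y_i$ exactly. Because every gene is
labeled, rankings are invariant to affine changes of $y$, which is why the
±1 convention carries no hidden tradeoff parameter; the single
fidelity-vs-smoothness weight is fixed at 1. Systems under 500 genes are
solved densely; larger ones by conjugate gradient to a relative residual of
1e-9 (capped at 10,000 iterations, with an error on non-convergence). Ranks
are deterministic: ties in score break by ascending gene identifier, and
the metrics are computed on the realized order rather than by mid-rank
averaging, so there is one source of ordering truth.

## Network weighting

The regression target follows the kernel-target alignment construction:
with $n_+$ positives among $n$ genes, the centered label
$\bar y_i$ is $n_-/n$ for positives and $-n_+/n$ for negatives, and the
target for gene pair $(i,j)$ is $\bar y_i \bar y_j$. Regression rows are
the upper-triangle pairs where at least one normalized network has a
nonzero entry — including the all-zero rows would let the (overwhelming)
empty part of the adjacency dominate the fit — plus an intercept column
that is discarded from the composite.

- **Unregularized** (training queries of ≥ 5 genes): ordinary least squares
  of the target on the per-network entries. Networks receiving
  non-positive weights are all removed and the system re-solved until every
  remaining weight is positive; if none survive, or the design is singular,
  the combination falls back to equal weights with a warning.
- **Simultaneous weights** (queries of < 5 genes): one shared weight vector
  fitted over *all* terms of an annotation collection at once; each term
  contributes its target rows over the same predictor columns. Because the
  design matrix is identical across terms, the stacked least-squares
  solution equals OLS against the mean target, which is how it is computed
  (a test checks this against a literally stacked dense solve). The
  collection defaults to the run's own gold standard restricted to terms
  with 3–300 genes — a self-contained stand-in for a broad
  biological-process collection. Terms with duplicated resolved gene sets
  are counted once, so duplicating a term in the collection cannot tilt the
  fit; likewise, networks with identical predictor columns keep only the
  lexicographically first name. Since the simultaneous fit depends only on
  the collection — not on the fold's training labels — `assess()` computes
  it once per network round and reuses it across folds.

The automatic selector dispatches on the training-query size (< 5 versus
≥ 5 positives), matching the default behavior of the integrator it models.
`--integration equal` bypasses the regression entirely.

## Metrics

AUROC is computed by rank-sum (the fraction of concordant
positive–negative pairs). AUPR is step-wise average precision — the mean of
precision at each positive's rank — without interpolation, the standard
choice for function-prediction cross-validation and exact on small worked
examples. Precision-at-10%-recall is the precision at the smallest cutoff
whose recall reaches 0.10; with ten or fewer positives that is the first
retrieved positive. All three are undefined (reported `NA`) when a fold has
no positives or no negatives, and %ERR is `NA` when the baseline mean is
undefined or non-positive. A perfect ranking gives AUROC = AUPR = 1; random
rankings average AUROC 0.5 and AUPR P/(P+N), which the test suite verifies
statistically (10,000 random orderings with P = 50, N = 950).

## Determinism and parallelism

Each term's fold plan is drawn from an RNG seeded by a hash of the run seed
and the term id, not from one global stream. Consequences: the baseline and
subject rounds partition identically; results are bitwise identical across
thread counts (`parallel::mclapply` forks per term) and across term
orderings; and a gold standard split across several files and re-merged
reproduces the single-run report up to the final sort. Seed 0 (or absent)
draws a time-based seed and logs it. Fold assignment deals the shuffled
positives round-robin, so folds may be empty when a term has fewer
positives than K; folds with no held-out positive (or no remaining training
positive) are skipped from the fold mean.

## The synthetic generator

`synthetic_spec()` plants GBA structure directly: within-term gene pairs
get edges with probability `p_in`, background pairs with `p_out`, weights
uniform on (0.1, 1) to exercise normalization. Terms may overlap, as GO
terms do. The defaults — 300 genes, 30 terms of 5–10 genes, `p_in = 0.8`,
`p_out = 0.02`, 5-fold CV — are the desk-scale study conditions under which
the package's headline property is demonstrated: adding the informative
network to a noise baseline yields a strongly positive median %ERR-AUC-ROC,
while adding a second noise network leaves it near zero. These sizes keep a
full double-round assessment under a minute on one core.

What the generator does *not* emulate: realistic degree distributions
(hubs), weight correlation structure between networks, annotation bias
toward well-studied genes, or the GO hierarchy. Passing the synthetic suite
therefore demonstrates correctness of the machinery and sensitivity to
planted signal, not performance levels transferable to real organisms; the
published large-scale medians depend on multi-gigabyte curated data
releases and are out of scope at desk scale, where the same size-binned
median ± percentile summaries (`summarize_assessment()`, bins 3–10 and
11–300 by default) are exercised on synthetic assessments instead. The 95%
interval reported is the percentile half-width,
(97.5th − 2.5th percentile)/2, of the per-term values — a descriptive
spread, not a standard error. Note also that with a near-chance baseline
(AUROC ≈ 0.5) the per-term %ERR is roughly twice the absolute AUROC
difference, so its median over a few dozen terms fluctuates by several
hundredths across generator seeds; the near-zero property for a noise
subject is a statement about the fixed study conditions, not every seed.

## Numerical and degenerate-input choices

- Duplicate undirected edges within a file collapse to the **maximum**
  weight — deterministic and order-free, so permuting file rows cannot
  change the parsed network. Self-loops are dropped with a warning.
- Weight regressions use QR; rank deficiency triggers the equal-weights
  fallback rather than a pseudo-inverse, keeping reported weights
  interpretable.
- Degree normalization computes each undirected edge once and mirrors it,
  keeping adjacency matrices exactly symmetric (chained
  diagonal-matrix products can round the two triangles apart).
- Report floats are printed with nine significant digits; `NA` marks
  undefined values. Edge weights round-trip through files at full double
  precision (`%.17g`).

## Worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1)
ann <- make_annotations(spec)
noise_spec <- spec; noise_spec$p_in <- noise_spec$p_out
noise <- make_coannotation_network(ann, noise_spec, name = "noise1")
info <- make_coannotation_network(ann, spec, name = "informative")
cfg <- run_config(folds = 5, min_annotations = 3, max_annotations = 10,
                  seed = 1)
r <- assess(list(noise), list(noise, info), ann, cfg)
median(r$err_auroc)
summarize_assessment(r, size_bins = list(c(3, 10)))
```

The vignette is not evaluated at build time; the README shows the numbers
this example prints, and `scripts/acceptance.R` recomputes them from
scratch.
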