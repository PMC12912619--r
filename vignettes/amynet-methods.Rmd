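---
title: "Individual-specific amyloid deposition networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-specific amyloid deposition networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amynet)
```

## The problem

Amyloid-beta plaque deposition, measured region by region with amyloid PET
as the standardized uptake value ratio (SUVR = regional mean uptake divided
by whole-pons mean uptake), does not accumulate independently across brain
regions: regions co-vary across subjects, and that covariance structure —
the *deposition network* — changes as disease progresses. Group-level
covariance networks cannot be attached to a single patient, so this package
implements the add-one-subject perturbation construction: a reference
correlation network is computed over $n$ control subjects, the network is
recomputed after adding one test subject, and the subject's
individual-specific network is the matrix of edge-wise Z-scores of the
perturbation.

Concretely, with $REN_n$ the ROI-by-ROI Pearson correlation matrix of the
control SUVRs and $CDN_{n+1}$ the same matrix over the $n$ controls plus
one subject,

$$ z_{ij} \;=\; \frac{\Delta_{ij}}{\bigl(1 - CDN_{ij}^2\bigr)\,/\,(n-1)},
   \qquad \Delta = CDN_{n+1} - REN_n . $$

The denominator is used exactly as written, without a square root; a
square-root variant is available through
`perturbation_zscore(..., denominator = "sqrt")` for sensitivity analysis.
One subject can only move a correlation of $n$ subjects by $O(1/n)$, and
the $(n-1)$ factor rescales that perturbation to an order-one quantity.

Each Z network is thresholded into binary graphs over a sparsity grid
(default 0.05 to 0.35 in steps of 0.01, 31 levels), keeping the strongest
$\lfloor s \cdot M \rfloor$ positive edges at sparsity $s$ out of
$M = R(R-1)/2$ possible edges. Negative edges are discarded. Ten
graph-theoretic properties are computed per graph — average degree, mean
clustering coefficient $C_p$, characteristic path length $L_p$, global and
local efficiency, and the small-world triple
$\gamma = C_p/C_p^{rand}$, $\lambda = L_p/L_p^{rand}$,
$\sigma = \gamma/\lambda$ at the global level; degree, betweenness
centrality, clustering, nodal efficiency and nodal local efficiency at the
regional level — and aggregated across the grid by the trapezoidal rule.

## Scoring control subjects: leave-one-out referencing

Controls are scored the same way as patients, by adding them to the
reference. Read literally, a control would be added *on top of a reference
that already contains them*, duplicating their own rows. We found in null
simulations that this duplication gives in-reference subjects a
systematically different Z distribution than out-of-reference subjects and
roughly doubles the family-wise error of control-versus-patient regional
comparisons. The default (`reference_handling = "loo"`) therefore scores
each control against the correlation network of the other $n-1$ controls,
the convention of the individual differential covariance network
literature; the literal duplication is available as
`reference_handling = "duplicate"`.

## Fisher transform placement

The variance-stabilizing arctanh transform is defined only on
correlation-valued matrices; applying it to a Z-score matrix would be
undefined wherever $|z| > 1$. `fisher_transform()` therefore accepts
reference and perturbed correlation networks (with clipping at $\pm 1$) and
refuses Z-scored individual networks. The pipeline's default path
binarizes the Z matrix directly, which is invariant to any monotone
transform of the edge weights — so for ranking-based thresholding the
placement question is moot.

## Graph-metric conventions

* Betweenness centrality uses Brandes' accumulation over unordered pairs;
  both the raw and the $(R-1)(R-2)/2$-normalized scales are returned, and
  group statistics default to the raw scale.
* Disconnected graphs: $L_p$ is the mean over connected ordered pairs with
  the infinite-pair fraction reported alongside; the efficiency metrics are
  the disconnection-robust quantities and are always defined.
* Clustering of a node with degree below 2 is 0, and $C_p$ averages over
  all nodes.
* Small-world normalization uses Maslov–Sneppen degree-preserving
  double-edge swaps (default 100 random graphs, 10 successful swaps per
  edge), driven by R's RNG so `set.seed()` makes runs reproducible. With
  zero swaps the ensemble is the graph itself and
  $\gamma = \lambda = \sigma = 1$ exactly, a property the tests exploit.
* Binarization ties are broken by (row, column) lexicographic order, so
  ensembles are bit-reproducible across platforms.
* The metric engine is compiled (Rcpp): cohort-scale runs evaluate
  millions of small graphs (subjects x 31 thresholds x randomizations),
  which is impractical in interpreted code. The test suite checks every
  metric exactly against brute-force oracles (Floyd–Warshall distances,
  exhaustive shortest-path enumeration for betweenness, triangle counting)
  on all 208 non-isomorphic graphs with up to 6 nodes, and against igraph
  on random graphs.

## Statistics policy

Group comparisons are normality-gated: if both groups pass Shapiro–Wilk at
$\alpha = 0.05$, a two-tailed Welch t-test is run on values residualized
against the supplied covariates (age, sex); otherwise a Mann–Whitney
rank-sum test is run on raw values with the Hodges–Lehmann shift estimate
and its distribution-free 95% CI. The nonparametric branch deliberately
performs no covariate adjustment — rank tests have no canonical covariate
mechanism, and inventing one would change the test's null distribution; the
branch taken is recorded in every result row. Region-wise comparisons are
Bonferroni-corrected at $0.05/26$ for cerebellar and $0.05/72$ for cortical
analyses. Non-normal features can be natural-log transformed (with a
recorded shift for non-positive features) before normal-theory analyses.
Bonferroni is the implemented correction; FDR is available as a
configuration option but carries no validation weight.

## The synthetic cohort generator

Real amyloid PET cohorts are access-controlled, so every stage is validated
on synthetic cohorts. Subjects are drawn from group-specific multivariate
normal distributions on the regional-SUVR scale: normality is the natural
choice because Pearson-correlation networks are exactly characterized under
it. Defaults emulate a four-group (CN/EMCI/LMCI/AD) cohort of
172/159/141/140 subjects over the 26 cerebellar regions:

* group mean cerebellar SUVR 0.55, 0.58, 0.60, 0.63 (CN to AD), with a
  fixed $\pm 0.05$ per-ROI offset profile;
* a single-factor base covariance (correlation of regions $i,j$ equal to
  $\ell_i \ell_j$ with loadings 0.35–0.8, per-ROI SD 0.10) — the one-factor
  structure mirrors the dominant global amyloid burden factor of real
  cohorts, and the parameters give a subject-level compartment-mean SD of
  about 0.06, matching the interquartile ranges the group summaries are
  calibrated against;
* demographics (age, sex, MMSE) drawn from group-specific distributions
  matching the cohort table; demographics are independent of SUVR by
  default, with an optional age slope so covariate-adjustment tests can
  have a nonzero ground truth.

What the generator does *not* emulate: site effects, partial-volume
residuals, non-Gaussian tails, or spatially structured noise. Passing tests
therefore certify the pipeline's statistical machinery, not its behavior on
any real cohort.

Connectivity ground truth is injected on the correlation scale:
`inject_edge_perturbation()` shifts chosen edges by a stated delta and
projects back to the PSD cone by eigenvalue clipping at $10^{-8}$, so the
injected quantity is exactly the quantity the perturbation Z-score is built
to detect. `roi_hyperconnectivity()` shifts every edge incident to chosen
target regions — regional hyper-connectivity, the disease signature the
region-wise analysis is designed to flag.

## Power analysis and the recovery validation

The add-one-subject Z-score on a single edge has, for a subject drawn from
a population whose edge correlation is shifted by $\delta$, a mean shift of
about $\delta/(1-r^2)$ against a per-subject SD near
$\sqrt{1+r^2}/(1-r^2)$: the per-edge effect size is bounded by roughly
$\delta/\sqrt{1+r^2} \le \delta$. At $\delta = 0.3$ and $n = 150$ per group
this caps any single-edge comparison near $d \approx 0.29$, and binarized
betweenness dilutes it further (measured $d \approx 0.1$–$0.2$): no
Bonferroni-corrected betweenness comparison can reach high sensitivity
under these conditions. The region statistic that retains the most signal
is the unbinarized *nodal strength* (row mean of Z), with measured
$d \approx 0.6$ under a moderate-covariance base. The recovery validation
therefore runs the region-wise Bonferroni pipeline on nodal strength
(`roi_wise_comparison(metric = "strength")`), with betweenness remaining
the default metric for the descriptive group analyses. The recovery study
conditions, fixed at design time: factor loadings 0.15–0.5, three target
regions with all incident edges shifted by +0.3, 150 subjects per group,
sensitivity over 50 cohorts and family-wise error over 200 null cohorts.

## Classification

Features are namespaced (`suvr.<roi>`, `global.<metric>`,
`nodal.<metric>.<roi>`; 26 + 8 + 130 = 164 columns for the cerebellar
template) and the positive class is always the later disease stage. The
pipeline per task: stratified 70/30 split; z-standardization fit on the
training split only; univariate filtering (the normality-gated two-group
test, default $\alpha = 0.05$ uncorrected); LASSO-penalized logistic
selection with lambda chosen by 5-fold cross-validated deviance; then six
classifier families (SVM, random forest, logistic regression, one-hidden-
layer MLP, gradient-boosted trees, k-NN) tuned by 5-fold CV AUC on the
training split. The reported model per task is chosen by cross-validated
AUC, never by test performance, and the test split is untouched until final
evaluation. Confidence intervals are stratified-bootstrap percentile
intervals (default 2000 resamples). Hyperparameter grids are deliberately
small, shipped in `default_tuning_grids()`, and fully user-overridable.

Attribution uses Monte-Carlo permutation-sampling Shapley values against a
single background vector (training-split medians): for each sampled feature
ordering, features flip one at a time from background to subject value and
the marginal prediction change is credited to the flipped feature. With one
background vector each permutation's credits sum exactly to prediction
minus baseline, so efficiency holds for the averages up to Monte-Carlo
noise, and for additive models the estimate is exact — both properties are
tested against closed forms.

## Numerical and degenerate-input choices

* Correlations saturated at $|r| = 1$ are clipped to $1 - 10^{-12}$ before
  the Z denominator, with a per-edge warning.
* Zero-variance ROIs are rejected by name when building reference networks.
* An all-negative Z matrix binarizes to empty graphs with a warning rather
  than an error.
* The global seed fans out to per-stage seeds through a documented
  derivation (`derive_seed`), so pipeline stages are independently
  reproducible and below the 32-bit integer ceiling.
* Validation problem sizes (50 recovery cohorts, 200 null cohorts, 2000
  calibration replicates, 8 ROIs / 12 subjects per group in the worked
  fixture) were chosen once so the full validation completes in minutes on
  one CPU.

## Known limitations

* The exact 26-region cerebellar and 72-region cortical label compositions
  at this granularity vary between published atlases; counts are enforced,
  the label sets are configurable (`default_selection_rules()`).
* The family-wise error of the region-wise pipeline is controlled at the
  Bonferroni level only as exactly as the per-test tails are exact; with
  rank tests at $n = 150$ the measured null FWER sits near the nominal
  0.05 within binomial tolerance.
* No partial-volume computation is performed; corrected and uncorrected
  SUVR tables are treated as separate inputs distinguished by a provenance
  flag, and reference networks are never mixed across them.
* Group-level partial-correlation networks (the population-level
  alternative construction) are out of scope; the implemented path is the
  individual-specific method.
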