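---
title: "From EV proteomes to diagnostic panels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EV proteomes to diagnostic panels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmarkers)
```

`evmarkers` takes label-free EV proteomic quantification tables through
candidate prioritization, marker-shape classification and diagnostic panel
selection. This vignette explains the statistical machinery, the defaults,
and the choices made where the design was genuinely open.

## The candidate funnel

The substrate is a protein × sample intensity matrix with per-sample
metadata: lineage (`FT` or `HGSOC`), source (`cell_line` or `tissue`),
a biological unit (cell line or explant) and a replicate index. A zero or
blank intensity means "not detected". The funnel runs a fixed stage order:

1. **Presence filtering.** Per biological unit, a protein must be detected
   in enough replicates: the default rules require at least 2 of 3
   replicates for HGSOC cell lines, and all replicates for FT cell lines
   and for tissue explants (`default_presence_rules()`). Detection is
   strictly `intensity > 0`.
2. **Per-group aggregation.** How per-cell-line sets combine into one
   lineage set is an open design point. The default is **union** — a
   protein robustly detected in any one cell line of a lineage counts —
   because requiring presence in every unit (intersection) is punitive
   under stochastic peptide sampling across runs and shrinks the group
   sets far below the thousands of proteins a typical EV run identifies.
   `combine = "intersection"` is available.
3. **Lineage consensus.** Tissue-explant set ∩ cell-line set, per lineage:
   keeps proteins attributable to the lineage's epithelium rather than to
   stroma or culture artifacts.
4. **Core proteome.** HGSOC consensus ∩ FT consensus: candidates present
   before and after transformation, i.e. lineage markers preserved in
   disease.
5. **Transmembrane intersection and common-EV subtraction.** Set
   intersection with a curated transmembrane list, then subtraction of the
   union of common-EV lists. Identifier matching is exact string equality
   after whitespace stripping; harmonizing accession versions or gene
   symbols is the caller's job.
6. **Fold-change filter.** Intensities are first normalized per sample to
   parts-per-million of the column total, because label-free totals differ
   per run. The log2 fold change is
   `log2((mean_HGSOC + c) / (mean_FT + c))` with pseudocount `c` set to
   half the smallest nonzero normalized intensity — symmetric, keeps
   presence/absence proteins finite, and preserves ordering. The default
   cutoff −0.58 (≈ 1.5-fold decrease) keeps proteins whose abundance is
   stable or rises from FT to HGSOC. Which samples feed the group means is
   not determined by the data model; the default pools tissue and
   cell-line samples per lineage (`fc_scope = "pooled"`), with tissue-only
   and cell-line-only as options. Ranking is by descending fold change
   with lexicographic tie-break for determinism.
7. **Manual exclusion** of literature-known common EV proteins, preserving
   rank order; requesting removal of an absent accession warns rather than
   errors.

Stage sets only shrink from the core stage onward; the tests assert this
monotonicity and full invariance to row order and duplicated annotation
lines. The IHC helper `h_score()` (0–300, intensity-weighted stained-area
sum) supports orthogonal tissue validation of funnel survivors.

## Smooth ROC and the curve-length statistic

For a marker scored in controls and cases, each group's density is
estimated with a Gaussian kernel. The bandwidth default is Silverman's
rule, `0.9·min(sd, IQR/1.34)·n^(−1/5)`, chosen per group independently; a
scalar override exists because no single bandwidth suits both a unimodal
control group and a bimodal case group equally well. The smooth ROC is the
curve `(1 − F̂(c), 1 − Ĝ(c))` over a shared grid of 512 thresholds spanning
the pooled data ± 4 bandwidths (leaving < 10⁻⁴ of kernel mass off-grid);
kernel CDFs are evaluated exactly as averaged normal CDFs rather than by
integrating the gridded density.

The **curve length** is computed in the threshold parametrization,
`L = ∫ √(f̂² + ĝ²) dc`, by trapezoid on the same grid; this equals the
polyline arc length of the smooth ROC to better than 10⁻³ (asserted in
tests). `L` ranges from √2 (identical distributions; diagonal ROC) to 2
(complete separation). A marker whose cases straddle the controls (e.g. a
symmetric bimodal mixture) has AUC ≈ 0.5 yet `L` well above √2: the length
recovers diagnostic signal the AUC cancels out.

Classification uses the length and the smooth-curve AUC together:

* **monotone**: `L ≥ 2 − 0.05` and (AUC > 0.8 or AUC < 0.2). A finite-sample
  KDE never attains 2 exactly, hence the tolerance 0.05 (configurable via
  `shape_thresholds()`). The two AUC arms cover markers strong in either
  direction.
* **non-monotone**: `L > 1.6` and 0.35 ≤ AUC ≤ 0.65.
* otherwise **neither**.

The AUC entering this rule is the smooth-ROC AUC, for internal consistency
with the length estimator; Table-style inference instead uses the
empirical AUC. Note the rule is calibrated for hundreds of observations per
group: at chip-cohort sizes (10 vs 20) even a strongly separating marker
smooths to `L ≈ 1.7–1.8` and classifies as `neither`, so shape
classification is intended for the proteomic screening stage, not the
small clinical cohort.

## Single-marker inference

The empirical ROC steps through all distinct observed scores with the
convention "score ≥ threshold calls a case"; its trapezoidal area equals
the Mann–Whitney statistic with ties counted ½ (verified against
brute-force pair counting on random instances). The AUC standard error is
DeLong's structural-components estimator, the CI is the normal
approximation clipped to [0, 1], and the one-tailed p-value tests
AUC = 0.5 against AUC > 0.5 via `z = (AUC − 0.5)/SE`. The original
single-marker analyses were run in a commercial package that does not name
its variance method; DeLong is the field standard and a bootstrap SE
(`method = "bootstrap"`) is provided for cross-checking. With perfect
separation the component variance is zero: the result is flagged
`degenerate`, the CI collapses, and the p-value is reported as the exact
permutation lower bound `1/choose(m+n, n)` rather than an unattainable 0.

Operating points are read off the empirical curve by default — at 10 cases
and 20 controls, attainable sensitivities are multiples of 1/10 and
specificities of 1/20, so a 99.8% specificity target is equivalent to
100% and smoothing would only obscure that granularity.
`sensitivity_at_specificity()` maximizes sensitivity subject to
specificity ≥ target (0 is a valid answer); `youden()` maximizes
J = sensitivity + specificity − 1, breaking ties toward the
higher-specificity threshold.

## Panel selection

Chip fluorescence spans decades, so scores are log-transformed before
modelling; the log base is not determined by the combination equation's
form and defaults to 10 (coefficients of order 10 then correspond to
decade-scale effects), configurable. Background subtraction (a
negative-control channel) is optional, with values floored at half the
smallest positive post-subtraction value so nothing maps to −∞.

`exhaustive_search()` fits a maximum-likelihood logistic regression (with
intercept, via `stats::glm`) for every marker subset of the requested sizes
(default 2 … m; size 1 by request; a guard refuses m > 20) and ranks by
AIC = 2k − 2·logL with lexicographic tie-break. At small n with strong
markers, ML logistic regression frequently hits complete or quasi-complete
separation; those fits are refit with a tiny ridge penalty (10⁻⁴ on
slopes, intercept unpenalised, Newton iterations) so every subset reports
finite coefficients and an AIC computed from the unpenalised log-likelihood
at the stabilised coefficients, and are flagged. The reported panel score
is the linear term only, `Σ βⱼ xⱼ` — ROC analysis is invariant to the
dropped intercept, and any deployment threshold absorbs it.

AIC is not a consistent selector: a pure-noise marker lowers the AIC of a
superset whenever its likelihood-ratio increment exceeds 2, which happens
with probability ≈ 0.16 per marker even asymptotically. Recovery of a
planted informative pair as *exactly* the best subset is therefore a
per-dataset event with substantial probability of one extra marker; what
holds deterministically is that the informative markers are contained in
the best subset and dominate all other subsets of their own size — the
test suite asserts these properties, plus exact recovery at one pinned
end-to-end simulation.

## Synthetic data and what it does (not) show

`simulate_proteome()` emulates the funnel substrate: a default design of
three HGSOC cell lines in triplicate, two FT cell lines in duplicate, and
three tissue-explant units per lineage in duplicate; log-normal intensities
(meanlog log(10⁶), sdlog 0.3, a typical LFQ dispersion); and planted
protein classes (core transmembrane keepers, fold-change failures at a
planted 4-fold HGSOC decrease vs a 2-fold increase for keepers, common-EV
members, non-transmembrane core, lineage-exclusive and absent proteins).
Planted classes are realized with presence probability 1 inside their
defining groups, so the expected count of every funnel stage is exact and
the funnel tests are deterministic bookkeeping, not statistics. The planted
fold-change margins (±1.4 log2 units from the cutoff) dominate both the
sampling noise of group means and the ppm-renormalization shift induced by
lineage-exclusive proteins.

`simulate_markers()` generates case/control scores on the log scale —
binormal with `delta = sqrt(2)·qnorm(target_auc)` (so the true AUC has a
closed form), perfectly separated (`delta = 10`), symmetric bimodal
(`½N(−δ,1) + ½N(δ,1)`, true AUC ½ by symmetry) and null shapes — then maps
them to a fluorescence-like scale `10^(3 + z/2)` with a log-normal
background channel, which `preprocess_scores()` inverts up to an affine
map. Generators draw through `withr::with_seed`, so they are bitwise
reproducible and never touch global RNG state.

None of this emulates real-data pathologies: inter-protein correlation,
batch effects across runs, heavy-tailed fluorescence noise, or imperfect
annotation lists. Green tests therefore certify the *algorithms'*
correctness and calibration, not field performance on deposited data.

## Numerical choices and limitations

* Grids: 512 points for KDE/ROC integration (configurable); trapezoid
  throughout; stochastic tests pin seeds.
* Ties: fold-change ranking and AIC ranking break ties lexicographically;
  Youden ties resolve to higher specificity.
* Degenerate inputs error early with instructive messages: zero-variance
  scores (KDE undefined under Silverman), single-class outcomes, all-zero
  sample columns, scope selectors matching nothing.
* Problem sizes in the test suite — n = 500–5000 per group for ROC
  calibration, n = 2000 for coefficient recovery, 120-model searches —
  were chosen as the smallest designs at which the analytic anchors
  (length 2 and √2, binormal AUC and Youden closed forms) are sharp.
* Not covered by design: differential-expression statistics, GO/network
  enrichment, covariate-adjusted or partial-AUC ROC methods,
  cross-validated panel assessment, and identifier mapping across
  annotation vocabularies.
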