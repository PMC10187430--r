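# evmarkers

High grade serous ovarian carcinoma (HGSOC) mostly arises from fallopian
tube (FT) secretory epithelium, and extracellular vesicles (EVs) shed by
both tissues carry surface proteins of their cell of origin into blood.
`evmarkers` is an R package for researchers mining label-free EV proteomics
for lineage-associated surface biomarkers and evaluating them as diagnostic
readouts on case/control cohorts. It covers three stages of that workflow:

1. **Candidate funnel** — turns a protein × sample intensity matrix into a
   ranked candidate list: presence filtering per biological-replicate set,
   tissue/cell-line lineage consensus, FT/HGSOC core-proteome intersection,
   restriction to annotated transmembrane proteins, subtraction of common
   EV proteins (ExoCarta/Vesiclepedia-style top-100 lists), a
   log2 fold-change filter (default cutoff −0.58) and manual exclusions.
2. **ROC-curve-length statistics** — smooths each group's scores with a
   Gaussian kernel density estimate (Silverman bandwidth) and traces the
   smooth ROC `(1 − F̂(c), 1 − Ĝ(c))`. Its arc length
   `L = ∫ √(f̂(c)² + ĝ(c)²) dc` is √2 for a useless marker and → 2 for a
   perfect one, and — unlike the AUC — detects *non-monotone* markers whose
   case scores straddle the controls. Markers are classified **monotone**
   (L ≥ 2 − 0.05 and AUC > 0.8 or < 0.2) or **non-monotone** (L > 1.6 and
   0.35 ≤ AUC ≤ 0.65). Single-marker inference uses the empirical
   (Mann–Whitney) AUC with DeLong standard errors, sensitivity at 99.8%
   specificity, specificity at 95% sensitivity, and the Youden index
   J = sensitivity + specificity − 1.
3. **Panel selection** — exhaustive logistic-regression subset search over
   marker combinations (2 markers, 3 markers, …, all markers), ranked by
   AIC = 2k − 2·logL, with the best model's linear term
   `Σ βⱼ·log(markerⱼ)` extracted as the combined score (intercept omitted;
   thresholds absorb it).

A seeded synthetic-data module generates every input format with
machine-readable ground truth, so the full pipeline runs and is testable
entirely offline.

## Worked example

Simulate a chip-style cohort (10 HGSOC cases, 20 healthy controls, seven
markers with realistic per-marker AUCs), then run single-marker and panel
analysis:

```r
library(evmarkers)

fix <- make_fixture(tempfile("ev"), "markers_paperlike", seed = 42)
scores <- read_score_table(fix["scores"])
scores
#> Marker score table: 30 subjects (10 case / 20 control), 7 markers

g <- marker_groups(scores, "ITGA5")
marker_report(log10(g$controls), log10(g$cases))$auc
#> AUC 0.935 (SE 0.043, 95% CI 0.850-1.000, one-tailed p 3.12e-24)

pre <- preprocess_scores(scores, log_base = 10)
search <- exhaustive_search(pre, subset_sizes = 2:7)
search
#> Exhaustive panel search: 120 models
#>   AIC    6.013  {ITGA2, ITGB3}
#>   AIC    6.014  {ITGB3, FOLR1}
#>   AIC    6.022  {ITGA5, ITGB3}
#>   AIC    6.031  {IGSF8, ITGB3}
#>   AIC    6.036  {ITGB3, MYOF}

panel_equation(search$best)
#> [1] "8.309 x log(ITGA2) + 18.232 x log(ITGB3)"

evaluate_panel(search$best, pre)$auc
#> AUC 1.000 (SE 0.000, 95% CI 1.000-1.000, one-tailed p 3.33e-08, degenerate SE)
```

The single ITGA5 channel separates cases from controls with AUC 0.935; the
AIC-best two-marker combination separates the cohort perfectly (at n = 30
the logistic fit hits separation, is ridge-stabilised and flagged, and the
DeLong SE degenerates to 0 — the reported p-value is then the exact
permutation lower bound). The linear-combination string has the same form
as a fitted two-marker panel score, e.g.
`11.299 x log(IGSF8) + 14.935 x log(ITGA5)`.

The same analyses are scriptable from a shell via the thin CLI:

```sh
Rscript exec/evmarkers simulate --preset funnel_small --seed 1 --out fix/
Rscript exec/evmarkers funnel --matrix fix/quant_matrix.tsv --meta fix/sample_meta.tsv \
    --tm-list fix/transmembrane.txt --common-ev fix/common_ev_top100.txt --out funnel.json
Rscript exec/evmarkers roc --scores scores.csv --all --shape --out roc.json
Rscript exec/evmarkers panel --scores scores.csv --sizes 2..7 --out panel.json
```

See `vignette("ev-biomarker-pipeline")` for the model details, parameter
defaults and design choices.

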