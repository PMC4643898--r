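# sepsimet

Urine ¹H-NMR metabolomic prognosis of 30-day mortality in severe sepsis
and septic shock, as one reproducible R workflow: a synthetic septic-cohort
generator, spectral preprocessing, metabolite quantification, chemometrics
(PCA / PLS-DA with cross-validation and permutation testing), and a
logistic metabolomic mortality score compared against the SOFA clinical
severity score by ROC analysis.

## The problem and the model

ICU patients with severe sepsis face high early mortality, and clinical
scores such as SOFA (Sequential Organ Failure Assessment) capture organ
dysfunction but not metabolic state. A single one-dimensional ¹H-NMR
spectrum of urine quantifies dozens of metabolites non-invasively. The
workflow here models a two-collection design (ICU admission "0h" and
"24h") for 60 subjects (48 survivors, 12 non-survivors):

1. **Spectra → features.** TSP referencing, integration into 0.005 ppm
   buckets over 0.5–10 ppm (1900 buckets), and normalization by the total
   aliphatic area (0.5–4.4 ppm), which cancels urine dilution exactly.
2. **Panel quantification.** Eight metabolites with planted prognostic
   signal — ethanol, glucose, hippurate and an unassigned 1.42 ppm singlet
   raised in non-survivors; methionine, glutamine, arginine and
   phenylalanine lowered — measured as dilution-invariant region integrals
   (a Levenberg–Marquardt Lorentzian line fitter is available for
   overlapped regions), screened by one-way ANOVA with FDR adjustment.
3. **Chemometrics.** PCA outlier screening (Hotelling T² + Q residual at
   95%), NIPALS PLS-DA with the component count chosen by leave-one-out
   RMSECV, Q² and a permutation overfit test.
4. **Prognosis.** A ridge-stabilised logistic score on the 16 panel
   measurements (both collections), evaluated strictly out-of-fold and
   compared to a SOFA-based score via Mann–Whitney AUC with stratified
   bootstrap CIs and a paired bootstrap test of the AUC difference.

Since no patient spectra of this design are deposited publicly, all data
are synthetic, produced by a generator with realistic nuisance structure
(log-normal dilution, chemical-shift jitter, baseline drift, residual
water, noise) and seeded end to end. `vignettes/methods.Rmd` documents
every model and parameter choice.

## Worked example

```r
library(sepsimet)

cohort  <- simulate_cohort(n_survivor = 16, n_nonsurvivor = 8, seed = 7)
spectra <- simulate_cohort_spectra(cohort, seed = 7)

c0 <- cohort[cohort$timepoint == "0h", ]
panel0 <- cohort_panel(lapply(spectra[c0$sample_id], reference_to_tsp))
anova_screen(panel0[-1], c0$outcome)[, c("metabolite", "direction",
                                         "F", "p", "p_adj")]
#>      metabolite direction     F        p   p_adj
#> 1       ethanol         1 10.08 0.004386 0.00702
#> 2       glucose         1  7.24 0.013339 0.01334
#> 3     hippurate         1  7.84 0.010451 0.01334
#> 4  unknown_1.42         1 19.68 0.000208 0.00059
#> 5    methionine        -1 21.71 0.000120 0.00059
#> 6     glutamine        -1  7.31 0.012994 0.01334
#> 7      arginine        -1 18.43 0.000295 0.00059
#> 8 phenylalanine        -1 19.16 0.000240 0.00059

c24 <- cohort[cohort$timepoint == "24h", ]
panel24 <- cohort_panel(lapply(spectra[c24$sample_id], reference_to_tsp))
y <- as.numeric(c0$outcome == "non-survivor")

met  <- cv_metabolomic_score(panel0, panel24, y)      # out-of-fold probs
sofa <- cv_sofa_score(c0$SOFA_0h, c0$SOFA_24h, y)
roc_curve(met, y)
#> <roc_result: AUC 1.000 (95% CI 1.000-1.000), Mann-Whitney AUC, ...>
roc_curve(sofa, y)
#> <roc_result: AUC 0.672 (95% CI 0.422-0.898), Mann-Whitney AUC, ...>
```

All eight planted effect directions are recovered, and the metabolomic
score outperforms SOFA out-of-fold — the qualitative result the full
workflow reproduces at scale.

## The full analysis workflow

The numbered scripts under `analysis/` regenerate every table in
`results/` from scratch (seed via `SEPSIMET_SEED`, default 1):

```sh
Rscript analysis/01_simulate.R      # cohort + 120 spectra + Table 1
Rscript analysis/02_preprocess.R    # normalized 1900-bucket matrices
Rscript analysis/03_quantify.R      # metabolite panels + ANOVA screens
Rscript analysis/04_chemometrics.R  # PCA outliers, PLS-DA + validation
Rscript analysis/05_prognosis.R     # metabolomic vs SOFA ROC comparison
Rscript analysis/06_report.R        # plain-text summary
```

At seed 1 the report reads:

```
PLS-DA spectral models (outliers excluded, out-of-fold metrics):
  0h:  A=3  R2Y=0.47  Q2_press=0.14  Q2_corr=0.19  RMSECV=0.37  cvAUC=0.84  perm p=0.0149
  24h: A=3  R2Y=0.38  Q2_press=0.14  Q2_corr=0.21  RMSECV=0.37  cvAUC=0.82  perm p=0.0100
ANOVA screen at 0h: 7/8 metabolites at BH-adjusted p < 0.05
Prognostic scores (leave-one-out cross-validated):
  metabolomic AUC 0.998 vs SOFA AUC 0.899
  difference 0.099 (95% CI 0.012 to 0.240, p=0.0050); metabolomic permutation p=0.0050
```

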