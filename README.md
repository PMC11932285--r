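# urinmr

Biomarker discovery from 1D ¹H-NMR urine spectra in small two-group
occupational-exposure studies (exposed workers vs healthy controls).

The package implements the complete analysis chain used in NMR urinary
metabolomics pilot studies:

1. **Internal-standard quantification.** Processed spectra (ppm, intensity)
   are converted to molar metabolite concentrations against the TSP
   reference (9 equivalent protons at 0 ppm, 1.82 mM in the tube) and then
   normalized to creatinine quantified from its 4.05 ppm singlet:

   ```
   conc_m  = (I_m / n_m) / (I_TSP / 9) × 1.82 mM
   out_m   = 1000 × conc_m / conc_creatinine        [µmol/mmol creatinine]
   ```

   where `I_m` is the trapezoidal integral of metabolite *m*'s overlap-free
   window and `n_m` the number of protons generating the signal.

2. **Chemometrics.** Autoscaling, PCA, and a two-class PLS-DA classifier
   (PLS1/NIPALS, class coding +1 = Exposed, −1 = CTRL) validated by
   *repeated double cross-validation* (default 20 repetitions × 5
   stratified outer folds; 5 inner folds pick the number of latent
   variables by minimum misclassification). Figures of merit —
   sensitivity, specificity, accuracy, percentage of correct
   classification — are reported as mean ± sd over repetitions.

3. **Stability-based variable selection.** A metabolite is significant for
   the discrimination when its weight on the first canonical variate (the
   unit-normalized PLS-DA coefficient vector) keeps one sign in *every*
   outer-fold model and its 95% percentile confidence interval excludes
   zero; the sign assigns it to the group it marks.

4. **Univariate branch.** Each metabolite is routed by Shapiro–Wilk
   normality and Levene homoscedasticity checks to either an
   equal-variance Student's *t* test or a Wilcoxon rank-sum test,
   two-sided at the 95% confidence level, with Benjamini–Hochberg adjusted
   p-values reported alongside.

5. **Synthetic data.** A generator emulates the study design end to end:
   12 exposed vs 13 control subjects, 46 named urinary metabolites plus 4
   unknowns with log-normal concentration noise, the reported
   direction-of-change pattern (22 metabolites lower and 6 higher in
   workers, furoylglycine ×4), and Lorentzian urine-like spectra with the
   TSP and creatinine reference singlets — so every stage is testable with
   known ground truth and no external data.

## Worked example

```r
library(urinmr)

m <- simulate_concentrations(sim_config(seed = 1))   # 25 × 50 table
res <- double_cross_validate(m, config = dcv_config(seed = 2))
res
#> <dcv_result> 20 repetition(s) x 5 outer fold(s), n = 25
#>   sensitivity      100.0 +/- 0.0 %
#>   specificity      100.0 +/- 0.0 %
#>   accuracy         100.0 +/- 0.0 %
#>   percent_correct  100.0 +/- 0.0 %

sel <- select_significant_variables(res)
subset(sel, selected)[1:5, ]
#>   variable median_weight  ci_lo   ci_hi sign_consistency selected group
#> 1      Leu       -0.1994 -0.222 -0.1783                1     TRUE  CTRL
#> 2      Val       -0.1842 -0.224 -0.1623                1     TRUE  CTRL
#> 3      Ile       -0.1845 -0.210 -0.1598                1     TRUE  CTRL
#> 4   3-HIBA       -0.1914 -0.223 -0.1645                1     TRUE  CTRL
#> 5  Lactate       -0.0865 -0.147 -0.0316                1     TRUE  CTRL

uni <- run_univariate(m)
subset(uni, metabolite == "Furoylglycine")
#>       metabolite test_used statistic  p_value     direction significant ...
#> 37 Furoylglycine  wilcoxon       156 2.49e-05 up_in_exposed        TRUE
```

The DCV figures say the nested-validation classifier separates the two
simulated groups perfectly; the selection report lists metabolites whose
discriminant weight is sign-stable across all 100 cross-validation models
(negative = higher in controls, e.g. the branched-chain amino acids);
the univariate row confirms the injected four-fold furoylglycine increase
in the exposed group (Wilcoxon, p ≈ 2×10⁻⁵).

The full pipeline (simulate → write spectra → quantify → analyze →
univariate) is driven by `run_pipeline()` or from a shell via
`inst/scripts/run_pipeline.R` with a YAML configuration; every run writes
a manifest that makes reruns byte-identical.

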