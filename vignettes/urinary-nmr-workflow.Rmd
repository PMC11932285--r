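---
title: "Methods: internal-standard NMR quantification, double cross-validated PLS-DA and routed univariate testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: internal-standard NMR quantification, double cross-validated PLS-DA and routed univariate testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinmr)
```

## The problem

Occupational-exposure metabolomics asks whether the urinary metabolic
profile of a small group of exposed workers differs systematically from
matched controls, and which metabolites carry the difference. `urinmr`
implements that chain for 1D ¹H-NMR urine data: absolute quantification
against an internal standard, a cross-validated multivariate classifier
with stability-based variable selection, and a distribution-checked
univariate branch. Because cohorts of this kind are small (here 12 exposed
vs 13 controls) and rarely public, the package ships a synthetic generator
that reproduces the design's statistical structure with known ground
truth; everything downstream is exercised against it.

## Quantification model

Spectra are assumed phased and baseline-corrected. Each quantifiable
metabolite is represented by one overlap-free resonance: a half-open
integration window $[lo, hi)$ in ppm and the proton count $n_m$ of the
signal. With $I_m$ the trapezoidal integral over the window,

$$\mathrm{conc}_m = \frac{I_m / n_m}{I_{\mathrm{TSP}} / 9}\;
  c_{\mathrm{TSP}}, \qquad c_{\mathrm{TSP}} = 1.82\ \mathrm{mM},$$

i.e. per-proton integrals are compared with the per-proton integral of the
TSP internal standard. Concentrations are then divided by the creatinine
concentration — itself quantified from the 4.05 ppm creatinine singlet by
the same formula — and reported as µmol/mmol creatinine
($1000 \times \mathrm{mM} / \mathrm{mM}$), which controls for urine
dilution. Quantifying creatinine through the same TSP chain (rather than
taking it as external input) keeps the whole table internally consistent;
it also makes every reported number invariant to global intensity scaling
of a spectrum, since the reference integral cancels.

Numerical choices:

* **Windows are half-open** `[lo, hi)` so adjacent windows can share an
  endpoint without double-counting.
* **Integration** is the trapezoidal rule on the native grid, with the
  intensities at the exact window bounds obtained by linear
  interpolation. A constant intensity $c$ over a window of width $w$
  therefore integrates to exactly $cw$ regardless of grid alignment.
* **No baseline subtraction** inside windows: spectra are declared
  baseline-corrected upstream, and raw-FID processing is out of scope.
* **Negative integrals** (possible on noisy baselines) are clamped to
  zero with a warning rather than propagating negative concentrations.
* The TSP window width and position are configuration, not constants:
  real spectra may need wider windows or ¹³C-satellite exclusion, which
  the library abstraction accommodates.

## The synthetic generator

`simulate_concentrations()` draws each subject's metabolite vector
log-normally around per-metabolite control medians: concentrations are
strictly positive and their noise multiplicative, which matches urinary
concentration data far better than additive Gaussian noise. The default
log-scale standard deviation is 0.3 (a geometric CV of ~35%, typical of
between-subject spread in creatinine-normalized urinary metabolites).
Group effects multiply the exposed-group median by $2^{\mathrm{log_2 FC}}$.

The default effect pattern mirrors the emulated study: 22 metabolites
lower in workers (the branched-chain amino acids and their catabolites,
several microbially derived acids, and others) and 6 higher (pyroglutamate,
glutamine, glycine, furoylglycine, trigonelline and the unknown compound
U03), with furoylglycine — the candidate exposure marker — four-fold
higher (log₂ FC = +2). Magnitudes other than furoylglycine's are not
published as numbers; the default |log₂ FC| = 0.65 corresponds to about
1.5 pooled standard deviations on the log scale at the default noise,
chosen a priori so that a single such metabolite is detectable with ~95%
power by a two-sample *t* test at these group sizes — large but realistic
for reported effects in exposure studies. Unknown compounds are simulated
identically to named metabolites.

`synthesize_spectrum()` renders a concentration vector as a sum of
Lorentzian multiplets on a common ppm grid: each signal's window integral
is proportional to concentration × proton count, with the TSP and
creatinine singlets added at their configured concentrations so the
quantification chain closes exactly. Multiplet line intensities follow the
binomial (Pascal's triangle) pattern with a 0.012 ppm line spacing (~7 Hz
at 600 MHz); most library entries are singlets or doublets so multiplets
stay well inside their windows.

Three resolution choices matter and are deliberate:

* **Line width.** The default Lorentzian HWHM is 1e-4 ppm — idealized
  narrow lines, sharper than a typical experimental urine spectrum. The
  generator's purpose is ground-truth fidelity of window integrals, and
  Lorentzian tails are the one mechanism that breaks it: a tail of a large
  neighbour leaking into a small metabolite's window biases its apparent
  concentration. At the default geometry (0.04 ppm windows, ≥ 0.09 ppm
  between window centers) the worst-case leakage bias stays well below the
  1% round-trip tolerance the test suite enforces per metabolite.
* **Tail truncation.** Lorentzian tails are cut 0.25 ppm from each line
  center, emulating the locally flat baseline of well-corrected processed
  spectra; the truncated fraction is identical for every signal at equal
  window geometry and cancels in the TSP ratio.
* **Grid.** The default grid (−0.5 to 10 ppm, 5e-5 ppm spacing) puts every
  default window center on a grid point, so all singlets are sampled in
  the same phase relative to their centers and discretization error
  cancels between analyte and reference. This is why the
  internal-standard identity (a 2-proton singlet at 2/9 of the TSP
  integral quantifying to exactly 1.82 mM) holds to machine precision.

What the generator does **not** emulate: peak overlap (windows are
disjoint by construction, mirroring the upstream choice to quantify only
overlap-free signals), phase and baseline artifacts, the water/urea
region, chemical-shift drift with pH and ionic strength, and any
correlation structure between metabolites beyond the group effects.
Passing tests therefore demonstrate the correctness of the computational
chain, not robustness to those experimental nuisances. The library's
chemical-shift windows are fixture constants in the style of literature
urine assignments, nudged where necessary to guarantee disjointness; they
are not measured values.

## Chemometrics

All multivariate work is done after **autoscaling** (per-variable
mean-centring and unit-variance scaling), the standard choice when
concentrations span orders of magnitude and every metabolite should enter
with equal a-priori weight. The scaler is an explicit fit/transform pair:
test data are always scaled with training statistics.

**PCA** (used for unsupervised inspection) is a thin wrapper around the
singular value decomposition: scores, loadings and explained-variance
fractions over $\min(n-1, p)$ components.

**PLS-DA** fits PLS1 regression of the class code (+1 = Exposed,
−1 = CTRL, mean-centred) on the scaled matrix with the NIPALS algorithm.
For two classes the discriminant subspace is one-dimensional; we take as
the "weights on the first canonical variate" the regression coefficient
vector $b = W (P'W)^{-1} q$ at the chosen complexity, normalized to unit
length, with sign fixed so the exposed-class training centroid projects
positive. The coefficient vector is the canonical representative of the
discriminant direction because it is what actually maps a spectrum's
variables to the predicted class score; the first weight vector $w_1
\propto X'y$ is available as an alternative convention (they coincide for
one latent variable). Classification thresholds the continuous prediction
at 0, with exact ties deterministically assigned to the exposed class.

**Repeated double cross-validation.** Model complexity (number of latent
variables) and performance must not be estimated on the same data at
n = 25. The outer loop (default 5 stratified folds) holds subjects out;
inside each outer-training set an inner loop (default 5 stratified folds)
picks the number of latent variables (1..5) minimizing the mean inner
misclassification rate, ties going to the smaller model. The model is
refit on the full outer-training set — autoscaling refit there too, so
held-out subjects never touch the scaling statistics — and applied to the
untouched fold. The whole scheme is repeated (default 20 times) with
reshuffled folds. Per repetition the pooled outer predictions give
sensitivity (true-exposed rate), specificity (true-control rate), accuracy
(pooled fraction correct) and percentage of correct classification (the
class-balanced mean of sensitivity and specificity; with 12/13 subjects
the two differ by little). Repetition and fold counts are not dictated by
the emulated study (which does not report them); 20 × 5 × 5 is standard
practice and every knob sits in `dcv_config()`. A `global_scaling` flag
reproduces the single-block convention of autoscaling once before
splitting, for comparison with analyses that did so.

All randomness flows from one master seed through deterministic
per-repetition streams: identical input and configuration give
bit-identical results.

**Variable selection.** Every outer-fold model contributes one CV1 weight
vector (100 samples at the defaults). A variable is selected when (i) its
weight has the same strict sign in every sample and (ii) the percentile
confidence interval (default 95%) of its weights excludes zero; its sign
assigns it to the class it marks. The percentile interval was chosen
because the weight samples are an empirical distribution over
cross-validation models, with no distributional form to justify a
parametric interval.

A limitation worth stating plainly: the weight samples come from models
trained on 80% subsets of the *same* 25 subjects, so they are strongly
correlated, and the rule cannot distinguish a genuine effect from a null
variable whose chance correlation with the labels happens to be large in
this particular cohort (at n = 25 the standard deviation of a null
correlation is ≈ 0.2, so a few of 50 variables will exceed |r| ≈ 0.35 by
chance). In the package's recovery simulation the rule finds essentially
all injected effects but also admits a handful of such null variables per
dataset — about five on average at the default geometry. Sign-stability
selection should therefore be read as ranking evidence for discussion,
not as an error-controlled significance procedure; the univariate branch
with its calibrated type-I error is the complementary guard.

## Univariate branch

For each metabolite the two groups are first checked for normality
(Shapiro–Wilk per group) and homoscedasticity (Levene's test,
median-centred, i.e. Brown–Forsythe) at α = 0.05; only when both groups
look normal *and* the variances homogeneous is the equal-variance
Student's *t* test used, otherwise the Wilcoxon rank-sum test. P-values
are two-sided; significance is declared at the 95% confidence level. The
Wilcoxon branch uses the exact distribution when both groups have n ≤ 10
and no ties, and the tie-corrected normal approximation with continuity
correction otherwise (the relevant case at 12/13). Identical constant
groups make either test undefined and return a flagged result with p = 1.
Degenerate one-sided constants route to Wilcoxon. No multiple-testing
correction is applied to the significance flag (matching common practice
in pilot studies of this size), but Benjamini–Hochberg adjusted p-values
are always emitted alongside.

Two arithmetic consequences of the routing design are worth knowing: the
probability of taking the *t* route under ideal Gaussian conditions is
about $0.95^3 \approx 0.86$, not 1, because three assumption tests gate
it; and the overall procedure stays calibrated near the nominal 5% type-I
error under the null regardless of the route taken — the property the
acceptance suite measures on 2000 null variables.

## Pipeline

`run_pipeline()` chains simulate → quantify → analyze → univariate under a
single master seed and writes the concentration matrix (CSV), the DCV
summary (JSON), the selection and univariate reports (CSV) and a run
manifest (YAML) that echoes the configuration; reruns are byte-identical.
Configurations can come from a YAML file (`read_pipeline_config()`), where
unknown keys fail validation before any stage runs; a thin Rscript wrapper
(`inst/scripts/run_pipeline.R`) exposes the same entry points from a
shell.

## Problem sizes used by the test suite

The suite exercises the full study geometry — 25 subjects × 50
metabolites, 20 × 5 × 5 double CV, full-resolution spectra for one cohort
— and scales Monte-Carlo checks to sizes that make their tolerances
meaningful: 2000 null variables for the type-I calibration, 10 simulated
cohorts for the recovery study, 120–400 replicates for routing and power
bands. Stochastic assertions use fixed seeds and tolerance bands derived
from the corresponding binomial or Monte-Carlo standard errors.

## Known limitations

* The selection rule's false-positive behaviour at small n, discussed
  above.
* Only two-class PLS-DA; no orthogonal-PLS variants or whole-model
  permutation p-values.
* No peak deconvolution: a metabolite without an overlap-free resonance
  cannot be quantified by this design.
* The JCAMP-DX hook for real spectra is limited to the two-column text
  reader; instrument-specific formats must be exported upstream.
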