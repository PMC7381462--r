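---
title: "Methods: lipid panels for clinical lipoprotein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid panels for clinical lipoprotein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `lipidpanelr`, the
assumptions of its synthetic-data generator, the tunable parameters, and
the numerical decisions taken where the procedure left genuine freedom.

## The analysis pipeline

The package addresses a common translational question in lipidomics: a
panel of lipid species discovered in plasma profiles should predict a
clinical lipoprotein (TriG, HDL, LDL, TC; all mmol/L), and the same panel
— restricted to lipids actually measurable there — should be retrainable
in a second matrix such as dried blood spots.

The stages, in order:

1. **Matching** (`match_spectrum()`): each lipid target is assigned the
   centroid with smallest |ppm deviation| within ±`window_ppm`. The
   default window of 10 ppm is twice the downstream 5 ppm mean-deviation
   filter: lipids drifting between 5 and 10 ppm are *observed and then
   filtered*, rather than silently unmatched. Equidistant candidates go to
   the more intense peak — a deterministic tie-break. Unmatched targets
   are encoded as intensity 0 with an absent deviation, so they feed the
   zero-fraction filter naturally and never drag the mean deviation.
2. **QC filtering** (`qc_filters`): four strict-inequality filters (mean
   |deviation| > 5 ppm; sample/blank mean ratio < 5; zero fraction > 10%;
   dilution-series Pearson r < 0.9), in that order. The mean deviation
   uses |deviation| by default — a signed mean of +8/−8 ppm would look
   perfect while the instrument is badly off — with a `use_signed` switch.
   The dilution-series r is computed over all QC replicates (levels ×
   replicates points), not level means, to avoid degenerate three-point
   fits; a zero-variance (flat) lipid has undefined r and fails the
   filter, since a flat signal cannot show a linear increase with serum
   concentration. Blank intensities are aggregated by arithmetic mean.
3. **Normalisation**: TIC normalisation divides each sample by its total
   over the *retained* lipids (normalisation follows filtering in the
   processing order; a switch to the pre-filter total would require
   carrying removed columns and is intentionally not the default), then
   per-cohort mean centering. Cohorts are always centered independently.
4. **Panel discovery** (`discover_panel()`): 70:30 split (sizes
   `round(0.7 n)` vs rest), all-lipid random forest on the training split
   (500 trees, `mtry = p/3`, permutation importance `%IncMSE` — the
   classic regression defaults), forward growth along the importance
   ranking until the k-lipid model's held-out r is within Δr = 0.01 of
   the all-lipid model's. "Performs as well as" is unquantified in common
   usage; an absolute Δr of 0.01 is small against seed-to-seed noise in
   RF test correlations and is exposed as `tolerance`. Candidate models
   are compared on the held-out test set, matching the reported workflow
   of the two-stage procedure; a leakage-safe variant is available by
   passing an inner validation split as the "test" arguments of
   `grow_panel()` — statistically preferable, but it changes what the
   reported test r means, so it is not the default.
5. **Validation** (`translate_panel()`, `validate_in_cohort()`): the
   panel's lipid *names* are intersected with the target cohort's lipid
   space; the model is retrained from scratch on the target training
   split. Trees are never transported; a clearly-labelled
   `transport = TRUE` mode exists for comparison and requires the full
   source panel to be measurable.
6. **Univariate GLMs** (`glm_per_lipid()`): one Gaussian GLM (intercept +
   lipid) per lipid on the whole cohort, no split. For a single Gaussian
   predictor the GLM p-value equals the Pearson-correlation t-test
   p-value; the suite asserts this numerically. The Bonferroni threshold
   is α/n with n the cohort's retained lipid count by default — a fixed
   external count (such as 125) can be supplied to reproduce a printed
   threshold whose lipid count does not match either cohort's.
7. **Stratification** (`assign_clinical()`, `assign_quartiles()`,
   `overlap_table()`, `chance_baseline()`): three-band clinical cut-offs
   with boundary values assigned to the Borderline band (the outer bounds
   are printed as strict inequalities); HDL runs in the protective
   direction. One published cut-off table garbles the HDL Poor bound
   ("< 1.2.2"); 1.1 mmol/L is used, consistent with the adjacent
   Borderline band, and is configurable. Quartiles are assigned by
   average rank with a stable original-order tie-break, keeping group
   sizes within one of each other; >10% ties triggers a warning. Overlap
   denominators are conditioned on the *measured* category — that choice
   reproduces the equal-denominator arithmetic of quartile tables and is
   recorded in every report. The chance baseline permutes predicted
   labels against fixed measured labels; for balanced quartiles it
   converges to 25%.

## The synthetic-data generator

### Clinical tables

TriG is right-skewed and is drawn lognormal, moment-matched to the
requested mean/SD. HDL and a latent "pre-mix" total cholesterol are
truncated normals. LDL is then *derived* by the Friedewald formula
`LDL = TC_premix − HDL − TriG/2.2`, and the reported TC column is
`HDL + LDL` by default (`tc_mode = "hdl_plus_ldl"`), mirroring cohort
descriptions in which TC is recorded as the sum of the two fractions.
These two conventions are mutually inconsistent — the sum omits the
TriG/2.2 term, so under the default the reported TC mean sits about
0.7 mmol/L below the latent input (5.14 vs 5.83 under the plasma-like
defaults) — which is why the `premix` switch exists to restore standard
clinical semantics. Draws yielding non-positive LDL are rejected and
redrawn (warning above 5%, hard error after 50 rounds).

Because TriG, HDL and TC_premix are drawn independently, the derived LDL
standard deviation (~1.25 mmol/L under the plasma-like defaults) exceeds
the ~1.0 typical of adult cohorts, where the three inputs are positively
correlated. The LDL *mean* (3.62 mmol/L) is unaffected. Modelling the
full covariance was judged not worth the extra parameters; z-scores used
for planting associations are standardised per cohort, so the
inflation does not propagate into effect calibration.

### Spectra and the intensity model

Each subject spectrum carries one centroid per detectable lipid — no
isotopes, adducts or in-source fragments. For subject *i*, lipid *j*:

    x_ij = b_j * max(0.01, 1 + c_bio (sqrt(f_j) z_i + sqrt(1 - f_j) e_ij)) * eta_ij

with lipid baselines `b_j ~ logNormal(log 1e5, 1)`, biological scale
`c_bio = 0.3`, `z_i` the subject's standardised concentration of the
lipid's associated lipoprotein, `f_j` the planted variance fraction
(0 for unassociated lipids), `e_ij` unit Gaussian, and `eta_ij`
mean-one lognormal measurement noise with CV `noise_cv = 0.1`. This is
the simplest model in which both the random-forest and GLM stages have
recoverable signal: noise-free, `cor(x_ij, lipoprotein) = sqrt(f_j)`
exactly, which the test suite verifies at n = 800. Peaks move by
Normal(0, 2) ppm and drop out with probability 0.02.

QC spectra model pooled serum: baseline × serum fraction × measurement
noise, with no biological term, so the dilution series is exactly
proportional at zero noise. Blanks contain off-target contaminant peaks
(kept > 100 ppm from every target) plus designated "blank-fail" lipids at
1/3 of their sample baseline — inside the < 5× removal zone. Further
designated subsets get 8 ppm mean mass error, 30% missingness, or an
inverted dilution response, so each of the four filters has guaranteed
positive and negative cases; these planted failures sit *on top of* the
clean detectable sets, so post-QC lipid counts equal the configured
detectable counts (163 plasma-like, 118 DBS-like, 71% shared).

### Calibration of planted effects

For a panel of k lipids sharing the lipoprotein factor at equal variance
fraction f, the optimally combined panel correlates with the lipoprotein

    r_panel = sqrt( f / (f + (1 - f)/k) )   =>   f = r^2 / (k (1 - r^2) + r^2)

The default effects invert this at published panel accuracies —
(k, r) = (12, 0.914) TriG, (11, 0.748) HDL, (10, 0.556) LDL,
(11, 0.424) TC — giving mean f of 0.297, 0.104, 0.043, 0.020 and
reproducing the TriG > HDL > LDL ≈ TC ordering. The closed form
describes noise-free abundances, but the default chain (measurement
noise, missingness, TIC compositional coupling) attenuates realised
per-lipid correlations by a measured factor of ≈ 0.76; default effects
are therefore inflated by 1/0.76² so the *processed-matrix* correlations
land on the calibrated targets. Under these defaults, n = 777 discovery
runs yield all-lipid test correlations of ~0.88–0.93 for TriG and grown
panels of 8–9 lipids. Panel size is the least stable recovered quantity:
the stopping rule compares two noisy test-set correlations, so ±2 lipids
of seed-to-seed variation is expected.

Cross-cohort attenuation multiplies validation-cohort effect sizes by
`attenuation²`, so planted *correlations* scale linearly with the factor
(default 0.8); 0 removes transferable signal entirely. `panel_dropout`
removes named lipids from the validation cohort's measurable set,
emulating panel members undetectable in dried blood spots (default: the
two last planted TriG lipids).

### What the generator does not emulate

Plate-to-plate batch variance, isotope/adduct structure, ionisation
suppression, storage-time chemistry, and the covariance of clinical
lipids noted above. Passing tests therefore demonstrate that the
*pipeline* recovers structure it is designed to detect under a clean
generative model — not that it would perform identically on real DIMS
data, where matrix effects and batch structure add error modes the QC
filters only partially address.

## Numerical choices and degenerate inputs

- All four filter thresholds are strict inequalities; values exactly at a
  threshold are retained.
- A lipid never matched in any sample is removed at the mass-deviation
  filter and reported distinctly, as is a lipid with undefined dilution r.
- A lipid absent from blanks (blank mean 0) has infinite ratio and is
  retained; an all-zero sample aborts TIC normalisation with the sample
  named.
- Pearson p-values use `t = r sqrt(n-2)/sqrt(1-r^2)` on n−2 df,
  two-sided; |r| = 1 maps to p = 0; zero-variance predictions yield an
  absent correlation with a warning rather than an error.
- Every stochastic step (generation, splits, forests, permutations) takes
  an explicit integer seed; forests are fitted inside `withr::with_seed()`
  so no global RNG state leaks between stages. Identical inputs reproduce
  bit-identical manifests; the run manifest stores md5 checksums of the
  serialised key tables to make that checkable.

## Problem sizes used by the checks

The test suite exercises the paired-cohort generator at n = 120 subjects
with 60/50-lipid detectable sets for structural checks, and the
parameter-recovery and degradation properties at n = 777 (163 lipids, 12
planted TriG lipids, 5 seeds) and n = 200 (60 lipids, 10 seeds × 5
attenuation levels) respectively. The acceptance script runs the full
pipeline once at n = 777/835 with 163/118 detectable lipids — the scale
the cohort parameters describe. Filter-oracle and arithmetic checks run
on hundreds of small random matrices where brute-force enumeration is
exact.

## Known limitations

- The iterative panel growth evaluates candidates on the same held-out
  set it finally reports, so the reported test r is mildly optimistic;
  use the inner-split mode when unbiased estimates matter.
- Random-forest importance splits credit between correlated lipids; a
  planted panel whose members are strongly mutually correlated can be
  recovered as a different same-sized subset with equal predictive value.
- TIC normalisation makes abundances compositional; correlations computed
  on normalised data are not identical to correlations on raw intensities
  (the calibration above absorbs this for the defaults).
- The quartile tie policy guarantees balanced groups but makes the group
  boundaries data-order dependent in the presence of heavy ties (hence
  the warning).
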