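---
title: "Calibrating dairy-cow heat production from milk mid-infrared spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating dairy-cow heat production from milk mid-infrared spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpmir)
```

## The problem

Heat production (HP) is the energy a cow dissipates rather than secretes in
milk, and at comparable milk yield and body weight it indexes metabolic
efficiency. The reference measurement is indirect calorimetry in a
respiration chamber: daily oxygen consumption, carbon dioxide and methane
production (L/d) and urinary nitrogen (g/d) enter the Brouwer equation

$$HP\ (\mathrm{kJ/d}) = 16.18\,V_{O_2} + 5.02\,V_{CO_2} - 2.17\,V_{CH_4} - 5.99\,N_u,$$

and HP is normalized to metabolic body weight, $mBW = BW^{0.75}$
(kg$^{0.75}$), the allometric scale of maintenance energy. Chambers are
accurate but slow and expensive. Milk Fourier-transform mid-infrared (FTIR)
spectroscopy is routine and cheap, and milk spectra encode the fat, protein
and lactose content that determines milk energy density. `hpmir` implements
and tests the full calibration chain from milk spectra plus milk yield to
HP per metabolic body weight.

Urinary N is rarely measured in routine runs; when absent it is assumed at
150 g/d. At chamber-typical gas volumes the $N_u$ term contributes well
under 1% of HP (`nu_term_fraction()` computes the exact share), so the
assumption is benign.

## Spectral preprocessing

Spectra arrive as transmittance on a wavenumber grid (by default 1060
uniformly spaced channels spanning 925–5008 cm$^{-1}$) and are transformed
to decadic absorbance, $A = \log_{10}(1/T)$. Base 10 is the mid-infrared
convention; the transform is exactly invertible (`to_transmittance()`).

Only three regions carry usable constituent information:
968–1577, 1720–1808 and 2564–2965 cm$^{-1}$, covering the lactose C–OH
band (~1080), the fat ester C–O (~1175) and carbonyl C=O (~1750) bands,
the protein amide bands below 1577, and the fat acyl C–H stretches
(2800–3000). The water-dominated stretches (1577–1720 cm$^{-1}$ and above
3000 cm$^{-1}$) are saturated and discarded. `select_regions()` keeps
exactly the channels whose wavenumber lies in a closed interval; the
retained count therefore depends on the instrument grid, and the package
never hard-codes a count. Intervals are closed on both ends and channels
are compared by their grid value.

First/second gap-difference derivatives (`apply_derivative()`) are
implemented but off by default: on raw milk absorbance they brought no
improvement in this problem class, and the default pipeline uses raw
region-selected spectra.

### Outlier screening

Spectral outliers are screened in latent-variable space: a SIMPLS model
with `outlier_n_lv` components (default 10, reduced when the sample is
small) is fitted, the robust center and covariance of the scores are
estimated by the minimum covariance determinant with coverage fraction
0.75 (`MASS::cov.rob`), and squared Mahalanobis distances are compared to
the $\chi^2_{k}$ quantile at tail probability `alpha` (default 0.025).
Screening runs after region selection, so artifacts confined to discarded
channels are invisible to it — by design, since those channels never enter
the model. Flagged rows are reported but kept unless `drop_outliers = TRUE`;
clean chamber datasets rarely contain gross spectral outliers, and silent
deletion would change the sample accounting. A singular robust covariance
gets a ridge of $10^{-10}\,\mathrm{tr}(\Sigma)/k$ with a warning.

## The four models

With $a_{am}, a_{pm}$ the session absorbance spectra and $y_{am}, y_{pm}$
the session yields (L):

* **L1** — ordinary least squares of HP/mBW on daily yield
  $y_{am}+y_{pm}$; the yield-only reference.
* **M1** — $(a_{am}+a_{pm})/2$: composition only, no quantity.
* **M2** — $\tfrac{a_{am}+a_{pm}}{2}(y_{am}+y_{pm})$: mean spectrum scaled
  by daily yield.
* **M3** — $(a_{am}y_{am}+a_{pm}y_{pm})/2$: each session weighted by its
  own yield, so within-day differences in composition and yield are
  combined the way milk energy actually leaves the udder.

The M3 divisor is 2 — the plain average of the yield-multiplied spectra —
not the total yield: dividing by total yield would renormalize away the
quantity information that distinguishes M3 from M1. The normalized variant
remains available (`m3_divisor = "total_yield"`). Note the exact identity
$M3 = M2/2 + (a_{am}-a_{pm})(y_{am}-y_{pm})/4$: the two schemes differ
only by the session-interaction term, so their performance difference is
genuine but small, and milk yield enters M2/M3 only as a spectral
multiplier, never as an appended predictor column.

## SIMPLS

The PLS core is authored in the package (de Jong's SIMPLS, single
response): each component takes the dominant direction of the deflated
cross-product $s = X_c^\top y_c$, normalizes the score to unit length, and
deflates $s$ against an orthonormal basis of the x-loadings. Numerical
choices:

* **Centering only, no autoscaling.** Channel variance in absorbance
  spectra is informative; unit-variance scaling would inflate noise
  channels. Partial-LV PLS is not scale-equivariant, so this choice is a
  modelling decision, not a convenience (at the full LV count the fit
  equals least squares and is equivariant — asserted in the tests).
* **Re-orthogonalization.** The loading basis gets two Gram–Schmidt passes
  per deflation, so score orthogonality survives the strong collinearity
  of spectral channels (verified to 1e-8 in the tests).
* **Zero-variance channels** (constant water-region leftovers) are
  retained with zero weight rather than erroring.
* **Rank exhaustion** truncates the component sequence with a warning;
  inside cross-validation folds this is routine and silent, and
  predictions above the achieved rank reuse the deepest component.

The number of latent variables is chosen as the global minimum of the
cross-validated RMSE curve, ties broken toward fewer components; the
search range defaults to 1..min(20, rank).

## Validation design

* **Random 10×10 cross-validation.** Each of 10 iterations partitions the
  cow-days into 10 near-equal folds (sizes differ by at most one), so each
  observation is validated exactly once per iteration. Per iteration the
  out-of-fold predictions are pooled into one RMSE and $R^2$ per LV count;
  reported RMSECV/R²CV curves are means over iterations. Pooling before
  averaging was chosen over averaging per-fold statistics for stability at
  fold sizes near 17.
* **External 4-fold validation.** One random split into quarters; each
  quarter is predicted by a model whose LV count was re-selected by an
  inner 10×10 CV on the other three quarters, so selection never leaks
  into the held-out data. RMSEV/R²V are means of the four per-quarter
  values.
* **Metrics.** $R^2$ is always $1 - SSE/SST$ (not a squared correlation),
  so cross-validated $R^2$ can be negative. Lin's concordance (CCC) uses
  population moments and is computed on the pooled cross-validated
  predictions at the chosen LV (calibration predictions would flatter it).
  RPD divides the sample SD (n−1) of the observed response by RMSECV at
  the chosen LV; a bias-corrected SEP denominator is available
  (`rpd_denominator = "sep"`), as printed RPDs in the literature sometimes
  use it.
* **Seeding.** One master seed drives everything; the external CV derives
  per-quarter inner seeds from its own stream, and all schemes are exactly
  reproducible from the seed (fold assignments are returned for audit).
  All schemes of one report share a seed, making model comparisons paired.

Repeated measurements on the same cow are treated as independent —
chamber observations are separated by diet, parity and lactation-stage
changes — so no cow-blocked CV is provided.

## The synthetic-data generator

Chamber datasets are small, proprietary and slow to collect, so the
package ships a generator (`generate_dataset()`) that emulates the joint
structure the calibration relies on; every pipeline stage is tested
against it. The defaults describe one fixed synthetic study and were set
a priori on domain grounds, not adjusted to test outcomes:

* **Design:** 84 cows × 2 cow-days = 168 observations, two milkings each
  (336 spectra) — the size of a realistic multi-experiment chamber
  compilation.
* **Animals:** body weight uniform on 500–915 kg; daily yield uniform on
  5.2–51.4 L, split 55% AM on average (the longer overnight interval) with
  cow-day jitter (sd 0.06, clamped to [0.25, 0.85]).
* **Milk composition:** cow-day fat 40 ± 12, protein 34 ± 5, lactose
  48 ± 2.5 g/kg — deliberately wide, as in a pool of two breeds, several
  diets and all lactation stages — plus AM/PM session variation (sd 5, 2,
  1 g/kg), reflecting the well-known within-day composition swing.
* **Spectra:** Gaussian bands at the canonical fat/protein/lactose
  assignments, absorbance linear in concentration, baseline 0.05, channel
  noise sd 0.01 absorbance, water regions saturated at absorbance 3,
  returned as transmittance.
* **Energy and HP:** milk energy density $e = 0.0384\,\mathrm{fat} +
  0.0223\,\mathrm{protein} + 0.0199\,\mathrm{lactose}$ MJ/kg (a generator
  convention giving ~3.2 MJ/kg at typical composition). Daily milk energy
  is session-resolved, $\sum_s e_s y_s$, which is what makes the
  yield-weighted M3 fusion the exactly-correct predictor. True HP =
  500 kJ/kg$^{0.75}$ maintenance + 0.8 × 1000 × milk energy + Gaussian
  noise (sd 30000 kJ/d). The two coefficients land mean HP/mBW near
  chamber-typical values (~1050 kJ/kg$^{0.75}$); the noise sd places the
  default-noise cross-validated R² in the moderate regime typical of
  FTIR-based physiological trait calibrations (~0.5–0.6).
* **Gas exchange** is back-solved from true HP at a fixed respiratory
  quotient (1.05) and a methane volume tied to a latent dry-matter intake
  (32 L/kg, DMI = 6 + 0.45 × yield + noise), so the Brouwer computation
  round-trips exactly (relative 1e-9, verified to 1e-15 in tests).

What the generator does **not** emulate: lactation-stage and diet dynamics,
breed effects, within-cow covariance of repeated measurements (cow-days
are independent given the cow's body weight), scatter effects needing
SNV/MSC correction, water-vapor interference, or instrument drift. Passing
tests on synthetic data therefore demonstrate that the algorithms are
correct and that the pipeline recovers a signal of the assumed structure —
not that real milk spectra predict real HP at any particular accuracy.

Degenerate intervals (for instance `bw_range = c(692, 692)`) are allowed
deliberately: constant-body-weight datasets isolate the milk-energy signal
and are used by the signal-recovery tests, where a noise-free dataset must
give M3 R²CV ≥ 0.95.

## Problem sizes used in tests

The shipped tests run the full 168-cow-day pipeline for the end-to-end
checks (about 3 s per scheme), 40-cow-day reduced-grid datasets (300
channels) for pipeline unit tests, and 50-replicate simulations for the
outlier-screen calibration; the whole suite completes in under two
minutes on one core. These sizes were chosen as the smallest that keep the
statistical checks stable.

## Known limitations

* Single-response PLS only; no multi-trait, sparse or kernel variants.
* The calibration-set RMSEP reported in the summary table is the training
  RMSE at the chosen LV count — optimistic by construction, and reported
  alongside the cross-validated and external figures for that reason.
* The reader accepts one body weight per cow-day; studies that weigh
  before and after the chamber stay should pre-average.
* No scatter correction or instrument standardization: spectra from
  different spectrometers are not made comparable.
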