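---
title: "Methods: fused vegetation-index time series and county/pixel yield prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fused vegetation-index time series and county/pixel yield prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropcast)
```

## The problem

County-level winter-wheat yield statistics exist for long periods, but
in-season, spatially resolved prediction needs satellite predictors.  A
fine-resolution optical sensor (30 m class, 16-day revisit) sees too few
cloud-free scenes over a wheat season; a coarse sensor (500 m class, 8-day
revisit) sees the season densely but blurs field-scale detail.  `cropcast`
implements the standard remedy as a tested pipeline: reconstruct a gap-free
monthly vegetation-index (VI) series at the fine resolution by substituting
resampled coarse-sensor values into fine-sensor gaps, aggregate VI and
monthly climate over a crop mask, regress county yields on the monthly
features, and evaluate the regressors with the validation battery used in
this literature (random 70/30 split, leave-one-year-out, relative-error
bands, pixel-level mapping with county- and site-level checks, and a
forward-month timing analysis).

All computation is exercised on synthetic scenes: no real Landsat/MODIS,
climate or yearbook data ships with the package, and none is downloaded.

## Vegetation indices

From red and near-infrared (NIR) surface reflectance:

* NDVI = (NIR − RED)/(NIR + RED), clipped to [−1, 1]; cells with a zero
  denominator are invalid.  Reflectance slightly outside [0, 1] is accepted,
  as real surface-reflectance products contain such values.
* NIRv = (NDVI − 0.08) · NIR, a proxy for photosynthetically active
  canopy reflectance; the 0.08 offset is a fixed constant of the index and
  the clipped NDVI is used.
* kNDVI = tanh(NDVI²), the kernelized index with fixed length scale — the
  printed closed form, not the general kernel with a tunable bandwidth.

## Season and feature layout

A season is indexed by harvest year `y` and spans 8 calendar month slots,
October of `y−1` through May of `y` (`SEASON_MONTHS`).  A feature row holds
48 columns, `<var>_<slot>` for var in {VI, Pr, Tmax, Tmin, VPD, SM}, months
Oct..May within each variable.  County rows and pixel rows share this
schema byte for byte, so a county-trained model maps pixels unchanged — the
level-transfer step that pixel mapping depends on.

## Reconstruction

Per season, in this order:

1. **Fine sensor**: cloud-masked VI observations are reduced per pixel and
   calendar month by *maximum-value compositing*, which suppresses residual
   cloud and aerosol contamination (undetected contamination biases VI
   downward).  Empty months stay invalid.
2. **Coarse sensor**: VI observations are temporally interpolated (linear
   in layer index between nearest valid neighbors; nearest-value fill at
   the ends), composited monthly the same way, then Savitzky–Golay (SG)
   smoothed.
3. **Fusion**: each coarse monthly layer is bilinearly resampled to the
   fine grid; output pixels take the fine composite where valid, else the
   resampled coarse value, else temporal interpolation; the final series is
   SG smoothed again with the same parameters.

Design choices worth stating explicitly:

* **SG parameters** default to window 5, order 2 — the largest odd window
  that leaves several independent interior positions on an 8-point series.
  One parameter set serves both smoothing passes; nothing in the procedure
  requires them to differ.  Edges are handled by fitting the polynomial to
  the first/last full window and evaluating it at the edge positions, so
  any series that is itself a polynomial of degree ≤ 2 is reproduced
  exactly at *every* position.  The operator is built from the
  least-squares solution directly and is cross-checked in the tests against
  `signal::sgolayfilt`.
* **Compositing operates on the VI**, computed per observation date, not on
  reflectance bands; with maximum compositing the two orders differ, and
  compositing the index is the interpretation consistent with compositing
  *after* cloud masking of VI imagery.
* **No inter-sensor bias correction**: gaps take the resampled coarse
  value as-is.  Where the sensors disagree systematically this is an
  accuracy limitation; it is reported, not hidden (gap counts and
  unfillable-pixel counts travel as attributes and logs).
* **Bilinear resampling** uses pixel-center alignment (row 1 top, centers
  at half-pixel offsets) and propagates invalidity conservatively: any
  contributing source cell invalid, or a target center outside the source
  center hull, makes the target invalid.  Gap repair belongs to the fusion
  step, not the resampler.  A consequence: a rim of half a coarse pixel
  around the scene can never take coarse values and relies on the fine
  sensor's own temporal interpolation.
* **Slot arithmetic**: monthly layers are nominally time-stamped on the
  15th and interpolation runs in slot index, not days — with one value per
  month, day-level spacing is spurious precision.
* Pixels never observed by either sensor across the season are excluded
  from all downstream products and counted (`emptyPixels()`).

## Features

Zonal means are arithmetic means of valid pixels per county label under the
crop mask; counties with zero contributing pixels are omitted and reported.
Conservation (sum of mean × count equals the masked total) is asserted in
the tests.  Climate is attached as-is per month (the source product is
already monthly) after bilinear resampling to the fine grid; both satellite
and climate features are masked by the crop mask before averaging.  Rows
missing any of the 48 features or the yield record are dropped and counted.
Site-level validation reads the single map pixel containing the site
coordinates (pixel-center containment); no footprint model is attempted.

## Models

Two regressors share the standardization contract (features and target
z-scored with training statistics; statistics frozen into the fitted model):

* **Gradient-boosted trees** (`"gbm"`, alias `"lgbm"` accepted): leaf-wise
  histogram trees via xgboost (`grow_policy = "lossguide"`), the same
  algorithm family as LightGBM.  Grid: learning rate {0.05, 0.1} × leaves
  {15, 31}; ≤ 500 trees.  Early stopping monitors a held-out 10% of the
  training rows, after which the model is refit on the full training set at
  the selected round count.
* **LSTM**: the 48 columns are reshaped to an 8-step sequence of 6
  channels in season order and fed to a single recurrent layer (hidden
  size 32 or 64 in the CV grid) with a linear head on the last hidden
  state (a mean-pooled head is available; on these tasks the last-state
  head validated better and is the default).  Training: Adam
  (learning rate 0.01, halved when the validation loss stalls for 8
  epochs), decoupled weight decay 0.003, batch 32, ≤ 300 epochs, early
  stopping patience 30 on a held-out 10% of training rows.  The predictor
  averages a committee of 3 independently initialised trainings, which
  stabilises the stochastic optimisation at these sample sizes.  The
  implementation is in-package, vectorised base R with full
  backpropagation through time, and is verified against numerical
  gradients in the test suite.

Protocol: rows are split 70/30 *by county-year row* (the option to group by
county or year exists but is off by default — ungrouped splitting is the
plain reading of a random split, at the cost of optimistic absolute
numbers); ten-fold CV for hyperparameter selection runs on the training
portion only, with near-equal folds and ties broken by grid order; the
winning spec is refit on the full training portion.  One seed governs
split, folds and fits, so comparisons across indices and algorithms are
paired.  Whether CV folds should be grouped by year is a threat to
validity we note but do not resolve; leave-one-year-out gives the
year-grouped view.

## Evaluation

R² is 1 − SS_res/SS_tot about the observed mean (it can be negative out of
sample) — the coefficient of determination proper, not a squared
correlation.  RMSE is in kg/ha.  Relative error is 100·(pred − obs)/obs,
banded at ±20% with the inner interval closed.  Leave-one-year-out refits
per held-out year; its test sets partition the records.  Yield maps clip
negative predictions to zero and count the clips.  County-level map
validation aggregates the map by the unweighted mean of crop pixels —
area weighting is not attempted.  The forward-month analysis retrains per
truncation (October through May), rather than masking inputs of a
full-season model, so each month's figure reflects a model that could have
been built at that date; the May entry coincides exactly with the
full-feature evaluation at the same seed.

## The synthetic scene generator

`sceneConfig()` defaults define the study conditions; they are fixed, not
tuning knobs:

* 120 × 120 fine grid (1 map unit per pixel), coarse sensor of 16 × 16
  blocks (the 30 m vs ~500 m ratio), climate on a coarser 40-pixel grid
  extended one cell beyond the scene so resampling covers every pixel.
* 20 harvest years (2001–2020), 100 rectangular counties, 13 validation
  sites — 2000 county-year records, the sample-size regime of multi-county
  yearbook panels.
* Fine sensor: 2 observations/month, each losing 30% of pixels to
  spatially correlated cloud (quantile-thresholded smooth noise, so the
  fraction is exact per date); coarse sensor: 4 observations/month, no
  gaps, band noise on both (sd 0.01 reflectance).
* Phenology: a double-logistic NDVI curve (base 0.15, peak 0.85, green-up
  inflection mid-January, senescence in May) with smooth spatial fields on
  the peak and green-up timing plus common year effects.  NIR is derived
  from NDVI by a fixed linear canopy relation and red by exact inversion,
  so the band-level pipeline (index computation included) is exercised
  end to end.  An optional late-season stress field (off by default)
  multiplies the VI from a configurable onset slot onward, emulating late
  frost or grain-filling drought.
* Yields: beta0 + Σ betaVi·VI_slot + Σ gamma·(season-mean climate) +
  N(0, 300²) kg/ha, floored at 100, computed from the *true* (pre-gap,
  pre-noise) features so that sensor/reconstruction error stays separable
  from model error.  Coefficients weight spring months most (April
  dominant), with magnitudes chosen once so county yields land in a
  realistic 4000–8000 kg/ha band with spread driven roughly 3:1 by
  vegetation vs climate.  Site yields use the site pixel's true features
  with independent noise.

Everything is a pure function of the config (master seed included); child
seeds are derived per stream, so e.g. cloud masks do not change when the
noise level does.

What the generator does **not** emulate — and hence what green tests do not
establish about real data: radiative transfer, BRDF and atmosphere;
non-calendar phenology shifts between regions; yield responses that are
nonlinear or non-additive in the features; reporting error in yearbook
statistics; real cloud climatology.  Passing the battery shows the
machinery is correct and recovers known signal under realistic corruption,
not that published real-data accuracy figures transfer.

## Experiment sizes and numerical choices

The test battery and the acceptance script run at sizes chosen for a
single-CPU desk run: the default 120 × 120 × 20-year scene for parameter
recovery and leave-one-year-out; 60 × 60 scenes with 25 counties for the
timing (12 years) and mapping (8 years) experiments, 5 seeds each where an
ordering is asserted.  The timing experiment switches the stress field on
(sd 0.2, onset at the April slot boundary 6.5) and sets all yield weight on
April's VI, so months before April genuinely cannot contain the stress
information — the mechanism behind an April optimum prediction time.
Numerical tie-breaks: CV ties go to the first grid entry; the SG operator
uses exact least-squares solves (no iterative fitting); interpolation uses
slot indices; R² is flagged `NA` when observed variance is zero.

## Known limitations

* Gap substitution without bias correction transfers any coarse-sensor
  bias into gap pixels; at county aggregation this is small (a coarse
  pixel is county-scale here) but at pixel scale it is visible in the map
  validation gap between county and site R².
* The LSTM is tuned for 8-step sequences of a few thousand rows; it is not
  a general-purpose deep-learning stack.
* One CRS per analysis; no reprojection, no multi-band stacks, no
  cloud-optimized formats.  Raster I/O is plain-text ESRI ASCII grids with
  a `.prj` sidecar — adequate for fixtures and synthetic scenes and
  readable by standard GIS tools, not a production tile store.
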