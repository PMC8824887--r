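---
title: "RF time-series tissue characterization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RF time-series tissue characterization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfseries)
```

## The measurement model

An ultrasound machine operated in research mode records, frame after
frame, the raw radio-frequency (RF) echo along each scan line before
envelope detection. When the probe is held still, the amplitude at one
fixed (line, depth-sample) location becomes a *time series* across
frames. The working hypothesis of RF time-series tissue characterization
is that the temporal statistics of these series — their roughness,
spectral decay and amplitude distribution — differ between tissue types
even when the B-mode image does not resolve the difference.

`rfseries` implements this analysis as four stages: build one time
series per ROI pixel, reduce each ROI to fourteen characteristic
parameters, collect one feature vector per subject into a table, and
compare groups with standard tests. Because clinical RF recordings are
rarely shareable, the package also includes a seeded simulator that
produces cohorts with *known* class contrasts, which is what all tests
run against.

## The simulator: what it emulates, and what it does not

`simulate_rf_sequence()` builds a speckle baseline — a random scatterer
field convolved along depth with a Gaussian-modulated sinusoid at the
configured center frequency — and then evolves every pixel over time:

$$y_p(t) = a\,\big(b_p + \sigma_{\mathrm{fbm}} B^{(H)}_p(t)
  + \sigma_{\mathrm{ar}} R_p(t)\big) + \sigma_w W_p(t),$$

where $b_p$ is the static speckle value, $B^{(H)}$ a fractional Brownian
motion path (cumulated exact fractional Gaussian noise, Hurst exponent
$H$), $R$ a stationary AR(1) drift, $W$ white noise, and $a$ the class
amplitude scale. All three fluctuation components are zero at the first
frame, so frame 0 is the pure speckle image. Class contrast is injected
through the *temporal* parameters because that is the axis the fourteen
features measure; the paths of different pixels are independent.

Defaults encode the reference acquisition this line of work uses: 256
frames over a 20 s hold (12.8 Hz frame rate), 6 MHz center frequency,
40 MHz sampling, 10 cm depth, a 128 × 64 grid with a centered 70 × 20
ROI — i.e. 1400 series of 256 points per subject, with tumor $H = 0.3$
(target FD $2 - H = 1.7$) versus normal $H = 0.8$ (target FD 1.2). The
fluctuation scales (`fbm_sd` 60, `ar_sd` 15, `noise_sd` 5 raw amplitude
units against a speckle SD normalized to 2000) were chosen once so that
the structured components dominate the additive noise without risking
16-bit clipping; they are class parameters, not calibrated constants.

What the simulator does **not** emulate: acoustic wave propagation,
probe motion, out-of-plane decorrelation, attenuation with depth,
spatially correlated tissue dynamics, or any physiological mechanism.
Passing tests therefore demonstrate that the *pipeline* recovers
engineered temporal contrasts — not that real cervical tissue carries
them. No claim of physiological fidelity is made or implied.

### Exact fractional Gaussian noise

The fractal driver matters most, so it is exact rather than approximate:
`generate_fgn()` uses circulant embedding of the closed-form
autocovariance
$\gamma(k) = \tfrac12\big(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}\big)$.
The $2n \times 2n$ circulant built from $[\gamma_0..\gamma_n,
\gamma_{n-1}..\gamma_1]$ has eigenvalues $\mathrm{fft}$ of that row;
shaping complex Gaussian noise by their square roots and
inverse-transforming yields a Gaussian vector with *exactly* the fGn
covariance. Should the embedding ever fail nonnegative-definiteness
(numerically it does not for $H \in (0,1)$ at the sizes used), the code
falls back to a dense Cholesky factorization and says so. The test suite
checks the sample autocovariance at lags 0–5 against $\gamma(k)$ and
against an independent dense-Cholesky oracle.

## The fourteen parameters

All per-series features are computed on mean-removed series; the
per-series mean is retained so `peak` can use the raw trace. Per ROI,
features are the arithmetic mean over the pixel series
(`cross_zero_std` is the across-series SD). The aggregation is a design
choice: a single value per subject is reported and the literature leaves
the pooling unstated; the mean is the simplest defensible choice and is
stated here prominently.

| parameter | definition | tunables (default) |
|---|---|---|
| `higuchi_fd` | $-$slope of $\log L(k)$ vs $\log k$, $L(k)$ the mean normalized curve length | `kmax` (8) |
| `sfd` | $2 - H$, $H = \tfrac12\,$slope of $\log S(\tau)$ vs $\log\tau$, $S(\tau)=\langle(x_{t+\tau}-x_t)^2\rangle$ | `tau_max` (16) |
| `slope`, `intercept`, `midbandfit` | OLS line through the working-scale spectrum over `fit_band`; midband = fitted value at the band midpoint | `fit_band` ([0, 0.5]), `spectrum_log` (TRUE) |
| `s1..s4` | linear-scale power sums over the four equal quarters of [0, 0.5] cycles/frame | — |
| `fuzzy_entropy` | $-\ln(\Phi_{m+1}/\Phi_m)$, exponential membership $e^{-(d/r)^{g}}$, Chebyshev $d$ on baseline-removed templates | `fuzzy_m` (2), `fuzzy_r_factor` (0.2·SD), `fuzzy_gradient` (2) |
| `peak` | max absolute raw amplitude | — |
| `kurtosis` | $m_4/m_2^2$ (`pearson`); $-3$ (`excess`); $/3$ (`normalized`) | `kurtosis_convention` (pearson) |
| `cross_zero_count`, `cross_zero_std` | strict sign changes per series (zeros inherit the previous sign); mean and across-series population SD | `crossing_scale` (log10) |

Choices worth spelling out:

* **Spectrum.** Hann window, one-sided periodogram normalized to unit
  total power, frequency in cycles/frame on $[0, 0.5]$. The line fit
  runs on the log10 spectrum by default (floored at `spectrum_eps`,
  $10^{-12}$) because slope/intercept magnitudes are otherwise dominated
  by the few largest bins; the flag makes the scale explicit and
  reversible. Band energies always use the linear scale, so
  $S_1+S_2+S_3+S_4$ equals total power exactly (to $10^{-9}$ in tests).
  A bin center falling exactly on a band edge goes to the lower band — a
  deterministic tie-break.
* **FD clipping.** Both estimators report values clipped to the
  theoretical range $[1, 2]$; the unclipped estimate travels as an
  attribute and clip events are counted, never silent. On simulator
  output the raw estimates stay within $[0.9, 2.1]$ (asserted as a
  property test).
* **Kurtosis conventions.** `pearson` is the plain fourth standardized
  moment (population moments). `normalized` divides by the Gaussian
  reference 3, so white noise scores 1 — a documented factor provided
  because published tables in this area use scales that are not
  recoverable from the text.
* **Crossing scale.** The default reported crossing statistic is
  $\log_{10}(\text{count}+1)$, with the raw count one flag away. Note
  a 256-point series has at most 255 crossings, so the log-scale value
  is at most 2.41: published magnitudes near 3.8 cannot be reproduced
  from 256-point series on either scale, and the package documents its
  own scale only.
* **Cross-zero SD reading.** "Zero-crossing SD" is ambiguous between
  the SD of crossing counts *across series* and the SD of crossing
  intervals *within* a series; the across-series reading is implemented
  (it is the only one that needs the block, matching its placement in
  the block-level API). The within-series alternative is noted here and
  not implemented.
* **Degenerate series** (zero variance, or zero spectral power after
  windowing) are skipped and counted, never imputed; an all-degenerate
  ROI is an error. The skip count is carried in the feature vector and
  the feature table.

## Statistics

The comparison stage mirrors the conventional reporting layout: per
feature, group means ± sample SD, the test statistic, and a two-sided
p-value, with significance marked strictly below 0.05. The default
two-group test is the pooled-variance Student t — matching the
equal-variance assumption such studies state — with Welch one flag away.
The grade comparison is a one-way fixed-effects ANOVA. Two-sidedness is
a choice (the convention when direction is not pre-registered); so is
reporting sample (n−1) SDs. No multiple-testing correction is applied by
default, reproducing the single-look procedure such tables report, but
`p_adjust` exposes `stats::p.adjust`'s methods and the choice is
recorded in the result's settings. A Shapiro–Wilk screen per feature and
group is available and advisory only.

Implementation note: the t and F statistics are delegated to
`stats::t.test` and `stats::oneway.test`; the test suite checks them
against from-scratch sum-of-squares oracles to $10^{-9}$, checks
antisymmetry under label swap, $F = t^2$ for two groups, and a 5% type-I
error within the 95% binomial band over 2000 Gaussian-null replicates.

## Reproducibility

A single master seed governs a run. Per-subject sub-seeds are derived by
a fixed linear mix modulo $2^{31}-1$ (`derive_subseed`), so cohorts are
reproducible from one integer while subjects stay independent; every
seeded function restores the caller's RNG state. `run_pipeline()` writes
a config snapshot, its MD5 hash, and checksums of every artifact into a
run manifest; identical config + seed reproduces byte-identical feature
tables and reports (asserted in the suite).

## Problem sizes used by the tests

The suite exercises the reference geometry where the structural claims
live (1400 × 256 blocks; a 20 + 20 subject end-to-end study) and a
desk-scale geometry (64 frames, 8 × 5 ROI) everywhere a property does
not depend on size. Monte-Carlo checks use 100–200 replicates for
distributional properties and 2000 for test calibration. These sizes are
the package's choices for a laptop-scale default run; all of them are
plain parameters that scale up without code changes.

## Known limitations

* The simulator's contrast is statistical, not physical; transfer to
  real tissue is an empirical question the package cannot answer.
* Feature magnitudes are tied to the package's documented scales
  (unit-power spectra, log10 crossings); only contrasts within a run are
  comparable across studies.
* The Ultrasonix-style dialect is a documented approximation of that
  machine family's raw export (fixed-point metadata; whole-Hz
  frequencies), not a vendor format; the portable dialect carries full
  double-precision metadata and is preferred for archival.
* Higuchi and structure-function estimators are biased near the ends of
  the FD range; estimates are clipped to $[1, 2]$ with the raw value
  logged rather than hidden.
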