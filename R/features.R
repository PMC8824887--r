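#' Canonical feature order
#'
#' The fixed order of the fourteen characteristic parameters used in every
#' feature vector, table and report: two fractal-dimension parameters,
#' seven frequency-domain parameters, five time-domain parameters.
#' @export
FEATURE_NAMES <- c("higuchi_fd", "sfd", "slope", "intercept", "midbandfit",
                   "s1", "s2", "s3", "s4",
                   "fuzzy_entropy", "peak", "kurtosis",
                   "cross_zero_count", "cross_zero_std")

#' Feature-extraction configuration
#'
#' Every tunable constant of the fourteen-parameter extraction lives here
#' so alternatives can be swapped without code changes.
#'
#' @param kmax Maximum coarse-graining delay of the Higuchi estimator.
#' @param tau_max Maximum lag of the second-order structure function.
#' @param fuzzy_m Fuzzy-entropy embedding dimension.
#' @param fuzzy_r_factor Fuzzy-entropy tolerance as a fraction of the
#'   series SD.
#' @param fuzzy_gradient Exponent of the exponential membership function.
#' @param fit_band Normalized frequency band `[f_lo, f_hi]` (cycles/frame,
#'   inside `[0, 0.5]`) over which the spectral line is fitted.
#' @param spectrum_log Fit the spectral line on a log10 power scale?
#' @param kurtosis_convention `"pearson"` (fourth standardized moment),
#'   `"excess"` (pearson minus 3) or `"normalized"` (pearson divided by 3,
#'   the Gaussian reference value, so white noise scores 1).
#' @param crossing_scale Scale of the reported zero-crossing statistics:
#'   `"log10"` reports `log10(count + 1)`, `"raw"` the plain count.
#' @param spectrum_eps Flooring constant before log10 conversion.
#' @return A `FeatureConfig` list.
#' @export
feature_config <- function(kmax = 8, tau_max = 16, fuzzy_m = 2,
                           fuzzy_r_factor = 0.2, fuzzy_gradient = 2,
                           fit_band = c(0, 0.5), spectrum_log = TRUE,
                           kurtosis_convention = c("pearson", "excess",
                                                   "normalized"),
                           crossing_scale = c("log10", "raw"),
                           spectrum_eps = 1e-12) {
  kurtosis_convention <- match.arg(kurtosis_convention)
  crossing_scale <- match.arg(crossing_scale)
  if (!is_count(kmax) || kmax < 2) stop_validation("`kmax` must be an integer >= 2")
  if (!is_count(tau_max) || tau_max < 1)
    stop_validation("`tau_max` must be an integer >= 1")
  if (!is_count(fuzzy_m) || fuzzy_m < 1)
    stop_validation("`fuzzy_m` must be an integer >= 1")
  if (fuzzy_r_factor <= 0) stop_validation("`fuzzy_r_factor` must be > 0")
  if (fuzzy_gradient <= 0) stop_validation("`fuzzy_gradient` must be > 0")
  if (length(fit_band) != 2 || fit_band[1] < 0 || fit_band[2] > 0.5 ||
      fit_band[1] >= fit_band[2])
    stop_validation("`fit_band` must satisfy 0 <= f_lo < f_hi <= 0.5")
  structure(list(kmax = as.integer(kmax), tau_max = as.integer(tau_max),
                 fuzzy_m = as.integer(fuzzy_m),
                 fuzzy_r_factor = fuzzy_r_factor,
                 fuzzy_gradient = fuzzy_gradient,
                 fit_band = as.numeric(fit_band),
                 spectrum_log = isTRUE(spectrum_log),
                 kurtosis_convention = kurtosis_convention,
                 crossing_scale = crossing_scale,
                 spectrum_eps = spectrum_eps),
            class = "FeatureConfig")
}

#' Build the per-pixel time-series block of an ROI
#'
#' Takes the pixel grid inside `roi` and forms one RF time series per
#' pixel: that pixel's amplitude across the first `n_frames_used` frames,
#' mean-removed per series. Rows are ordered line-major: all depth samples
#' of the first ROI line first, i.e. row index
#' `(line - line_start) * roi_samples + (sample - sample_start) + 1`.
#' The per-series means are kept alongside so amplitude-scale features
#' (peak) can be computed on the raw trace.
#'
#' @param seq An [rf_sequence()].
#' @param roi An [roi_spec()] inside `seq`.
#' @param n_frames_used Frames to keep from the start of the sequence
#'   (default: all).
#' @param subject_id Optional provenance tag.
#' @return A `TimeSeriesBlock`: list with `series` (n_series x n_frames,
#'   mean-removed), `series_mean`, `n_series`, `n_frames`, `provenance`.
#' @examples
#' p <- sim_params(n_frames = 32, n_lines = 16, n_samples = 8,
#'                 roi_lines = 4, roi_samples = 2)
#' seq <- simulate_rf_sequence(p, "tumor", seed = 1)
#' blk <- extract_roi_block(seq, roi_spec(0, 4, 0, 2))
#' blk$n_series
#' @export
extract_roi_block <- function(seq, roi, n_frames_used = seq$n_frames,
                              subject_id = NULL) {
  if (!inherits(seq, "RFSequence")) stop_validation("`seq` must be an RFSequence")
  if (!inherits(roi, "ROISpec")) stop_validation("`roi` must be an ROISpec")
  validate_roi_in_sequence(roi, seq)
  if (!is_count(n_frames_used) || n_frames_used < 2)
    stop_validation("`n_frames_used` must be an integer >= 2")
  if (n_frames_used > seq$n_frames)
    stop_validation("`n_frames_used` (%d) exceeds the sequence's %d frames",
                    n_frames_used, seq$n_frames)
  lines <- (roi$line_start + 1L):roi$line_stop
  samples <- (roi$sample_start + 1L):roi$sample_stop
  sub <- seq$data[seq_len(n_frames_used), lines, samples, drop = FALSE]
  # (sample, line, frame) flattened column-major = line-major row order
  m <- matrix(as.numeric(aperm(sub, c(3L, 2L, 1L))),
              nrow = length(lines) * length(samples), ncol = n_frames_used,
              byrow = FALSE)
  mu <- rowMeans(m)
  structure(list(series = m - mu, series_mean = mu,
                 n_series = nrow(m), n_frames = ncol(m),
                 provenance = list(subject_id = subject_id, roi = roi)),
            class = "TimeSeriesBlock")
}

## ---------------------------------------------------------------------------
## Fractal-dimension estimators
## ---------------------------------------------------------------------------

# Higuchi normalized curve lengths L(k), k = 1..kmax, for a block of series
# (rows). Returns n_series x kmax matrix.
block_higuchi_lengths <- function(mat, kmax) {
  n <- ncol(mat)
  L <- matrix(0, nrow(mat), kmax)
  for (k in seq_len(kmax)) {
    acc <- 0
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      ng <- length(idx) - 1L
      if (ng < 1L) stop_validation("kmax too large for series of length %d", n)
      d <- rowSums(abs(mat[, idx[-1L], drop = FALSE] -
                         mat[, idx[-length(idx)], drop = FALSE]))
      acc <- acc + d * (n - 1) / (ng * k) / k
    }
    L[, k] <- acc / k
  }
  L
}

# Least-squares slope of each row of `y` against `x` (shared abscissa).
row_slopes <- function(x, y) {
  xc <- x - mean(x)
  as.vector(y %*% xc) / sum(xc^2)
}

# Raw (unclipped) Higuchi FD per row; NA for degenerate (constant) rows.
block_higuchi_fd <- function(mat, kmax) {
  L <- block_higuchi_lengths(mat, kmax)
  ok <- rowSums(L > 0) == kmax
  fd <- rep(NA_real_, nrow(mat))
  if (any(ok))
    fd[ok] <- -row_slopes(log(seq_len(kmax)), log(L[ok, , drop = FALSE]))
  fd
}

# Raw structure-function FD (2 - H) per row; NA for degenerate rows.
block_sf_fd <- function(mat, tau_max) {
  n <- ncol(mat)
  S <- matrix(0, nrow(mat), tau_max)
  for (tau in seq_len(tau_max)) {
    d <- mat[, (1L + tau):n, drop = FALSE] - mat[, 1L:(n - tau), drop = FALSE]
    S[, tau] <- rowMeans(d^2)
  }
  ok <- rowSums(S > 0) == tau_max
  fd <- rep(NA_real_, nrow(mat))
  if (any(ok)) {
    H <- row_slopes(log(seq_len(tau_max)), log(S[ok, , drop = FALSE])) / 2
    fd[ok] <- 2 - H
  }
  fd
}

clip_fd <- function(fd) pmin(pmax(fd, 1), 2)

#' Higuchi fractal dimension of a series
#'
#' Estimates the fractal dimension of a 1-D signal from the scaling of its
#' mean normalized curve length `L(k)` with the coarse-graining delay
#' `k = 1..kmax`: the FD is minus the least-squares slope of
#' `log L(k)` versus `log k`. Values are reported clipped to the
#' theoretical range `[1, 2]`; the unclipped estimate is attached as
#' attribute `"raw"`.
#'
#' @param x Numeric series, length >= `2 * kmax`, not constant.
#' @param kmax Maximum delay (default 8).
#' @return FD in `[1, 2]` with attribute `raw`.
#' @examples
#' higuchi_fd(seq(0, 255))          # smooth line: ~1
#' @export
higuchi_fd <- function(x, kmax = 8) {
  check_series(x, min_len = 2 * kmax,
               msg = sprintf("series length must be >= 2 * kmax = %d", 2 * kmax))
  if (!is_count(kmax) || kmax < 2 || kmax >= length(x) / 2)
    stop_validation("`kmax` must be an integer in [2, n/2)")
  fd <- block_higuchi_fd(matrix(x, 1), kmax)
  structure(clip_fd(fd), raw = fd)
}

#' Structure-function fractal dimension of a series
#'
#' Computes the second-order structure function
#' `S(tau) = mean_t (x(t + tau) - x(t))^2` for `tau = 1..tau_max`,
#' estimates the Hurst exponent as half the least-squares slope of
#' `log S(tau)` versus `log tau`, and reports `FD = 2 - H` clipped to
#' `[1, 2]` (unclipped value in attribute `"raw"`).
#'
#' @param x Numeric series, length >= `2 * tau_max`, not constant.
#' @param tau_max Maximum lag (default 16).
#' @return FD in `[1, 2]` with attribute `raw`.
#' @export
structure_function_fd <- function(x, tau_max = 16) {
  check_series(x, min_len = 2 * tau_max,
               msg = sprintf("series length must be >= 2 * tau_max = %d",
                             2 * tau_max))
  if (!is_count(tau_max) || tau_max < 1 || tau_max >= length(x) / 2)
    stop_validation("`tau_max` must be an integer in [1, n/2)")
  fd <- block_sf_fd(matrix(x, 1), tau_max)
  structure(clip_fd(fd), raw = fd)
}

check_series <- function(x, min_len = 2, msg = NULL) {
  if (!is.numeric(x) || length(x) < min_len)
    stop_validation(msg %||% sprintf("series must be numeric, length >= %d", min_len))
  if (any(!is.finite(x))) stop_validation("series contains non-finite values")
  if (max(x) == min(x)) stop_degenerate("constant series")
  invisible(TRUE)
}

stop_degenerate <- function(...) {
  stop(structure(class = c("rfseries_degenerate_error", "error", "condition"),
                 list(message = paste0("degenerate input: ", sprintf(...)),
                      call = NULL)))
}

## ---------------------------------------------------------------------------
## Frequency-domain features
## ---------------------------------------------------------------------------

#' Spectrum container
#'
#' A one-sided power spectrum on a normalized frequency axis in
#' cycles/frame. `power` is the working scale used by the line fit
#' (log10 when `units_log`); `power_linear` always holds the linear-scale
#' values used by the band energies.
#'
#' @param freq Strictly increasing frequency axis in `[0, 0.5]`.
#' @param power Spectral values, same length; must be nonnegative when
#'   `units_log` is `FALSE`.
#' @param units_log Is `power` on a log10 scale?
#' @param power_linear Linear-scale power; defaults to `power`
#'   (`10^power` when `units_log`).
#' @return An `rf_spectrum` object.
#' @export
rf_spectrum <- function(freq, power, units_log = FALSE, power_linear = NULL) {
  if (length(freq) != length(power))
    stop_validation("`freq` and `power` must have equal length")
  if (any(diff(freq) <= 0)) stop_validation("`freq` must be strictly increasing")
  if (any(freq < 0) || any(freq > 0.5 + 1e-12))
    stop_validation("`freq` must lie inside [0, 0.5] cycles/frame")
  if (!units_log && any(power < 0))
    stop_validation("linear-scale `power` must be nonnegative")
  if (is.null(power_linear))
    power_linear <- if (units_log) 10^power else power
  structure(list(freq = as.numeric(freq), power = as.numeric(power),
                 units_log = isTRUE(units_log),
                 power_linear = as.numeric(power_linear)),
            class = "rf_spectrum")
}

#' Power spectrum of an RF time series
#'
#' Mean-removes the series, applies a Hann window, and computes the
#' one-sided periodogram normalized to unit total power. When
#' `cfg$spectrum_log` the working power is converted to log10 after
#' flooring at `cfg$spectrum_eps`; the exact linear-scale power is kept in
#' `power_linear` either way.
#'
#' @param x Numeric series of length >= 8.
#' @param cfg A [feature_config()].
#' @return An [rf_spectrum()].
#' @export
power_spectrum <- function(x, cfg = feature_config()) {
  if (!is.numeric(x) || length(x) < 8)
    stop_validation("series must be numeric with length >= 8")
  x0 <- x - mean(x)
  if (all(x0 == 0)) stop_degenerate("all-zero series after mean removal")
  n <- length(x0)
  w <- hann_window(n)
  X <- stats::fft(x0 * w)
  nh <- floor(n / 2) + 1L
  p <- Mod(X[seq_len(nh)])^2
  tot <- sum(p)
  if (tot == 0) stop_degenerate("zero spectral power after windowing")
  p <- p / tot
  freq <- (seq_len(nh) - 1) / n
  if (cfg$spectrum_log)
    rf_spectrum(freq, log10(pmax(p, cfg$spectrum_eps)), units_log = TRUE,
                power_linear = p)
  else
    rf_spectrum(freq, p, units_log = FALSE)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Spectral line fit: slope, intercept, midband fit
#'
#' Ordinary least-squares line `power ~ slope * freq + intercept` over the
#' spectrum bins inside `fit_band`, on the spectrum's working scale.
#' `midbandfit` is the fitted value at the band midpoint, so
#' `midbandfit == slope * f_mid + intercept` holds exactly by construction.
#'
#' @param spec An [rf_spectrum()].
#' @param fit_band Closed frequency interval `[f_lo, f_hi]`; at least 3
#'   bins must fall inside it.
#' @return List with `slope`, `intercept`, `midbandfit`, `f_mid`.
#' @export
spectral_line_fit <- function(spec, fit_band = c(0, 0.5)) {
  if (!inherits(spec, "rf_spectrum")) stop_validation("`spec` must be an rf_spectrum")
  inb <- spec$freq >= fit_band[1] & spec$freq <= fit_band[2]
  if (sum(inb) < 3)
    stop_validation("fewer than 3 spectrum bins inside the fitting band [%g, %g]",
                    fit_band[1], fit_band[2])
  f <- spec$freq[inb]
  p <- spec$power[inb]
  fc <- f - mean(f)
  slope <- sum(fc * p) / sum(fc^2)
  intercept <- mean(p) - slope * mean(f)
  f_mid <- mean(fit_band)
  list(slope = slope, intercept = intercept,
       midbandfit = slope * f_mid + intercept, f_mid = f_mid)
}

# Band index (1..4) of each frequency: four equal quarters of [0, 0.5],
# bin centers exactly on an edge go to the lower band.
band_index <- function(freq) {
  b <- ceiling(freq / 0.125 - 1e-9)
  pmin(pmax(b, 1L), 4L)
}

#' Four-band spectral energies S1-S4
#'
#' Splits the normalized frequency band `[0, 0.5]` into four equal-width
#' sub-bands and sums the linear-scale power in each. Bins whose center
#' falls exactly on a band edge are assigned to the lower band. The four
#' sums always partition the total linear-scale power.
#'
#' @param spec An [rf_spectrum()] with at least 4 bins.
#' @return Named numeric vector `c(s1, s2, s3, s4)`.
#' @export
band_energies <- function(spec) {
  if (!inherits(spec, "rf_spectrum")) stop_validation("`spec` must be an rf_spectrum")
  if (length(spec$freq) < 4) stop_validation("spectrum must have >= 4 bins")
  b <- band_index(spec$freq)
  s <- vapply(1:4, function(i) sum(spec$power_linear[b == i]), 0)
  names(s) <- c("s1", "s2", "s3", "s4")
  s
}

## ---------------------------------------------------------------------------
## Time-domain features
## ---------------------------------------------------------------------------

#' Fuzzy entropy of a series
#'
#' Regularity statistic `-ln(Phi_{m+1} / Phi_m)` where `Phi_m` is the mean
#' exponential similarity `exp(-(d/r)^gradient)` over all pairs of
#' baseline-removed template vectors of length `m` (Chebyshev distance
#' `d`), with tolerance `r = r_factor * sd(x)`. Lower values indicate a
#' more regular (self-similar) signal.
#'
#' @param x Numeric series, length > `m + 1`, not constant.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of the series SD (default 0.2).
#' @param gradient Membership exponent (default 2).
#' @return Nonnegative scalar (up to numerical error).
#' @export
fuzzy_entropy <- function(x, m = 2, r_factor = 0.2, gradient = 2) {
  if (!is.numeric(x) || length(x) <= m + 1)
    stop_validation("series length must exceed m + 1 = %d", m + 1)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_degenerate("constant series gives zero fuzzy-entropy tolerance")
  cpp_fuzzyen(as.numeric(x), as.integer(m), r_factor * s, gradient)
}

#' Kurtosis of a series
#'
#' Fourth-moment peakedness statistic under three conventions:
#' `"pearson"` is the fourth standardized moment `m4 / m2^2` (population
#' moments; 3 for a Gaussian), `"excess"` subtracts 3, and `"normalized"`
#' divides the Pearson value by the Gaussian reference 3, so Gaussian
#' white noise scores 1.
#'
#' @param x Numeric series, length >= 4, nonzero variance.
#' @param convention One of `"pearson"`, `"excess"`, `"normalized"`.
#' @return Scalar with attribute `convention`.
#' @export
kurtosis <- function(x, convention = c("pearson", "excess", "normalized")) {
  convention <- match.arg(convention)
  if (!is.numeric(x) || length(x) < 4)
    stop_validation("series must be numeric with length >= 4")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) stop_degenerate("zero variance")
  k <- mean(xc^4) / m2^2
  k <- switch(convention, pearson = k, excess = k - 3, normalized = k / 3)
  structure(k, convention = convention)
}

#' Peak amplitude of a series
#'
#' Maximum absolute amplitude of the raw (pre-mean-removal) trace.
#' Homogeneous of degree one: `peak_amplitude(c * x) == abs(c) * peak_amplitude(x)`.
#'
#' @param x Nonempty numeric series.
#' @return Nonnegative scalar.
#' @export
peak_amplitude <- function(x) {
  if (!is.numeric(x) || length(x) == 0)
    stop_validation("series must be a nonempty numeric vector")
  max(abs(x))
}

# Strict sign changes of one mean-removed series; zeros inherit the
# previous sign, so crossings are counted between consecutive nonzero
# samples of opposite sign.
count_crossings <- function(v) {
  s <- sign(v[v != 0])
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Zero-crossing statistics of a time-series block
#'
#' Counts strict sign changes of each mean-removed series (zeros inherit
#' the previous sign), then reports the mean count over the block's series
#' and the population SD of the per-series counts, both on the configured
#' scale: `"log10"` (default) transforms each count `c` to `log10(c + 1)`
#' before aggregating, `"raw"` uses plain counts.
#'
#' @param block A `TimeSeriesBlock` (see [extract_roi_block()]).
#' @param scale `"log10"` or `"raw"`.
#' @return List with `cross_zero_count` (mean) and `cross_zero_std`
#'   (population SD), plus the per-series `counts_raw`.
#' @export
zero_crossing_stats <- function(block, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  if (!inherits(block, "TimeSeriesBlock"))
    stop_validation("`block` must be a TimeSeriesBlock")
  counts <- apply(block$series, 1L, count_crossings)
  v <- if (scale == "log10") log10(counts + 1) else as.numeric(counts)
  list(cross_zero_count = mean(v),
       cross_zero_std = sqrt(mean((v - mean(v))^2)),
       counts_raw = counts)
}

## ---------------------------------------------------------------------------
## Full 14-parameter extraction
## ---------------------------------------------------------------------------

#' Extract the fourteen characteristic parameters of an ROI
#'
#' Computes every per-series feature for each RF time series of the block
#' and averages over series; `cross_zero_std` is the across-series SD of
#' the (scaled) crossing counts. Series failing the degenerate-input guard
#' (zero variance, or zero spectral power after windowing) are skipped,
#' never imputed; the skip count travels with the result. Fractal
#' dimensions are averaged after clipping to `[1, 2]`; the count of
#' clipped series and the unclipped means are attached as attributes.
#'
#' @param block A `TimeSeriesBlock`.
#' @param cfg A [feature_config()].
#' @return A `FeatureVector`: named numeric vector of the 14 parameters in
#'   [FEATURE_NAMES] order, with attributes `skip_count`, `n_series_used`,
#'   `fd_clip_count`, `fd_raw_means` and `config`.
#' @export
extract_feature_vector <- function(block, cfg = feature_config()) {
  if (!inherits(block, "TimeSeriesBlock"))
    stop_validation("`block` must be a TimeSeriesBlock")
  if (!inherits(cfg, "FeatureConfig"))
    stop_validation("`cfg` must be a FeatureConfig")
  n <- block$n_frames
  if (cfg$kmax >= n / 2 || cfg$tau_max >= n / 2)
    stop_validation("kmax and tau_max must be below n_frames / 2 = %g", n / 2)
  if (n <= cfg$fuzzy_m + 1 || n < 8)
    stop_validation("block too short (%d frames) for the configured features", n)

  mat <- block$series
  w <- hann_window(n)
  # degenerate guard: zero temporal variance, or zero windowed power
  varz <- rowSums(mat^2) == 0
  Fm <- stats::mvfft(w * t(mat))
  nh <- floor(n / 2) + 1L
  P <- Mod(Fm[seq_len(nh), , drop = FALSE])^2
  tot <- colSums(P)
  degen <- varz | tot == 0
  skip_count <- sum(degen)
  if (skip_count == block$n_series)
    stop(structure(class = c("rfseries_extraction_error", "error", "condition"),
                   list(message = "all series in the block are degenerate",
                        call = NULL)))
  ok <- !degen
  mat <- mat[ok, , drop = FALSE]
  P <- sweep(P[, ok, drop = FALSE], 2L, tot[ok], "/")
  freq <- (seq_len(nh) - 1) / n

  # fractal dimensions
  hig_raw <- block_higuchi_fd(mat, cfg$kmax)
  sfd_raw <- block_sf_fd(mat, cfg$tau_max)
  fd_clip_count <- sum(hig_raw < 1 | hig_raw > 2, na.rm = TRUE) +
    sum(sfd_raw < 1 | sfd_raw > 2, na.rm = TRUE)

  # spectral line fit (per series, shared design)
  Pwork <- if (cfg$spectrum_log) log10(pmax(P, cfg$spectrum_eps)) else P
  inb <- freq >= cfg$fit_band[1] & freq <= cfg$fit_band[2]
  if (sum(inb) < 3)
    stop_validation("fewer than 3 spectrum bins inside the fitting band")
  f <- freq[inb]
  fc <- f - mean(f)
  slopes <- as.vector(crossprod(Pwork[inb, , drop = FALSE], fc)) / sum(fc^2)
  intercepts <- colMeans(Pwork[inb, , drop = FALSE]) - slopes * mean(f)
  f_mid <- mean(cfg$fit_band)
  midband <- slopes * f_mid + intercepts

  # band energies on the linear scale
  b <- band_index(freq)
  S <- t(rowsum(P, b))                       # n_series x 4
  if (ncol(S) < 4) {                         # very short series: missing bands
    S4 <- matrix(0, nrow(S), 4)
    S4[, as.integer(colnames(S))] <- S
    S <- S4
  }

  # time domain
  fe <- cpp_fuzzyen_block(mat, cfg$fuzzy_m, cfg$fuzzy_r_factor,
                          cfg$fuzzy_gradient)
  m2 <- rowMeans(mat^2)
  kur <- rowMeans(mat^4) / m2^2
  kur <- switch(cfg$kurtosis_convention,
                pearson = kur, excess = kur - 3, normalized = kur / 3)
  raw <- mat + block$series_mean[ok]
  pk <- apply(abs(raw), 1L, max)
  counts <- apply(mat, 1L, count_crossings)
  cz <- if (cfg$crossing_scale == "log10") log10(counts + 1) else as.numeric(counts)

  out <- c(
    higuchi_fd = mean(clip_fd(hig_raw), na.rm = TRUE),
    sfd = mean(clip_fd(sfd_raw), na.rm = TRUE),
    slope = mean(slopes), intercept = mean(intercepts),
    midbandfit = mean(midband),
    s1 = mean(S[, 1]), s2 = mean(S[, 2]), s3 = mean(S[, 3]), s4 = mean(S[, 4]),
    fuzzy_entropy = mean(fe, na.rm = TRUE),
    peak = mean(pk),
    kurtosis = mean(kur),
    cross_zero_count = mean(cz),
    cross_zero_std = sqrt(mean((cz - mean(cz))^2)))
  stopifnot(identical(names(out), FEATURE_NAMES))
  structure(out, class = "FeatureVector",
            skip_count = skip_count, n_series_used = sum(ok),
            fd_clip_count = fd_clip_count,
            fd_raw_means = c(higuchi = mean(hig_raw, na.rm = TRUE),
                             sfd = mean(sfd_raw, na.rm = TRUE)),
            config = cfg)
}

#' Extract a feature table from a simulated or loaded cohort
#'
#' Runs [extract_roi_block()] and [extract_feature_vector()] for every
#' cohort record and assembles the subjects x features table consumed by
#' the statistics stage.
#'
#' @param cohort List of records with `subject_id`, `label`, `sequence`,
#'   `roi` (as returned by [simulate_cohort()]).
#' @param cfg A [feature_config()].
#' @param n_frames_used Frames used per subject (default: all available).
#' @return A data.frame with columns `subject_id`, `label`, the 14
#'   features in [FEATURE_NAMES] order, and `skip_count`.
#' @export
extract_features_cohort <- function(cohort, cfg = feature_config(),
                                    n_frames_used = NULL) {
  rows <- lapply(cohort, function(rec) {
    nf <- n_frames_used %||% rec$sequence$n_frames
    blk <- extract_roi_block(rec$sequence, rec$roi, nf,
                             subject_id = rec$subject_id)
    fv <- extract_feature_vector(blk, cfg)
    cbind(data.frame(subject_id = rec$subject_id, label = rec$label,
                     stringsAsFactors = FALSE),
          as.data.frame(t(unclass(fv)[FEATURE_NAMES])),
          data.frame(skip_count = attr(fv, "skip_count")))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
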