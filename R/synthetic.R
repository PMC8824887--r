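#' Tissue-class parameters for the RF simulator
#'
#' Each simulated tissue class is defined by the temporal statistics of its
#' per-pixel RF time series, not by spatial texture: the fourteen
#' characteristic parameters are computed on per-pixel series, so the
#' temporal axis is the one the analysis actually measures. A pixel's
#' series is a static speckle baseline plus a mixture of three fluctuation
#' components:
#'
#' * a fractional-Brownian-motion path (cumulated exact fractional
#'   Gaussian noise) with Hurst exponent `hurst`, giving the series a
#'   target fractal dimension of `2 - hurst`;
#' * a stationary AR(1) drift with lag-1 coefficient `ar_coeff`;
#' * additive white noise.
#'
#' @param hurst Hurst exponent in (0, 1). Lower values give rougher series
#'   (higher fractal dimension).
#' @param ar_coeff Lag-1 autoregressive coefficient in (-1, 1) of the slow
#'   drift component.
#' @param amplitude_scale Dimensionless multiplier on the RF amplitude
#'   (baseline and structured fluctuation).
#' @param noise_sd Additive white-noise standard deviation, raw amplitude
#'   units.
#' @param fbm_sd,ar_sd Standard deviations (raw amplitude units, before
#'   `amplitude_scale`) of one fBm increment and of the AR(1) component.
#' @return A `TissueClassParams` list.
#' @examples
#' tissue_class_params(hurst = 0.3)  # rough, tumor-like dynamics
#' @export
tissue_class_params <- function(hurst, ar_coeff = 0.6, amplitude_scale = 1,
                                noise_sd = 5, fbm_sd = 60, ar_sd = 15) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_validation("`hurst` must lie strictly inside (0, 1), got %s",
                    format(hurst))
  if (!is.numeric(ar_coeff) || abs(ar_coeff) >= 1)
    stop_validation("`ar_coeff` must lie strictly inside (-1, 1)")
  if (amplitude_scale <= 0) stop_validation("`amplitude_scale` must be > 0")
  if (noise_sd < 0) stop_validation("`noise_sd` must be >= 0")
  if (fbm_sd < 0 || ar_sd < 0) stop_validation("component SDs must be >= 0")
  structure(list(hurst = hurst, ar_coeff = ar_coeff,
                 amplitude_scale = amplitude_scale, noise_sd = noise_sd,
                 fbm_sd = fbm_sd, ar_sd = ar_sd),
            class = "TissueClassParams")
}

#' Simulation parameters
#'
#' Defaults reproduce the reference acquisition geometry: 256 frames
#' recorded over 20 s of a held transvaginal probe at 6 MHz center
#' frequency and 10 cm depth, with a 70 x 20 pixel ROI (1 pixel per mm)
#' centered on a 128 x 64 grid, i.e. 1400 per-pixel time series per
#' subject. The two default classes differ in Hurst exponent
#' (tumor 0.3, normal 0.8), so the tumor class has the higher fractal
#' dimension.
#'
#' @param n_frames Frames per sequence (>= 2).
#' @param n_lines,n_samples Grid size (scan lines x depth samples).
#' @param scatterers_per_cell Mean scatterer count per depth-sample cell of
#'   the speckle field.
#' @param pulse_fractional_bandwidth Fractional -6 dB bandwidth of the
#'   Gaussian-modulated transmit pulse.
#' @param classes Named list of [tissue_class_params()].
#' @param center_frequency_hz,sampling_rate_hz,depth_cm Acquisition
#'   metadata copied into every simulated sequence.
#' @param acquisition_s Wall-clock duration of the recording; sets the
#'   frame rate `n_frames / acquisition_s`.
#' @param roi_lines,roi_samples Size of the centered ROI attached to each
#'   simulated subject.
#' @param seed Default master seed.
#' @return A `SimParams` list.
#' @export
sim_params <- function(n_frames = 256, n_lines = 128, n_samples = 64,
                       scatterers_per_cell = 4,
                       pulse_fractional_bandwidth = 0.5,
                       classes = list(
                         tumor = tissue_class_params(hurst = 0.3),
                         normal = tissue_class_params(hurst = 0.8)),
                       center_frequency_hz = 6e6, sampling_rate_hz = 40e6,
                       depth_cm = 10, acquisition_s = 20,
                       roi_lines = 70, roi_samples = 20, seed = 1L) {
  if (!is_count(n_frames) || n_frames < 2)
    stop_validation("`n_frames` must be an integer >= 2")
  if (!is_count(n_lines) || n_lines < 1 || !is_count(n_samples) || n_samples < 1)
    stop_validation("grid dimensions must be positive integers")
  if (length(classes) < 1 || is.null(names(classes)) || any(!nzchar(names(classes))))
    stop_usage("`classes` must be a non-empty named list")
  for (cl in classes)
    if (!inherits(cl, "TissueClassParams"))
      stop_validation("every class must be a TissueClassParams")
  if (roi_lines > n_lines || roi_samples > n_samples)
    stop_validation("ROI (%d x %d) does not fit the %d x %d grid",
                    roi_lines, roi_samples, n_lines, n_samples)
  structure(list(
    n_frames = as.integer(n_frames), n_lines = as.integer(n_lines),
    n_samples = as.integer(n_samples),
    scatterers_per_cell = scatterers_per_cell,
    pulse_fractional_bandwidth = pulse_fractional_bandwidth,
    classes = classes,
    center_frequency_hz = center_frequency_hz,
    sampling_rate_hz = sampling_rate_hz, depth_cm = depth_cm,
    acquisition_s = acquisition_s,
    roi_lines = as.integer(roi_lines), roi_samples = as.integer(roi_samples),
    seed = as.integer(seed)
  ), class = "SimParams")
}

# fGn autocovariance gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H) / 2
fgn_autocov <- function(hurst, lags) {
  (abs(lags + 1)^(2 * hurst) - 2 * abs(lags)^(2 * hurst) +
     abs(lags - 1)^(2 * hurst)) / 2
}

# k independent exact fGn paths of length n as a k x n matrix (no seeding;
# caller controls the RNG). Circulant embedding: the 2n x 2n circulant
# with first row [g0..gn, g(n-1)..g1] has eigenvalues fft(row); complex
# Gaussian noise shaped by sqrt(eigenvalues) and inverse-transformed gives
# a Gaussian vector with exactly the fGn covariance.
fgn_matrix <- function(hurst, n, k) {
  if (n < 2) stop_validation("`n` must be >= 2")
  g <- fgn_autocov(hurst, 0:n)
  row <- c(g, g[n:2])                      # length 2n
  lam <- Re(fft(row))
  m <- length(row)
  if (min(lam) < -1e-8 * max(lam)) {
    # embedding not nonnegative definite at this n: exact dense factorization
    message(sprintf(
      "circulant embedding not nonnegative definite (min eigenvalue %.3g); using dense factorization",
      min(lam)))
    return(fgn_matrix_dense(hurst, n, k))
  }
  lam <- pmax(lam, 0)
  eps <- matrix(stats::rnorm(m * k), m, k) + 1i * matrix(stats::rnorm(m * k), m, k)
  y <- stats::mvfft(sqrt(lam) * eps, inverse = TRUE) / sqrt(m)
  t(Re(y[seq_len(n), , drop = FALSE]))
}

# Exact dense-factorization fallback (and test oracle), O(n^3).
fgn_matrix_dense <- function(hurst, n, k) {
  S <- fgn_autocov(hurst, abs(outer(seq_len(n), seq_len(n), "-")))
  L <- chol(S)
  matrix(stats::rnorm(k * n), k, n) %*% L
}

#' Exact fractional Gaussian noise
#'
#' Generates a stationary, unit-variance fractional Gaussian noise series
#' with Hurst exponent `hurst` by circulant embedding of the exact
#' autocovariance, so the sample has the theoretical covariance
#' `gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2` exactly (not
#' asymptotically). The cumulative sum of the output is a fractional
#' Brownian motion path with fractal dimension `2 - hurst`.
#'
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param n Series length (>= 2).
#' @param seed Integer seed; the output is deterministic given `(hurst, n, seed)`
#'   and the caller's RNG state is left untouched.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- generate_fgn(0.8, 256, seed = 42)
#' fbm <- cumsum(x)  # rough path with fractal dimension ~ 1.2
#' @export
generate_fgn <- function(hurst, n, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || !is.finite(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_validation("`hurst` must lie strictly inside (0, 1), got %s",
                    format(hurst))
  if (!is_count(n) || n < 2) stop_validation("`n` must be an integer >= 2")
  with_seed(seed, drop(fgn_matrix(hurst, n, 1L)))
}

#' Simulate one RF frame sequence
#'
#' Builds a speckle baseline frame - a random scatterer field convolved
#' along depth with a Gaussian-modulated sinusoid at the configured center
#' frequency - and evolves every pixel over time with the class's mixture
#' of fBm (fractal component), AR(1) drift and white noise. The fluctuation
#' components are zero at the first frame, so frame 0 is the pure speckle
#' image. Output amplitudes are rounded and clipped to the signed 16-bit
#' range; the number of clipped samples is attached as attribute
#' `clip_count` and raises a warning when positive.
#'
#' @param params A [sim_params()].
#' @param class_label Name of an entry of `params$classes`.
#' @param seed Integer seed (defaults to `params$seed`). Identical
#'   `(params, class_label, seed)` give bit-identical output.
#' @return An [rf_sequence()].
#' @export
simulate_rf_sequence <- function(params, class_label, seed = params$seed) {
  if (!inherits(params, "SimParams"))
    stop_validation("`params` must be a SimParams")
  if (!class_label %in% names(params$classes))
    stop_usage("unknown class label `%s`; declared classes: %s", class_label,
               paste(names(params$classes), collapse = ", "))
  cl <- params$classes[[class_label]]
  nf <- params$n_frames; nl <- params$n_lines; ns <- params$n_samples
  npix <- nl * ns

  with_seed(seed, {
    base <- speckle_frame(nl, ns, params)            # n_lines x n_samples
    base <- base / stats::sd(as.vector(base)) * 2000 # raw RF amplitude scale

    # fluctuation components, one column per pixel, zero at frame 1
    fbm <- apply(fgn_matrix(cl$hurst, nf - 1L, npix), 1L, cumsum) # (nf-1) x npix
    fbm <- rbind(0, fbm)
    ar <- matrix(0, nf, npix)
    innov_sd <- sqrt(1 - cl$ar_coeff^2)
    e <- matrix(stats::rnorm((nf - 1L) * npix, sd = innov_sd), nf - 1L, npix)
    for (t in 2:nf) ar[t, ] <- cl$ar_coeff * ar[t - 1L, ] + e[t - 1L, ]
    wn <- rbind(0, matrix(stats::rnorm((nf - 1L) * npix), nf - 1L, npix))

    y <- matrix(rep(as.vector(base) * cl$amplitude_scale, each = nf), nf, npix) +
      cl$amplitude_scale * (cl$fbm_sd * fbm + cl$ar_sd * ar) +
      cl$noise_sd * wn
    y <- round(y)
    n_clip <- sum(y < -32768 | y > 32767)
    if (n_clip > 0) {
      warning(sprintf("%d sample(s) clipped to the signed 16-bit range", n_clip))
      y <- pmin(pmax(y, -32768), 32767)
    }
    out <- rf_sequence(array(y, dim = c(nf, nl, ns)),
                       center_frequency_hz = params$center_frequency_hz,
                       sampling_rate_hz = params$sampling_rate_hz,
                       frame_rate_hz = params$n_frames / params$acquisition_s,
                       depth_cm = params$depth_cm)
    attr(out, "clip_count") <- n_clip
    attr(out, "class_label") <- class_label
    out
  })
}

# One speckle frame: per scan line, Gaussian-amplitude scatterers binned to
# the depth grid, convolved with a Gaussian-modulated sinusoid.
speckle_frame <- function(n_lines, n_samples, params) {
  fc <- params$center_frequency_hz
  fs <- params$sampling_rate_hz
  # -6 dB fractional bandwidth -> Gaussian envelope SD in samples
  sigma_f <- params$pulse_fractional_bandwidth * fc / (2 * sqrt(2 * log(2)))
  sigma_t <- fs / (2 * pi * sigma_f)                      # samples
  half <- max(2L, ceiling(3 * sigma_t))
  tt <- seq(-half, half)
  pulse <- exp(-tt^2 / (2 * sigma_t^2)) * cos(2 * pi * fc / fs * tt)

  n_scat <- max(1L, round(params$scatterers_per_cell * n_samples))
  frame <- matrix(0, n_lines, n_samples)
  for (l in seq_len(n_lines)) {
    pos <- sample.int(n_samples, n_scat, replace = TRUE)
    amp <- stats::rnorm(n_scat)
    field <- numeric(n_samples)
    agg <- rowsum(amp, pos)
    field[as.integer(rownames(agg))] <- agg
    line <- stats::convolve(field, rev(pulse), type = "open")
    frame[l, ] <- line[half + seq_len(n_samples)]
  }
  frame
}

#' Simulate a cohort of subjects
#'
#' One seeded RF sequence plus a centered, labelled ROI per synthetic
#' subject. Per-subject sub-seeds are derived deterministically from the
#' master seed, so the whole cohort is reproducible from one integer while
#' subjects remain mutually independent.
#'
#' @param params A [sim_params()].
#' @param n_per_class Named integer vector/list, subjects per class label;
#'   all labels must exist in `params$classes`. Subjects are emitted in
#'   declared class order.
#' @param seed Master seed (defaults to `params$seed`).
#' @return A list of records, each with elements `subject_id`, `label`,
#'   `seed`, `sequence` (an `RFSequence`) and `roi` (an `ROISpec`).
#' @examples
#' p <- sim_params(n_frames = 16, n_lines = 8, n_samples = 8,
#'                 roi_lines = 4, roi_samples = 4)
#' cohort <- simulate_cohort(p, c(tumor = 2, normal = 1), seed = 7)
#' vapply(cohort, `[[`, "", "label")
#' @export
simulate_cohort <- function(params, n_per_class, seed = params$seed) {
  if (!inherits(params, "SimParams"))
    stop_validation("`params` must be a SimParams")
  n_per_class <- unlist(n_per_class)
  if (length(n_per_class) == 0 || is.null(names(n_per_class)))
    stop_usage("`n_per_class` must be a non-empty named vector")
  unknown <- setdiff(names(n_per_class), names(params$classes))
  if (length(unknown))
    stop_usage("unknown class label(s): %s", paste(unknown, collapse = ", "))
  if (any(n_per_class < 1) || any(n_per_class != round(n_per_class)))
    stop_validation("per-class counts must be integers >= 1")

  l0 <- (params$n_lines - params$roi_lines) %/% 2L
  s0 <- (params$n_samples - params$roi_samples) %/% 2L
  out <- list()
  idx <- 0L
  for (label in names(n_per_class)) {
    for (j in seq_len(n_per_class[[label]])) {
      idx <- idx + 1L
      sub_seed <- derive_subseed(seed, idx)
      out[[idx]] <- list(
        subject_id = sprintf("S%03d_%s", idx, label),
        label = label,
        seed = sub_seed,
        sequence = simulate_rf_sequence(params, label, seed = sub_seed),
        roi = roi_spec(l0, l0 + params$roi_lines, s0, s0 + params$roi_samples,
                       label = label))
    }
  }
  out
}
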