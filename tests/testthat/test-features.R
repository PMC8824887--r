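test_that("ROI block has one mean-removed series per pixel, line-major", {
  seq0 <- make_test_sequence(8, 6, 10, seed = 2)
  roi <- roi_spec(1, 4, 2, 7)
  blk <- extract_roi_block(seq0, roi, 8)
  expect_identical(blk$n_series, 3L * 5L)
  expect_identical(blk$n_frames, 8L)
  expect_equal(rowMeans(blk$series), rep(0, 15))
  # row (l, s) = (line - line_start) * roi_samples + (sample - sample_start) + 1
  for (l in 0:2) for (s in 0:4) {
    trace <- as.numeric(seq0$data[1:8, 1 + roi$line_start + l,
                                  1 + roi$sample_start + s])
    r <- l * 5 + s + 1
    expect_equal(blk$series[r, ], trace - mean(trace))
    expect_equal(blk$series_mean[r], mean(trace))
  }
})

test_that("ROI block validation: bounds, frame budget, degenerate pixels", {
  seq0 <- make_test_sequence(4, 4, 4)
  expect_error(extract_roi_block(seq0, roi_spec(0, 8, 0, 2)),
               "exceeds sequence bounds")
  expect_error(extract_roi_block(seq0, roi_spec(0, 2, 0, 2), 1), ">= 2")
  # constant pixels are annihilated by mean removal
  const <- rf_sequence(array(7L, c(4, 2, 2)), 6e6, 40e6, 1, 10)
  blk <- extract_roi_block(const, roi_spec(0, 2, 0, 2))
  expect_true(all(blk$series == 0))
})

test_that("Higuchi and structure-function FD match theory on canonical signals", {
  ramp <- seq(0, 255)
  expect_equal(as.numeric(higuchi_fd(ramp)), 1, tolerance = 0.05)
  expect_equal(as.numeric(structure_function_fd(ramp)), 1, tolerance = 1e-6)

  wn <- withr::with_seed(8, matrix(rnorm(200 * 256), 200, 256))
  expect_equal(mean(rfseries:::block_higuchi_fd(wn, 8)), 2, tolerance = 0.1)
  expect_equal(mean(rfseries:::block_sf_fd(wn, 16)), 2, tolerance = 0.1)

  fbm <- withr::with_seed(9, t(apply(rfseries:::fgn_matrix(0.8, 256, 200),
                                     1, cumsum)))
  expect_equal(mean(rfseries:::block_higuchi_fd(fbm, 8)), 1.2,
               tolerance = 0.15)
  expect_equal(mean(rfseries:::block_sf_fd(fbm, 16)), 1.2, tolerance = 0.15)
})

test_that("FD estimators guard their domain", {
  expect_error(higuchi_fd(rep(3, 64)), class = "rfseries_degenerate_error")
  expect_error(structure_function_fd(rep(3, 64)),
               class = "rfseries_degenerate_error")
  expect_error(higuchi_fd(rnorm(64), kmax = 40), "kmax")
  expect_error(higuchi_fd(rnorm(10), kmax = 8), "length")
})

test_that("vectorized curve lengths and structure functions match naive oracles", {
  withr::with_seed(17, {
    for (rep in 1:8) {
      n <- sample(16:32, 1)
      x <- rnorm(n)
      kmax <- sample(2:6, 1)
      expect_equal(as.numeric(rfseries:::block_higuchi_lengths(matrix(x, 1), kmax)),
                   oracle_higuchi_lengths(x, kmax), tolerance = 1e-12)
      tau_max <- sample(2:7, 1)
      S <- matrix(0, 1, tau_max)
      for (tau in seq_len(tau_max))
        S[1, tau] <- mean((x[(1 + tau):n] - x[1:(n - tau)])^2)
      expect_equal(as.numeric(S), oracle_structure_function(x, tau_max),
                   tolerance = 1e-12)
    }
  })
})

test_that("power spectrum is normalized, peak-locating, and guarded", {
  cfg <- feature_config(spectrum_log = FALSE)
  x <- sin(2 * pi * 0.25 * seq_len(256))
  sp <- power_spectrum(x, cfg)
  expect_equal(sp$freq[which.max(sp$power)], 0.25, tolerance = 1 / 256)
  expect_equal(sum(sp$power), 1, tolerance = 1e-9)
  expect_equal(sum(power_spectrum(rnorm(128), cfg)$power), 1, tolerance = 1e-9)
  expect_error(power_spectrum(rep(0, 64), cfg),
               class = "rfseries_degenerate_error")
  # constant series has zero power after mean removal
  expect_error(power_spectrum(rep(5, 64), cfg),
               class = "rfseries_degenerate_error")
})

test_that("spectral line fit recovers exact linear spectra to float precision", {
  f <- seq(0, 0.5, length.out = 64)
  spec <- rf_spectrum(f, -0.32 * f + 0.48, units_log = TRUE)
  fit <- spectral_line_fit(spec, c(0, 0.5))
  expect_equal(fit$slope, -0.32, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.48, tolerance = 1e-12)
  expect_equal(fit$midbandfit, -0.32 * 0.25 + 0.48, tolerance = 1e-12)
  # flat spectrum
  flat <- rf_spectrum(f, rep(0.7, 64))
  fitf <- spectral_line_fit(flat)
  expect_equal(fitf$slope, 0, tolerance = 1e-12)
  expect_equal(fitf$midbandfit, 0.7, tolerance = 1e-12)
  expect_error(spectral_line_fit(spec, c(0, 0.005)), "fewer than 3")
})

test_that("seed-averaged white-noise spectrum is flat", {
  cfg <- feature_config(spectrum_log = FALSE)
  acc <- withr::with_seed(12, {
    p <- 0
    for (i in 1:200) p <- p + power_spectrum(rnorm(128), cfg)$power
    p / 200
  })
  fit <- spectral_line_fit(rf_spectrum((0:64) / 128, acc))
  expect_lt(abs(fit$slope), 0.02)
})

test_that("band energies partition the spectrum with ties to the lower band", {
  f <- (0:127) / 256 + 1 / 512   # 128 bin centers inside (0, 0.5)
  s <- band_energies(rf_spectrum(f, rep(1, 128)))
  expect_equal(unname(s), c(32, 32, 32, 32))
  imp <- rep(0, 128); imp[10] <- 1
  expect_equal(unname(band_energies(rf_spectrum(f, imp))), c(1, 0, 0, 0))
  # a bin exactly on the 0.125 edge goes to the lower band
  edge <- rf_spectrum(c(0.1, 0.125, 0.2, 0.4), c(0, 1, 0, 0))
  expect_equal(unname(band_energies(edge)), c(1, 0, 0, 0))
  # conservation on arbitrary spectra
  withr::with_seed(4, {
    p <- runif(100)
    sp <- rf_spectrum(sort(runif(100, 0, 0.5)), p)
    expect_equal(sum(band_energies(sp)), sum(p), tolerance = 1e-9)
  })
})

test_that("fuzzy entropy: regular signals score near zero, monotone in r", {
  x <- 1 + seq_len(128) * 1e-4
  expect_equal(fuzzy_entropy(x), 0, tolerance = 0.05)
  y <- withr::with_seed(3, rnorm(128))
  expect_lte(fuzzy_entropy(y, r_factor = 0.4), fuzzy_entropy(y, r_factor = 0.2))
  expect_error(fuzzy_entropy(rep(2, 64)), class = "rfseries_degenerate_error")
})

test_that("fuzzy entropy matches a naive double-loop oracle on short series", {
  withr::with_seed(44, {
    for (rep in 1:5) {
      x <- rnorm(sample(20:32, 1))
      r <- 0.2 * sd(x)
      expect_equal(fuzzy_entropy(x, m = 2, r_factor = 0.2, gradient = 2),
                   oracle_fuzzyen(x, 2, r, 2), tolerance = 1e-12)
      expect_equal(fuzzy_entropy(x, m = 3, r_factor = 0.3, gradient = 3),
                   oracle_fuzzyen(x, 3, 0.3 * sd(x), 3), tolerance = 1e-12)
    }
  })
})

test_that("Pearson kurtosis agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(45, {
    for (rep in 1:5) {
      x <- rnorm(100) + rexp(100)
      expect_equal(as.numeric(kurtosis(x, "pearson")),
                   e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-12)
    }
  })
})

test_that("white noise has higher fuzzy entropy than strongly regular AR(1)", {
  withr::with_seed(21, {
    d <- vapply(1:60, function(i) {
      wn <- rnorm(256)
      ar <- as.numeric(stats::filter(rnorm(256), 0.9, method = "recursive"))
      fuzzy_entropy(wn) - fuzzy_entropy(ar)
    }, 0)
    expect_gt(mean(d), 0)
    expect_gt(mean(d) / (sd(d) / sqrt(length(d))), 3)  # clearly separated
  })
})

test_that("kurtosis conventions agree with closed forms", {
  alt <- rep(c(1, -1), 128)
  expect_equal(as.numeric(kurtosis(alt)), 1, tolerance = 1e-12)
  expect_equal(as.numeric(kurtosis(alt, "excess")), -2, tolerance = 1e-12)
  expect_equal(as.numeric(kurtosis(alt, "normalized")), 1 / 3, tolerance = 1e-12)
  g <- withr::with_seed(10, colMeans(matrix(
    vapply(1:500, function(i) as.numeric(kurtosis(rnorm(256))), 0), nrow = 500)))
  expect_equal(mean(g), 3, tolerance = 0.1)
  expect_error(kurtosis(rep(1, 10)), class = "rfseries_degenerate_error")
})

test_that("peak amplitude is max-abs and homogeneous", {
  expect_identical(peak_amplitude(c(-3, 2)), 3)
  expect_identical(peak_amplitude(rep(0, 5)), 0)
  x <- withr::with_seed(2, rnorm(50))
  expect_equal(peak_amplitude(-2.5 * x), 2.5 * peak_amplitude(x))
})

test_that("zero-crossing stats: alternation, ramps and arithmetic", {
  blk_of <- function(mat) structure(
    list(series = mat - rowMeans(mat), series_mean = rowMeans(mat),
         n_series = nrow(mat), n_frames = ncol(mat),
         provenance = list()), class = "TimeSeriesBlock")
  alt <- matrix(rep(c(1, -1), 128), 4, 256, byrow = TRUE)
  zs <- zero_crossing_stats(blk_of(alt), scale = "raw")
  expect_identical(unname(zs$counts_raw), rep(255L, 4))
  expect_identical(zs$cross_zero_std, 0)
  ramp <- matrix(seq(-1, 1, length.out = 64), 1)
  expect_identical(zero_crossing_stats(blk_of(ramp), "raw")$counts_raw[[1]], 1L)
  zs2 <- zero_crossing_stats(blk_of(rbind(c(1, -1, 1, 2, 2, 2, 2, 2) - 1.25,
                                          c(1, -1, 1, -1, 1, 2, 2, 2) - 0.625)),
                             "raw")
  expect_equal(zs2$cross_zero_count, mean(zs2$counts_raw))
  expect_equal(zs2$cross_zero_std,
               sqrt(mean((zs2$counts_raw - mean(zs2$counts_raw))^2)))
  # log10 scale default
  zl <- zero_crossing_stats(blk_of(alt))
  expect_equal(zl$cross_zero_count, log10(256))
})

test_that("feature vector: 14 finite values, deterministic, midband identity", {
  p <- small_sim_params()
  s <- simulate_rf_sequence(p, "tumor", seed = 5)
  blk <- extract_roi_block(s, roi_spec(4, 12, 3, 8))
  cfg <- feature_config(kmax = 6, tau_max = 8)
  fv <- extract_feature_vector(blk, cfg)
  expect_identical(names(fv), FEATURE_NAMES)
  expect_length(unclass(fv), 14)
  expect_true(all(is.finite(fv)))
  expect_identical(unclass(fv), unclass(extract_feature_vector(blk, cfg)))
  # exact midband identity survives per-series averaging
  expect_equal(fv[["midbandfit"]],
               fv[["slope"]] * 0.25 + fv[["intercept"]], tolerance = 1e-12)
  # band sums partition unit normalized power
  expect_equal(fv[["s1"]] + fv[["s2"]] + fv[["s3"]] + fv[["s4"]], 1,
               tolerance = 1e-9)
})

test_that("degenerate series are skipped and counted, never imputed", {
  p <- small_sim_params()
  s <- simulate_rf_sequence(p, "tumor", seed = 6)
  # freeze a pixel over time: its series is constant
  s$data[, 5, 4] <- 100L
  blk <- extract_roi_block(s, roi_spec(4, 12, 3, 8))
  fv <- extract_feature_vector(blk, feature_config(kmax = 6, tau_max = 8))
  expect_identical(attr(fv, "skip_count"), 1L)
  expect_identical(attr(fv, "n_series_used"), blk$n_series - 1L)
  expect_true(all(is.finite(fv)))
  # an all-degenerate block is an extraction error
  const <- rf_sequence(array(7L, c(64, 4, 4)), 6e6, 40e6, 1, 10)
  cblk <- extract_roi_block(const, roi_spec(0, 4, 0, 4))
  expect_error(extract_feature_vector(cblk, feature_config(kmax = 6, tau_max = 8)),
               class = "rfseries_extraction_error")
})

test_that("feature extraction is invariant to amplitude sign flip", {
  p <- small_sim_params()
  s <- simulate_rf_sequence(p, "normal", seed = 11)
  blk <- extract_roi_block(s, roi_spec(4, 12, 3, 8))
  flipped <- blk
  flipped$series <- -blk$series
  flipped$series_mean <- -blk$series_mean
  cfg <- feature_config(kmax = 6, tau_max = 8)
  expect_equal(unclass(extract_feature_vector(blk, cfg)),
               unclass(extract_feature_vector(flipped, cfg)),
               tolerance = 1e-9)
})

test_that("raw FD estimates on simulator output stay near [1, 2] and clips are logged", {
  p <- small_sim_params()
  for (lab in c("tumor", "normal")) {
    s <- simulate_rf_sequence(p, lab, seed = 13)
    blk <- extract_roi_block(s, roi_spec(4, 12, 3, 8))
    hig <- rfseries:::block_higuchi_fd(blk$series, 6)
    sfd <- rfseries:::block_sf_fd(blk$series, 8)
    expect_true(all(hig > 0.9 & hig < 2.1))
    expect_true(all(sfd > 0.9 & sfd < 2.1))
    fv <- extract_feature_vector(blk, feature_config(kmax = 6, tau_max = 8))
    expect_identical(attr(fv, "fd_clip_count"),
                     sum(hig < 1 | hig > 2) + sum(sfd < 1 | sfd > 2))
  }
})

test_that("tumor (low hurst) subjects score higher FD than normal through the pipeline", {
  p <- small_sim_params()
  cfg <- feature_config(kmax = 6, tau_max = 8)
  fd <- function(lab, seeds) colMeans(do.call(rbind, lapply(seeds, function(sd) {
    s <- simulate_rf_sequence(p, lab, seed = sd)
    fv <- extract_feature_vector(extract_roi_block(s, roi_spec(4, 12, 3, 8)), cfg)
    fv[c("higuchi_fd", "sfd")]
  })))
  tum <- fd("tumor", 1:8); nor <- fd("normal", 101:108)
  expect_gt(tum[["higuchi_fd"]], nor[["higuchi_fd"]])
  expect_gt(tum[["sfd"]], nor[["sfd"]])
})
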