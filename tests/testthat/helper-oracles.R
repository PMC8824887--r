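# Independent brute-force oracles used to cross-check the package's
# vectorized implementations. Deliberately naive: explicit loops, no
# shared code with the package internals.

# Higuchi normalized curve lengths L(k), one scalar per k, double loop.
oracle_higuchi_lengths <- function(x, kmax) {
  n <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      ng <- floor((n - m) / k)
      s <- 0
      for (i in seq_len(ng)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lm[m] <- (s * (n - 1) / (ng * k)) / k
    }
    L[k] <- mean(lm)
  }
  L
}

# Second-order structure function S(tau), double loop.
oracle_structure_function <- function(x, tau_max) {
  n <- length(x)
  S <- numeric(tau_max)
  for (tau in seq_len(tau_max)) {
    s <- 0
    for (t in seq_len(n - tau)) s <- s + (x[t + tau] - x[t])^2
    S[tau] <- s / (n - tau)
  }
  S
}

# Pooled-variance two-sample t statistic and df from explicit sums.
oracle_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  m1 <- sum(x) / n1; m2 <- sum(y) / n2
  ss1 <- sum((x - m1)^2); ss2 <- sum((y - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  tval <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tval, df = n1 + n2 - 2,
       p = 2 * stats::pt(-abs(tval), n1 + n2 - 2))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(groups) {
  all_x <- unlist(groups)
  gm <- mean(all_x)
  k <- length(groups)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1; df2 <- length(all_x) - k
  fval <- (ssb / df1) / (ssw / df2)
  list(f = fval, df1 = df1, df2 = df2,
       p = stats::pf(fval, df1, df2, lower.tail = FALSE))
}

# Naive fuzzy entropy: explicit loops over template pairs, absolute
# tolerance r, exponential membership.
oracle_fuzzyen <- function(x, m, r, grad) {
  N <- length(x)
  M <- N - m
  phi <- function(wlen) {
    sims <- numeric(0)
    for (i in seq_len(M)) for (j in seq_len(M)) if (i != j) {
      xi <- x[i:(i + wlen - 1)]; xi <- xi - mean(xi)
      xj <- x[j:(j + wlen - 1)]; xj <- xj - mean(xj)
      d <- max(abs(xi - xj))
      sims <- c(sims, exp(-(d / r)^grad))
    }
    mean(sims)
  }
  log(phi(m)) - log(phi(m + 1))
}

# fGn theoretical autocovariance.
oracle_fgn_autocov <- function(h, k) {
  (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h)) / 2
}

# Exact fGn sample by dense Cholesky factorization (oracle generator).
oracle_fgn_dense <- function(h, n, n_rep) {
  S <- outer(seq_len(n), seq_len(n),
             function(i, j) oracle_fgn_autocov(h, abs(i - j)))
  matrix(rnorm(n_rep * n), n_rep, n) %*% chol(S)
}

# Tiny RF sequence with reproducible integer amplitudes.
make_test_sequence <- function(n_frames = 4, n_lines = 8, n_samples = 16,
                               seed = 1) {
  withr::with_seed(seed, {
    data <- array(sample(-2000:2000, n_frames * n_lines * n_samples,
                         replace = TRUE),
                  dim = c(n_frames, n_lines, n_samples))
    rf_sequence(data, center_frequency_hz = 6e6, sampling_rate_hz = 40e6,
                frame_rate_hz = 12.8, depth_cm = 10)
  })
}

# Small desk-scale simulation geometry shared by several tests.
small_sim_params <- function(...) {
  sim_params(n_frames = 64, n_lines = 16, n_samples = 12,
             roi_lines = 8, roi_samples = 5, ...)
}
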