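# Independent reference implementations used as oracles. These are coded as
# plain loops, separately from the package internals, and deliberately kept
# naive.

# Literal local-maxima-scalogram peak detector: builds the full L x N matrix
# entry by entry with a random fill, sums rows, truncates at the lambda
# index, and reports columns whose standard deviation is exactly zero. The
# arbitrary-fill freedom in the lambda argmin is resolved by the zero-count
# row statistic, the only reading under which detection does not depend on
# the fill realisation.
ampd_reference <- function(x) {
  n <- length(x)
  L <- ceiling(n / 2) - 1
  m <- matrix(0, L, n)
  cnt <- integer(L)
  for (k in 1:L) {
    for (i in 1:n) {
      if (i - k >= 1 && i + k <= n && x[i] > x[i - k] && x[i] > x[i + k]) {
        m[k, i] <- 0
      } else {
        m[k, i] <- runif(1) + 1
      }
    }
  }
  for (k in 1:L) cnt[k] <- sum(m[k, ] != 0)
  lambda <- which.min(cnt)
  peaks <- integer(0)
  for (i in 1:n) {
    col <- m[seq_len(lambda), i]
    s <- if (lambda >= 2) sd(col) else abs(col[1])
    if (s == 0) peaks <- c(peaks, i)
  }
  peaks
}

# Quasi-periodic random test signal: a mixture of 1-3 sinusoids with random
# period, amplitude and phase plus mild noise, the signal class the
# multiscale detector is designed for.
random_quasiperiodic <- function() {
  n <- sample(16:64, 1)
  t <- seq_len(n)
  x <- numeric(n)
  for (h in seq_len(sample(1:3, 1))) {
    x <- x + runif(1, 0.5, 2) * sin(2 * pi * t / runif(1, 4, n / 2) + runif(1, 0, 2 * pi))
  }
  x + rnorm(n, 0, 0.05)
}

# Amplitude of the component of y at a known frequency, by least-squares
# projection on the sine/cosine pair over a central window (edges excluded).
sine_amplitude <- function(y, freq_hz, dt_ms, trim = 0.2) {
  n <- length(y)
  idx <- seq.int(floor(n * trim), ceiling(n * (1 - trim)))
  tt <- (idx - 1) * dt_ms / 1000
  fit <- stats::lm(y[idx] ~ sin(2 * pi * freq_hz * tt) + cos(2 * pi * freq_hz * tt))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

# ICC(2,1) oracle: mean squares from a two-way stats::aov fit on the long
# format, then the Shrout-Fleiss single-measure absolute-agreement formula
# and its F-based interval.
icc21_aov_oracle <- function(ratings, confidence = 0.95) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  long <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - confidence
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  list(
    icc = icc,
    ci_low = n * (msr - f_l * mse) / (f_l * (k * msc + (k * n - k - n) * mse) + n * msr),
    ci_high = n * (f_u * msr - mse) / (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  )
}

# Fixture battery for recovery tests: heart rates spanning 110-160 bpm with
# interval fractions perturbed +/-20% around the defaults, renormalised.
fixture_specs <- function(n_cases, noise_sd = 0, seed = 42) {
  set.seed(seed)
  hr <- runif(n_cases, 110, 160)
  mult <- matrix(runif(4 * n_cases, 0.8, 1.2), ncol = 4)
  lapply(seq_len(n_cases), function(r) {
    f <- c(0.08, 0.35, 0.10, 0.47) * mult[r, ]
    f <- f / sum(f)
    synth_spec(heart_rate_bpm = hr[r], frac_ivct = f[1], frac_et = f[2],
               frac_ivrt = f[3], frac_ft = f[4], noise_sd = noise_sd, seed = r)
  })
}

# Landmark recovery of one generated fixture through the default pipeline:
# worst landmark error in samples and the absolute TI/KI errors of the
# waveform means against the generator-implied values.
recovery_errors <- function(spec, cfg = pipeline_config()) {
  ge <- generate_envelope(spec)
  rep <- suppressWarnings(analyze_envelope(ge$signal, cfg))
  lm <- rep$per_cycle
  tr <- ge$truth
  ci <- vapply(lm$A_peak, function(a) which.min(abs(tr$A_peak - a)), integer(1))
  errs <- c()
  for (nm in c("FT_start", "E_peak", "A_peak", "FT_end", "ET_start", "ET_end")) {
    errs <- c(errs, (lm[[nm]] - tr[[nm]][ci]) / spec$dt_ms)
  }
  has_prev <- ci > 1
  errs <- c(errs, (lm$prev_ET_end[has_prev] - tr$ET_end[ci[has_prev] - 1L]) / spec$dt_ms)
  imp <- implied_mpi(spec)
  ti <- rep$summary$mean[rep$summary$measure == "TI"]
  ki <- rep$summary$mean[rep$summary$measure == "KI"]
  c(max_landmark_err = max(abs(errs)),
    ti_err = abs(ti - imp[["TI"]]),
    ki_err = abs(ki - imp[["KI"]]))
}
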