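# Shared fixtures and independent brute-force oracles. Oracles are written
# as literal transcriptions of the defining formulas (explicit loops, no
# shared code with the implementation) so that agreement is meaningful.

T0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")

make_series <- function(values, epoch = 60, start = T0) {
  epoch_series(start + epoch * (seq_along(values) - 1), values, epoch)
}

# literal double sum of the MLiT definition: loop over daily periods j and
# days k, indicator strictly above C
mlit_bruteforce <- function(values, epoch, C, start = T0) {
  m <- 86400 %/% epoch
  time <- as.numeric(start) + epoch * (seq_along(values) - 1)
  num <- 0; den <- 0
  for (i in seq_along(values)) {
    j <- (time[i] %% 86400) %/% epoch + 1          # daily period index
    v <- values[i]
    I <- if (!is.na(v) && v > C) 1 else 0
    num <- num + j * I
    den <- den + I
  }
  if (den == 0) NA_real_ else num / den
}

# exhaustive circular scan over all onsets for a fixed window length (in
# profile periods); returns list(onset_index, mean); ties -> earliest onset
window_scan_bruteforce <- function(profile_means, w) {
  p <- length(profile_means)
  means <- rep(NA_real_, p)
  for (s in seq_len(p)) {
    idx <- ((s - 1 + 0:(w - 1)) %% p) + 1
    vals <- profile_means[idx]
    if (!anyNA(vals)) means[s] <- mean(vals)
  }
  list(all = means,
       min_onset = which.min(means), min_mean = min(means, na.rm = TRUE),
       max_onset = which.max(means), max_mean = max(means, na.rm = TRUE))
}

# IS transcribed directly from the defining ratio for complete data
is_bruteforce <- function(values, epoch, start = T0) {
  p <- 86400 %/% epoch
  tod_idx <- ((as.numeric(start) + epoch * (seq_along(values) - 1)) %% 86400) %/% epoch + 1
  xbar <- mean(values)
  xh <- vapply(1:p, function(h) mean(values[tod_idx == h]), numeric(1))
  n <- length(values)
  n * sum((xh - xbar)^2) / (p * sum((values - xbar)^2))
}

iv_bruteforce <- function(values) {
  n <- length(values)
  xbar <- mean(values)
  n * sum(diff(values)^2) / ((n - 1) * sum((values - xbar)^2))
}

# squared magnitude response of the forward-backward (zero-phase)
# Butterworth filter at digital frequency w (radians/sample), from the
# transfer-function polynomials
filtfilt_gain <- function(coef, w) {
  z <- exp(-1i * w)
  H <- sum(coef$b * z^(seq_along(coef$b) - 1)) /
       sum(coef$a * z^(seq_along(coef$a) - 1))
  Mod(H)^2
}

# amplitude of a sinusoidal component at frequency f_cycles_per_sample in
# the interior of a series (edges dropped to avoid filter transients)
probe_amplitude <- function(y, f, drop = 0.2) {
  n <- length(y)
  keep <- seq.int(floor(n * drop) + 1, ceiling(n * (1 - drop)))
  t <- keep - 1
  fit <- stats::lm(y[keep] ~ cos(2 * pi * f * t) + sin(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

random_series <- function(n, epoch = 60, missing_frac = 0, start = T0) {
  v <- stats::rlnorm(n, meanlog = 3, sdlog = 2)
  if (missing_frac > 0)
    v[stats::runif(n) < missing_frac] <- NA_real_
  make_series(v, epoch, start)
}
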