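test_that("summary statistics match closed forms and per-window recomputation", {
  s <- make_series(rep(7, 100), epoch = 60)
  row <- summary_statistics(s)
  expect_equal(row$mean, 7); expect_equal(row$median, 7)
  expect_equal(row$sd, 0); expect_equal(row$min, 7); expect_equal(row$max, 7)

  s2 <- make_series(1:100, epoch = 60)
  row2 <- summary_statistics(s2)
  expect_equal(row2$mean, 50.5)
  expect_equal(row2$median, 50.5)

  withr::with_seed(51, {
    s3 <- random_series(1440, missing_frac = 0.05)
    wins <- list(morning = c(T0 + 6 * 3600, T0 + 12 * 3600),
                 evening = c(T0 + 18 * 3600, T0 + 24 * 3600))
    row3 <- summary_statistics(s3, windows = wins)
    for (w in names(wins)) {
      t <- as.numeric(s3$time)
      v <- s3$values[t >= as.numeric(wins[[w]][1]) &
                       t < as.numeric(wins[[w]][2])]
      expect_equal(row3[[paste0("mean_", w)]], mean(v, na.rm = TRUE))
      expect_equal(row3[[paste0("sd_", w)]], stats::sd(v, na.rm = TRUE))
      expect_equal(row3[[paste0("p75_", w)]],
                   unname(stats::quantile(v, 0.75, na.rm = TRUE)))
    }
  })
})

test_that("light exposure level is the mean strictly above threshold", {
  s <- make_series(c(0, 5, 2, 7), epoch = 60)
  expect_equal(light_exposure_level(s, 2), 6)          # (5+7)/2
  expect_equal(light_exposure_level(s, -1), mean(c(0, 5, 2, 7)))
  expect_equal(light_exposure_level(s), mean(c(0, 5, 2, 7)))
  expect_true(is.na(light_exposure_level(s, 10)))
  # value == C is not above
  expect_equal(light_exposure_level(make_series(c(2, 3), 60), 2), 3)
})

test_that("TAT equals epoch length times the binarized sum", {
  two_days <- make_series(rep(500, 2 * 1440), epoch = 60)
  expect_equal(tat(two_days, 100, "minute"), 2880)
  expect_equal(tat(two_days, 1000, "minute"), 0)
  expect_equal(tat(two_days, 100, "count"), 2880)
  expect_equal(as.numeric(tat(two_days, 100, "timedelta"), units = "secs"),
               2880 * 60)
  expect_error(tat(two_days, 100, "fortnights"),
               class = "lightdose_error_parameter")

  withr::with_seed(61, {
    for (i in 1:100) {
      s <- random_series(sample(100:2000, 1), epoch = 60,
                         missing_frac = stats::runif(1, 0, 0.2))
      C <- stats::runif(1, 0, 300)
      expect_identical(tat(s, C, "minute"),
                       sum(binarize(s, C)$values, na.rm = TRUE) * s$epoch / 60)
    }
  })
})

test_that("windowed TAT is additive over a partition of the recording", {
  withr::with_seed(62, {
    s <- random_series(2 * 1440, epoch = 60)
    C <- 50
    whole <- list(all = c(T0, T0 + 2 * 86400))
    expect_equal(tat_per_window(s, C, whole)$all, tat(s, C, "minute"))
    halves <- list(d1 = c(T0, T0 + 86400), d2 = c(T0 + 86400, T0 + 2 * 86400))
    tw <- tat_per_window(s, C, halves)
    expect_equal(tw$d1 + tw$d2, tat(s, C, "minute"))
    # arbitrary windows against a brute-force count
    wins <- list(a = c(T0 + 1234 * 60, T0 + 1834 * 60),
                 b = c(T0 + 7 * 3600, T0 + 11 * 3600))
    tw2 <- tat_per_window(s, C, wins, output_format = "count")
    for (w in names(wins)) {
      t <- as.numeric(s$time)
      inw <- t >= as.numeric(wins[[w]][1]) & t < as.numeric(wins[[w]][2])
      expect_equal(tw2[[w]], sum(s$values[inw] > C, na.rm = TRUE))
    }
  })
})

test_that("MLiT reproduces worked single- and two-day cases", {
  # one exceedance at 13:00 -> clock time 13:00
  v <- rep(0, 1440)
  v[13 * 60 + 1] <- 1000
  r <- mlit(make_series(v, epoch = 60), 100)
  expect_equal(r$clock_time, 13 * 3600)
  expect_equal(r$m, 1440)
  expect_equal(r$exceedance_count, 1)

  # exceedances at minute-index 601 (day 1) and 721 (day 2) -> index 661 = 11:00
  v2 <- rep(0, 2 * 1440)
  v2[601] <- 1000
  v2[1440 + 721] <- 1000
  r2 <- mlit(make_series(v2, epoch = 60), 100)
  expect_equal(r2$index, 661)
  expect_equal(r2$clock_time, 11 * 3600)
  expect_equal(r2$n, 2)

  # exceedances symmetric about noon -> clock time 12:00
  v3 <- rep(0, 1440)
  v3[c(10 * 60 + 1, 14 * 60 + 1)] <- 1000   # 10:00 and 14:00
  expect_equal(mlit(make_series(v3, epoch = 60), 100)$clock_time, 12 * 3600)

  # nothing above threshold -> missing index, zero count
  r4 <- mlit(make_series(rep(1, 1440), epoch = 60), 100)
  expect_true(is.na(r4$index))
  expect_equal(r4$exceedance_count, 0)
})

test_that("MLiT equals the brute-force double sum on random series", {
  withr::with_seed(71, {
    for (i in 1:100) {
      days <- sample(2:5, 1)
      m <- sample(c(12, 24, 48, 96, 144, 288), 1)  # 10-60+ periods/day range
      epoch <- 86400 / m
      n <- days * m
      v <- stats::rlnorm(n, 3, 2)
      v[stats::runif(n) < 0.1] <- NA
      C <- stats::quantile(v, stats::runif(1, 0.2, 0.95), na.rm = TRUE)
      s <- make_series(v, epoch = epoch)
      got <- mlit(s, C)
      want <- mlit_bruteforce(v, epoch, C)
      if (is.na(want)) expect_true(is.na(got$index))
      else expect_identical(got$index, want)
    }
  })
})

test_that("MLiT index is bounded and invariant under monotone transforms", {
  withr::with_seed(72, {
    for (i in 1:20) {
      s <- random_series(3 * 288, epoch = 300)
      C <- stats::quantile(s$values, 0.8)
      r <- mlit(s, C)
      expect_gte(r$index, 1)
      expect_lte(r$index, r$m)
      # log is strictly monotone: transformed series + transformed C
      r2 <- mlit(log_transform(s, 1), log10(C + 1))
      expect_equal(r2$index, r$index, tolerance = 1e-12)
    }
  })
})

test_that("L5/M10 match the exhaustive circular scan", {
  # square-wave profile: 1000 on [08:00, 18:00), hourly epochs
  v <- rep(0, 24); v[9:18] <- 1000   # periods 9..18 = clock [08:00,18:00)
  s <- make_series(rep(v, 2), epoch = 3600)
  res <- l5m10(s)
  expect_equal(res$M10$onset, 8 * 3600)
  expect_equal(res$M10$mean_value, 1000)
  expect_equal(res$L5$mean_value, 0)
  expect_equal(res$L5$onset, 0)      # earliest all-zero window by tie-break

  # constant profile: both onsets 00:00 by the earliest-onset rule
  cs <- make_series(rep(5, 48), epoch = 3600)
  resc <- l5m10(cs)
  expect_equal(resc$L5$onset, 0); expect_equal(resc$M10$onset, 0)
  expect_equal(resc$L5$mean_value, 5); expect_equal(resc$M10$mean_value, 5)

  # sinusoid peaking at 12:00: M10 onset 07:00, L5 straddles midnight
  tod <- (0:23 + 0.5) / 24
  sv <- 500 * (1 + cos(2 * pi * (tod - 0.5)))
  ssin <- make_series(rep(sv, 3), epoch = 3600)
  ress <- l5m10(ssin)
  expect_equal(ress$M10$onset, 7 * 3600)
  oracle <- window_scan_bruteforce(daily_profile(ssin)$period_means, 5)
  expect_equal(ress$L5$onset, (oracle$min_onset - 1) * 3600)
  expect_equal(ress$L5$mean_value, oracle$min_mean)

  withr::with_seed(81, {
    for (i in 1:50) {
      p <- sample(c(24, 48, 96, 288), 1)
      prof_vals <- stats::rlnorm(p, 3, 1.5)
      s2 <- make_series(rep(prof_vals, 2), epoch = 86400 / p)
      r2 <- l5m10(s2)
      prof <- daily_profile(s2)$period_means
      o5 <- window_scan_bruteforce(prof, 5 * 3600 / (86400 / p))
      o10 <- window_scan_bruteforce(prof, 10 * 3600 / (86400 / p))
      expect_equal(r2$L5$onset, (o5$min_onset - 1) * 86400 / p)
      expect_equal(r2$L5$mean_value, o5$min_mean)
      expect_equal(r2$M10$onset, (o10$max_onset - 1) * 86400 / p)
      expect_equal(r2$M10$mean_value, o10$max_mean)
      expect_gte(r2$M10$mean_value, mean(prof))
      expect_lte(r2$L5$mean_value, mean(prof))
    }
  })
})

test_that("IS is 1 for periodic data, ~1/d for noise, undefined for constants", {
  withr::with_seed(91, {
    day <- stats::rlnorm(24, 3, 1.5)
    s <- make_series(rep(day, 7), epoch = 3600)
    expect_equal(interdaily_stability(s), 1, tolerance = 1e-9)

    expect_error(interdaily_stability(make_series(rep(5, 7 * 24), 3600)),
                 class = "lightdose_error_undefined_metric")

    # iid noise over d days: E[IS] ~ 1/d
    for (d in c(4, 7)) {
      vals <- replicate(200, {
        x <- abs(stats::rnorm(d * 24))
        interdaily_stability(make_series(x, epoch = 3600))
      })
      expect_equal(mean(vals), 1 / d, tolerance = 0.25)  # +/- 0.02 abs at 1/7
      expect_lt(abs(mean(vals) - 1 / d), 0.02)
    }
  })
})

test_that("IS agrees with a direct transcription of its formula and stays in [0,1]", {
  withr::with_seed(92, {
    for (i in 1:20) {
      d <- sample(2:6, 1)
      x <- stats::rlnorm(d * 24, 3, 1)
      s <- make_series(x, epoch = 3600)
      expect_equal(interdaily_stability(s), is_bruteforce(x, 3600),
                   tolerance = 1e-12)
      v <- interdaily_stability(s)
      expect_gte(v, -1e-9); expect_lte(v, 1 + 1e-9)
    }
  })
})

test_that("optional resampling before IS/IV uses mean aggregation", {
  withr::with_seed(93, {
    s <- random_series(7 * 1440, epoch = 60)
    hourly <- resample(s, "1H", "mean")
    expect_equal(interdaily_stability(s, freq = "1H"),
                 interdaily_stability(hourly))
    expect_equal(intradaily_variability(s, freq = "1H"),
                 intradaily_variability(hourly))
  })
})

test_that("IV matches closed forms and the iid limit", {
  # alternating +1/-1 around a mean: exactly 4
  alt <- make_series(rep(c(2, 0), 720), epoch = 60)
  expect_identical(intradaily_variability(alt), 4)

  # hourly 24 h sinusoid: IV -> 2(1 - cos(2*pi/24)) = 4 sin^2(pi/24)
  tod <- (0:(28 * 24 - 1)) / 24
  sv <- 500 * (1 + sin(2 * pi * tod))
  expect_equal(intradaily_variability(make_series(sv, epoch = 3600)),
               4 * sin(pi / 24)^2, tolerance = 0.01)

  expect_error(intradaily_variability(make_series(rep(3, 100), 60)),
               class = "lightdose_error_undefined_metric")

  withr::with_seed(101, {
    # iid Gaussian: E[(x_{i+1}-x_i)^2] = 2 sigma^2, so IV -> 2
    vals <- replicate(100, {
      x <- abs(stats::rnorm(1e4, mean = 20, sd = 1))
      intradaily_variability(make_series(x, epoch = 60))
    })
    expect_gte(mean(vals), 1.95); expect_lte(mean(vals), 2.05)
    # direct transcription on complete data
    for (i in 1:10) {
      x <- stats::rlnorm(500, 3, 1)
      expect_equal(intradaily_variability(make_series(x, 60)),
                   iv_bruteforce(x), tolerance = 1e-12)
    }
  })
})

test_that("the chi-square periodogram generalizes IS across folding periods", {
  withr::with_seed(111, {
    for (i in 1:20) {
      s <- random_series(sample(3:6, 1) * 24, epoch = 3600)
      expect_equal(is_at_period(s, "24H"), interdaily_stability(s),
                   tolerance = 1e-12)
    }
    # exactly 12 h periodic -> value 1 at a 12 h trial period
    half_day <- stats::rlnorm(12, 3, 1)
    s12 <- make_series(rep(half_day, 8), epoch = 3600)
    expect_equal(is_at_period(s12, "12H"), 1, tolerance = 1e-9)

    # noisy 24 h rhythm: periodogram peaks at the injected period
    tod <- (0:(7 * 24 - 1)) / 24
    x <- 200 * (1 + sin(2 * pi * tod)) + abs(stats::rnorm(7 * 24, 0, 40))
    sn <- make_series(x, epoch = 3600)
    periods <- c(8, 12, 16, 20, 24, 28, 32) * 3600
    vals <- vapply(periods, function(p) is_at_period(sn, p), numeric(1))
    expect_equal(periods[which.max(vals)], 24 * 3600)
  })
})

test_that("order-free metrics are unchanged when masked epochs are removed instead", {
  withr::with_seed(121, {
    for (i in 1:50) {
      n <- 1440
      v <- stats::rlnorm(n, 3, 2)
      t <- T0 + 60 * (0:(n - 1))
      rec <- light_recording("r", t, list(L = v))
      # random mask pattern via intervals
      k <- sample(1:5, 1)
      starts <- sort(sample(0:(n - 60), k)) * 60
      spec <- mask_spec(T0 + starts, T0 + starts + sample(10:120, k, TRUE) * 60)
      recm <- apply_mask(rec, spec)
      s_masked <- channel_data(recm, "L", masked = TRUE)
      keep <- !recm$mask
      v_removed <- v[keep]
      C <- stats::quantile(v, 0.6)
      expect_equal(mean(s_masked$values, na.rm = TRUE), mean(v_removed))
      expect_equal(light_exposure_level(s_masked, C),
                   mean(v_removed[v_removed > C]))
      expect_equal(tat(s_masked, C, "count"), sum(v_removed > C))
    }
  })
})

test_that("metric tables isolate per-cell failures and reduce to direct calls", {
  withr::with_seed(131, {
    sims <- lapply(1:3, function(i)
      generate_recording(synthetic_params(n_days = 2, seed = 200 + i)))
    recs <- lapply(sims, `[[`, "recording")
    spec <- list(
      Level_100 = list(metric = "light_exposure_level", threshold = log10(101)),
      TAT_100 = list(metric = "tat", threshold = log10(101),
                     output_format = "minute"),
      MLit_500 = list(metric = "mlit", threshold = log10(501)))
    tbl <- compute_metric_table(recs, "White Light", spec, log10_offset = 1)
    expect_equal(dim(tbl), c(3, 4))
    expect_equal(tbl$name, vapply(recs, function(r) r$name, character(1)))
    s1 <- log_transform(channel_data(recs[[1]], "White Light", TRUE), 1)
    expect_equal(tbl$Level_100[1], light_exposure_level(s1, log10(101)))
    expect_equal(tbl$TAT_100[1], tat(s1, log10(101), "minute"))
    expect_equal(tbl$MLit_500[1], mlit(s1, log10(501))$clock_time / 3600)

    # single recording + single metric = the direct call
    one <- compute_metric_table(recs[1], "White Light",
                                list(M = list(metric = "mean")))
    expect_equal(one$M,
                 mean(channel_data(recs[[1]], "White Light", TRUE)$values,
                      na.rm = TRUE))

    # constant recording: IS cell missing, others filled, run does not abort
    const <- light_recording("flat", T0 + 3600 * (0:(48 - 1)),
                             list(`White Light` = rep(5, 48)))
    tbl2 <- compute_metric_table(c(recs[1], list(const)), "White Light",
                                 list(IS = list(metric = "is"),
                                      M = list(metric = "mean")))
    expect_true(is.na(tbl2$IS[2]))
    expect_equal(tbl2$M[2], 5)
    expect_false(anyNA(tbl2[1, -1]))
    expect_match(names(attr(tbl2, "errors")), "flat/IS", all = FALSE)

    expect_error(compute_metric_table(list(), "White Light", spec),
                 class = "lightdose_error_parameter")
  })
})
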