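make_rec <- function(traces, fs = 10000) {
  structure(list(traces = traces, sampling_rate = fs,
                 duration_s = ncol(traces) / fs,
                 channel_map = data.frame(electrode = seq_len(nrow(traces)),
                                          chamber = "chamber1")),
            class = "mea_recording")
}

test_that("band-pass matches the analytic Butterworth response", {
  fs <- 10000
  t <- seq(0, 1, by = 1 / fs)[-1]
  # analytic magnitude of the digital 2nd-order band-pass at f Hz,
  # squared for the zero-phase forward-backward pass
  bf <- signal::butter(2, c(300, 3000) / (fs / 2), "pass")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(bf$b * z^(0:4)) / sum(bf$a * z^(0:4)))^2
  }
  mid <- 2000:8000
  rms_amp <- function(x) sqrt(2) * sd(x)  # sine amplitude from RMS
  for (f in c(1000, 500)) {
    tone <- sin(2 * pi * f * t)
    out <- bandpass(make_rec(rbind(tone), fs))$traces[1, ]
    expect_equal(rms_amp(out[mid]), gain2(f), tolerance = 0.01)
  }
  # a 1 kHz tone sits near the passband centre and survives
  expect_gt(gain2(1000), 0.9)

  # a 10 Hz tone is attenuated by at least 20 dB
  expect_gt(-10 * log10(gain2(10)), 20)
  slow <- sin(2 * pi * 10 * t)
  outs <- bandpass(make_rec(rbind(slow), fs))$traces[1, ]
  expect_lt(rms_amp(outs[mid]), 0.1)

  # DC is removed by the high-pass edge (away from edge transients)
  outd <- bandpass(make_rec(rbind(rep(7, fs)), fs))$traces[1, ]
  expect_lt(max(abs(outd[mid])), 1e-4)

  expect_error(bandpass(make_rec(rbind(rep(0, fs)), fs = 6000)),
               "Nyquist|band", ignore.case = TRUE)
})

test_that("the detection threshold is median minus five SDs", {
  set.seed(1)
  x <- rnorm(50000, 0, 4)
  x <- (x - median(x)) / sd(x) * 4      # median 0, SD exactly 4
  st <- detect_spikes(make_rec(rbind(x)))
  expect_equal(st$thresholds_uV[1], -20, tolerance = 1e-9)

  zero <- make_rec(rbind(rep(0, 10000)))
  expect_length(detect_spikes(zero)$times[[1]], 0L)
})

test_that("spikes are detected with high recall, precision and timing accuracy", {
  p <- quick_params(duration_s = 30, n_channels = 3L, rate_hz = 1)
  g <- gen_mea_recording(p)
  st <- detect_spikes(bandpass(g$recording))
  for (ch in 1:3) {
    tru <- g$truth$spike_times[[ch]]
    det <- st$times[[ch]]
    hits <- vapply(det, function(t) min(abs(tru - t)), numeric(1))
    expect_gte(sum(hits <= 5e-4) / length(tru), 0.99)
    expect_gte(sum(hits <= 5e-4) / length(det), 0.99)
    expect_lte(max(hits[hits <= 5e-4]), 5e-4)
  }
})

test_that("binning counts every spike exactly once in half-open 1-ms bins", {
  tt <- c(0.0005, 0.001, 0.0014, 0.5, 9.9995)
  b <- bin_spikes(tt, duration_s = 10)
  expect_equal(sum(b), 5L)
  expect_equal(b[1], 1L)        # [0, 1) ms
  expect_equal(b[2], 2L)        # 1.0 and 1.4 ms share [1, 2)
  expect_equal(b[10000], 1L)

  # conservation across random trains
  set.seed(3)
  for (k in 1:5) {
    t <- sort(runif(200, 0, 7))
    expect_equal(sum(bin_spikes(t, 7)), 200L)
  }
})

test_that("firing rates are spikes per second and average across electrodes", {
  trains <- list(seq(0, 419, by = 1), numeric(0))
  mfr <- mean_firing_rate(trains, 420)
  expect_equal(mfr$per_electrode, c(1, 0))
  expect_equal(mfr$network_mfr, 0.5)

  expect_equal(mean_firing_rate(list(numeric(0)), 10)$network_mfr, 0)

  # Poisson truth: network MFR within 3 standard errors of the rate
  p <- quick_params(duration_s = 100, n_channels = 12L, rate_hz = 0.5)
  g <- gen_mea_recording(p)
  mfr2 <- mean_firing_rate(g$truth$spike_times, 100)
  se <- sqrt(0.5 / 100 / 12)
  expect_lt(abs(mfr2$network_mfr - 0.5), 3 * se)
})

test_that("lagged correlation matches the direct per-lag oracle", {
  set.seed(8)
  n <- 4000
  for (k in 1:3) {
    a <- rpois(n, 0.08)
    b <- rpois(n, 0.08)
    lc <- lagged_correlation(a, b, max_lag_ms = 15, full = TRUE)
    direct <- vapply(-15:15, function(L) {
      if (L >= 0) cor(a[1:(n - L)], b[(1 + L):n])
      else cor(a[(1 - L):n], b[1:(n + L)])
    }, numeric(1))
    expect_equal(lc$r, direct, tolerance = 1e-12)
    # p at the peak equals the t transform recomputed by hand
    m <- lc$n_overlap
    tstat <- lc$peak_r * sqrt((m - 2) / (1 - lc$peak_r^2))
    expect_equal(lc$p, 2 * pt(-abs(tstat), m - 2), tolerance = 1e-12)
  }
})

test_that("identical and shifted trains peak at the expected lags", {
  set.seed(5)
  a <- rpois(3000, 0.1)
  self <- lagged_correlation(a, a, 20)
  expect_equal(self$peak_r, 1)
  expect_equal(self$peak_lag_ms, 0)

  b <- c(rep(0, 52), a[1:(3000 - 52)])   # b follows a by 52 ms
  sh <- lagged_correlation(a, b, 100)
  expect_equal(sh$peak_lag_ms, 52)
  expect_gt(sh$peak_r, 0.99)

  flat <- rep(0L, 3000)
  expect_true(lagged_correlation(a, flat, 20)$degenerate)
})

test_that("reversing the pair mirrors the lag axis", {
  set.seed(11)
  a <- rpois(1500, 0.1); b <- rpois(1500, 0.1)
  ab <- lagged_correlation(a, b, 10, full = TRUE)
  ba <- lagged_correlation(b, a, 10, full = TRUE)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
})

test_that("nominal peak p-values are anticonservative against a permutation null", {
  # on independent sparse trains the t-transform p at the selected peak
  # is far smaller than the permutation p of the same statistic; the
  # p <= 0.001 filter therefore passes chance coincidences
  set.seed(21)
  n <- 20000
  a <- tabulate(sample.int(n, 30), n)
  b <- tabulate(sample.int(n, 30), n)
  obs <- lagged_correlation(a, b, 100)
  perm <- replicate(199, {
    bp <- tabulate(sample.int(n, 30), n)   # regenerate the null partner
    lagged_correlation(a, bp, 100)$peak_r
  })
  p_perm <- (1 + sum(perm >= obs$peak_r)) / 200
  expect_gt(p_perm, obs$p)     # nominal p understates the peak null
  expect_gt(p_perm, 0.01)      # the permutation p itself is unremarkable
})

test_that("network correlation applies activity and significance filters", {
  dur <- 60
  mk <- function(times) bin_spikes(times, dur)
  set.seed(2)
  t1 <- sort(runif(120, 0, dur))
  t2 <- sort(t1 + 0.052)                  # perfectly coupled at +52 ms
  t3 <- sort(runif(9, 0, dur))            # inactive: < 10 spikes
  t4 <- sort(runif(10, 0, dur))           # exactly 10: retained
  conn <- network_correlation(list(mk(t1), mk(t2), mk(t3), mk(t4)),
                              duration_s = dur)
  expect_equal(conn$n_active, 3L)
  expect_false(any(conn$pairs$a == 3 | conn$pairs$b == 3))
  expect_true(any(conn$pairs$a == 4 | conn$pairs$b == 4))
  p12 <- conn$pairs[conn$pairs$a == 1 & conn$pairs$b == 2, ]
  expect_equal(p12$lag_ms, 52)
  expect_true(p12$included)
  # total is the mean peak r over included pairs
  inc <- conn$pairs[conn$pairs$included, ]
  expect_equal(conn$total_network_correlation, mean(inc$r))

  # all electrodes inactive -> undefined, flagged
  quiet <- network_correlation(list(mk(t3), mk(t3 + 1)), duration_s = dur)
  expect_true(quiet$undefined)
  expect_true(is.na(quiet$total_network_correlation))
})

test_that("injected coupling lags are recovered exactly from binned truth", {
  p <- quick_params(duration_s = 300, n_channels = 2L, rate_hz = 1.2,
                    coupled_pairs = list(list(a = 1L, b = 2L, lag_ms = 37,
                                              prob = 0.6)))
  g <- gen_mea_recording(p)
  a <- bin_spikes(g$truth$spike_times[[1]], 300)
  b <- bin_spikes(g$truth$spike_times[[2]], 300)
  lc <- lagged_correlation(a, b, 100)
  expect_lte(abs(lc$peak_lag_ms - 37), 1)
})
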