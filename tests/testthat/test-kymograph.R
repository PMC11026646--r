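make_kymo <- function(m, col_size = 0.2, row_interval = 1, sign = 1L) {
  structure(list(matrix = m, row_interval = row_interval,
                 col_size = col_size, tunnel = 1L,
                 anterograde_sign = sign), class = "kymograph")
}

test_that("kymograph rows are width-averaged luminance in time order", {
  p <- quick_params(n_stationary = 0L, n_motile = 0L)
  g <- gen_mito_series(p)
  km <- build_kymograph(g$series, g$rois[1, ])
  expect_equal(nrow(km$matrix), 20L)
  expect_equal(ncol(km$matrix), g$rois$col1[1])

  # uniform series -> constant matrix
  u <- image_series(array(0.4, c(10, 30, 5)), 0.2, 1)
  roi <- data.frame(tunnel = 1L, row0 = 2L, row1 = 9L, col0 = 1L,
                    col1 = 30L, anterograde_sign = 1L)
  ku <- build_kymograph(u, roi)
  expect_true(all(abs(ku$matrix - 0.4) < 1e-12))

  # linear in luminance
  s2 <- u; s2$frames <- u$frames * 3
  expect_equal(build_kymograph(s2, roi)$matrix, ku$matrix * 3)

  bad <- roi; bad$row1 <- 99L
  expect_error(build_kymograph(u, bad), "outside")
})

test_that("a 60-frame series gives a 60-row kymograph whose argmax tracks truth", {
  p <- sim_params(n_frames = 60L, n_stationary = 0L, n_motile = 1L,
                  speeds_um_s = 1.0, noise_sd = 0.001,
                  ramp_amplitude = 0, seed = 6L)
  g <- gen_mito_series(p)
  km <- build_kymograph(g$series, g$rois[1, ])
  expect_equal(nrow(km$matrix), 60L)
  amax <- apply(km$matrix, 1, which.max)
  # 1.0 um/s at 0.2 um/px and 1 s rows -> 5 px per row
  expect_equal(unname(diff(amax)), rep(5, 59), tolerance = 0.21)
})

test_that("stationary stripes are removed and counted", {
  # single constant vertical stripe
  m <- matrix(0.01, 40, 120)
  m[, 60:62] <- 0.2
  sup <- suppress_stationary(make_kymo(m))
  expect_lt(max(sup$filtered$matrix), 1e-12)
  expect_equal(sup$n_stationary, 1L)

  # blank kymograph
  set.seed(2)
  blank <- matrix(abs(rnorm(40 * 120, 0.01, 0.001)), 40)
  expect_equal(suppress_stationary(make_kymo(blank))$n_stationary, 0L)

  # two stripes plus one slanted line: stripes counted, line kept
  m2 <- matrix(0.01, 60, 200)
  m2[, 40:42] <- 0.2; m2[, 150:152] <- 0.2
  for (t in 1:60) {
    cc <- 10 + 2 * (t - 1)
    m2[t, cc:(cc + 1)] <- m2[t, cc:(cc + 1)] + 0.25
  }
  sup2 <- suppress_stationary(make_kymo(m2))
  expect_equal(sup2$n_stationary, 2L)
  line_energy <- function(m) {
    e <- 0
    for (t in 1:60) e <- e + sum(m[t, (10 + 2 * (t - 1)) + 0:1])
    e
  }
  expect_gte(line_energy(sup2$filtered$matrix) / (0.25 * 2 * 60), 0.9)
})

test_that("track speed is displacement over time by construction", {
  tr <- data.frame(slope_px_per_row = 3)
  km <- make_kymo(matrix(0, 10, 50), col_size = 0.2, row_interval = 1)
  expect_equal(track_speed(tr, km), 0.6)   # 30 px over 10 rows
  expect_equal(track_speed(data.frame(slope_px_per_row = 0), km), 0)
})

test_that("track detection finds slanted lines and ignores vertical residues", {
  # blank filtered kymograph -> no tracks
  set.seed(9)
  blank <- make_kymo(matrix(abs(rnorm(60 * 200, 0, 0.001)), 60))
  expect_equal(nrow(detect_tracks(blank)), 0L)

  # one clean line of slope 3 px/row
  m <- matrix(0.001, 60, 260)
  for (t in 1:60) {
    cc <- 20 + 3 * (t - 1)
    m[t, cc:(cc + 2)] <- 0.2
  }
  tr <- detect_tracks(make_kymo(m))
  expect_equal(nrow(tr), 1L)
  expect_lt(abs(tr$slope_px_per_row - 3) / 3, 0.05)
  expect_equal(tr$direction, "anterograde")

  # vertical residual line -> stationary, excluded from motile set
  mv <- matrix(0.001, 60, 100)
  mv[, 50] <- 0.2
  trv <- detect_tracks(make_kymo(mv))
  expect_true(nrow(trv) == 0L ||
                all(trv$direction %in% c("stationary", "bidirectional")))
})

test_that("slope agrees with a coarse Hough-style scan on clean lines", {
  m <- matrix(0.001, 60, 400)
  for (t in 1:60) {
    cc <- round(30 + 4.6 * (t - 1))
    m[t, cc:(cc + 2)] <- 0.2
  }
  tr <- detect_tracks(make_kymo(m))
  # oracle: maximise summed intensity over slope/intercept candidates
  slopes <- seq(0, 8, by = 0.2)
  best <- c(-Inf, NA)
  for (s in slopes) for (c0 in seq(1, 120, by = 2)) {
    cols <- round(c0 + s * (0:59))
    ok <- cols >= 1 & cols <= 400
    e <- sum(m[cbind(which(ok), cols[ok])])
    if (e > best[1]) best <- c(e, s)
  }
  expect_lt(abs(tr$slope_px_per_row - best[2]), 0.3)
})

test_that("full-pipeline speed recovery stays within 5% at both group means", {
  for (v in c(0.639, 1.296)) {
    rec <- vapply(1:4, function(s) {
      p <- sim_params(n_stationary = 8L, n_motile = 1L, speeds_um_s = v,
                      snr = 5, seed = s)
      g <- gen_mito_series(p)
      sup <- suppress_stationary(build_kymograph(g$series, g$rois[1, ]))
      tr <- detect_tracks(sup$filtered)
      mo <- tr[tr$direction %in% c("anterograde", "retrograde"), ]
      mean(mo$speed_um_s)
    }, numeric(1))
    expect_lt(abs(mean(rec) - v) / v, 0.05)
  }
})

test_that("motility summaries reduce to the stated arithmetic", {
  tracks <- data.frame(direction = c(rep("anterograde", 2),
                                     "retrograde"),
                       speed_um_s = c(0.5, 0.7, 0.9))
  ms <- motility_summary(tracks, n_stationary = 17L)
  expect_equal(ms$motile_ratio, 3 / 20)
  expect_equal(ms$anterograde_fraction, 2 / 3)
  expect_equal(ms$mean_speed_um_s, 0.7)

  ten <- data.frame(direction = rep(c("anterograde", "retrograde"), 5),
                    speed_um_s = rep(1, 10))
  expect_equal(motility_summary(ten, 0L)$anterograde_fraction, 0.5)

  none <- tracks[0, ]
  expect_true(motility_summary(none, 0L)$undefined)
})

test_that("summary equals truth labels when detection is perfect", {
  p <- sim_params(n_stationary = 6L, n_motile = 2L,
                  speeds_um_s = c(0.8, -1.1), snr = 8, seed = 13L)
  g <- gen_mito_series(p)
  sup <- suppress_stationary(build_kymograph(g$series, g$rois[1, ]))
  tr <- detect_tracks(sup$filtered)
  ms <- motility_summary(tr, sup$n_stationary)
  expect_equal(ms$n_motile, 2L)
  expect_equal(ms$n_stationary, 6L)
  expect_equal(ms$motile_ratio, 0.25)
  expect_equal(ms$anterograde_fraction, 0.5)
})
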