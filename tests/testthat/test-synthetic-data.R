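test_that("identical parameters give bit-identical outputs", {
  p <- quick_params()
  a <- gen_mito_series(p); b <- gen_mito_series(p)
  expect_identical(a$series$frames, b$series$frames)
  expect_identical(a$truth$objects, b$truth$objects)

  r1 <- gen_mea_recording(p); r2 <- gen_mea_recording(p)
  expect_identical(r1$recording$traces, r2$recording$traces)

  # a different seed changes the scene
  p2 <- quick_params(seed = 2L)
  expect_false(identical(gen_mito_series(p2)$series$frames,
                         a$series$frames))
})

test_that("every rendered object has exactly one truth record", {
  p <- quick_params(n_stationary = 5L, n_motile = 2L, n_tunnels = 3L,
                    speeds_um_s = NULL)
  g <- gen_mito_series(p)
  expect_equal(nrow(g$truth$objects), 3L * 7L)
  expect_equal(sum(g$truth$objects$motile), 6L)
  expect_true(all(is.finite(g$truth$objects$speed_um_s)))
})

test_that("empty scenes contain only background and noise", {
  p <- quick_params(n_stationary = 0L, n_motile = 0L)
  g <- gen_mito_series(p)
  expect_equal(nrow(g$truth$objects), 0L)
  fr <- get_frame(g$series, 1L)
  det <- detect_mitochondria(fr, mito_cfg(), g$rois[1, ])
  expect_equal(det$count, 0L)
})

test_that("a 60-frame 1 s series spans one minute and 60 TIFF pages", {
  p <- sim_params(n_frames = 60L, frame_interval = 1, n_stationary = 2L,
                  n_motile = 0L, tunnel_length_um = 30, seed = 3L)
  g <- gen_mito_series(p)
  expect_equal(dim(g$series$frames)[3], 60L)
  expect_equal(dim(g$series$frames)[3] * g$series$frame_interval, 60)
  tf <- file.path(tempdir(), "series.tif")
  write_tiff(g$series, tf)
  expect_length(tiff::readTIFF(tf, all = TRUE), 60L)
  back <- read_tiff(tf)
  expect_equal(back$frames, g$series$frames, tolerance = 2e-4)
  expect_equal(back$frame_interval, 1)
})

test_that("a motile object's rendered argmax advances by speed per frame", {
  p <- sim_params(pixel_size = 0.2, frame_interval = 1, n_frames = 10L,
                  n_stationary = 0L, n_motile = 1L, speeds_um_s = 1.0,
                  noise_sd = 0.001, ramp_amplitude = 0,
                  tunnel_length_um = 30, seed = 5L)
  g <- gen_mito_series(p)
  roi <- g$rois[1, ]
  centre <- round(g$truth$objects$row)
  cols <- vapply(seq_len(10L), function(t)
    which.max(g$series$frames[centre, , t]), integer(1))
  expect_equal(diff(cols), rep(5, 9), tolerance = 0.21) # 1.0/0.2 px/frame
})

test_that("parameters that push a trajectory outside the tunnel are rejected", {
  p <- sim_params(n_frames = 60L, n_motile = 1L, speeds_um_s = 2,
                  tunnel_length_um = 30, n_stationary = 0L, seed = 1L)
  expect_error(gen_mito_series(p), "reject")
})

test_that("neurite truth lists one record per free terminus", {
  p <- quick_params()
  g0 <- gen_neurite_image(p, n_neurites = 0L, n_branches = 0L,
                          shape = c(64L, 64L))
  expect_equal(nrow(g0$truth$objects), 0L)

  g1 <- gen_neurite_image(p, n_neurites = 1L, n_branches = 0L,
                          shape = c(128L, 128L))
  expect_equal(nrow(g1$truth$objects), 1L)

  g2 <- gen_neurite_image(p, n_neurites = 5L, n_branches = 2L)
  expect_equal(nrow(g2$truth$objects), 7L)
  # termini lie inside the field, away from the anchored border
  expect_true(all(g2$truth$objects$col > 12 &
                    g2$truth$objects$col < 500))
})

test_that("synapse channels respect overlap counts and the 15 um cut-off", {
  p <- quick_params()
  g0 <- gen_synapse_channels(p, n_overlap = 0L, n_unique_a = 12L,
                             n_unique_b = 12L, unique_diameter_um = 1.5)
  ma <- threshold_image(g0$channel_a, "otsu")$mask
  mb <- threshold_image(g0$channel_b, "triangle")$mask
  expect_lte(sum(ma & mb), 3L)   # borders of nearby puncta at most

  g <- gen_synapse_channels(p, n_overlap = 5L,
                            overlap_diameters_um = c(1, 1, 1, 1, 20),
                            shape = c(512L, 512L))
  expect_equal(nrow(g$truth$objects), 5L)
  expect_equal(sum(g$truth$objects$over_cutoff), 1L)
  expect_equal(g$truth$objects$equiv_diameter_um[5], 20)
})

test_that("z-stack truth height is slice span times z-step", {
  p <- quick_params()
  g1 <- gen_zstack(p, n_slices = 6L, signal_slices = c(3L, 3L))
  expect_equal(g1$truth$height_um, 1)

  p$z_step <- 0.5
  g2 <- gen_zstack(p, n_slices = 15L, signal_slices = c(3L, 11L))
  expect_equal(g2$truth$height_um, (11 - 3 + 1) * 0.5)
  expect_error(gen_zstack(p, n_slices = 5L, signal_slices = c(3L, 11L)))
})

test_that("MEA generator injects coupled co-spikes at the stated lag", {
  p <- quick_params(duration_s = 60, n_channels = 2L, rate_hz = 0.5,
                    coupled_pairs = list(list(a = 1L, b = 2L,
                                              lag_ms = 52, prob = 1)))
  g <- gen_mea_recording(p)
  ta <- g$truth$spike_times[[1]]
  tb <- g$truth$spike_times[[2]]
  expect_gt(length(ta), 10)
  # every source spike has a partner 52 ms later (sample-rounded)
  for (t in ta)
    expect_lt(min(abs(tb - (t + 0.052))), 1.5 / p$sampling_rate)

  expect_equal(ncol(g$recording$traces),
               round(p$duration_s * p$sampling_rate))
})

test_that("silent channels and weak spikes behave as documented", {
  p <- quick_params(duration_s = 20, n_channels = 2L, rate_hz = 0)
  g <- gen_mea_recording(p)
  expect_equal(nrow(g$truth$objects), 0L)

  p2 <- quick_params(duration_s = 5, n_channels = 1L,
                     spike_amplitude_uV = -10, noise_sd_uV = 5)
  expect_warning(gen_mea_recording(p2), "underpowered")
})

test_that("recordings round-trip through the flat binary container", {
  p <- quick_params(duration_s = 2, n_channels = 3L)
  g <- gen_mea_recording(p)
  path <- file.path(tempdir(), "rec.raw")
  write_recording(g$recording, path)
  back <- read_recording(path)
  expect_equal(back$traces, g$recording$traces, tolerance = 1e-6)
  expect_equal(back$sampling_rate, 10000)
  expect_equal(back$channel_map, g$recording$channel_map)
})

test_that("simulation parameters round-trip through YAML and ROIs through JSON", {
  p <- quick_params(coupled_pairs = list(list(a = 1L, b = 2L,
                                              lag_ms = -30, prob = 0.5)))
  f <- file.path(tempdir(), "params.yaml")
  write_sim_params(p, f)
  q <- read_sim_params(f)
  expect_equal(q$coupled_pairs, p$coupled_pairs)
  expect_equal(q$seed, p$seed)

  rois <- tunnel_rois(sim_params(n_tunnels = 4L))
  rf <- file.path(tempdir(), "rois.json")
  write_rois(rois, rf)
  expect_equal(read_rois(rf), rois)
  expect_error(sim_params(coupled_pairs = list(list(a = 1, b = 2,
                                                    lag_ms = 150,
                                                    prob = 1))))
})

test_that("physical truth equals pixel truth times the calibration", {
  p <- quick_params(pixel_size = 0.25, n_stationary = 0L, n_motile = 1L,
                    speeds_um_s = 0.5)
  g <- gen_mito_series(p)
  ob <- g$truth$objects
  px_per_frame <- ob$speed_um_s * p$frame_interval / p$pixel_size
  expect_equal(px_per_frame, 2)  # 0.5 um/s at 0.25 um/px, 1 s frames
})
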