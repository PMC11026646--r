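test_that("top-hat removes flat and ramped backgrounds, preserves spots", {
  flat <- calibrated_image(matrix(0.3, 20, 20), 0.5)
  out <- tophat(flat, 2)
  expect_true(all(out$pixels == 0))

  # bright spot on a linear ramp: the ramp goes, the spot stays
  ramp <- matrix(rep(seq(0.1, 0.2, length.out = 30), each = 30), 30)
  ramp[15, 15] <- ramp[15, 15] + 0.5
  img <- calibrated_image(ramp, 0.5)
  out <- tophat(img, 1.5)
  expect_gt(out$pixels[15, 15], 0.45)
  expect_lt(max(out$pixels[-(15 + 14 * 30)]), 0.05)
  # never exceeds the input
  expect_true(all(out$pixels <= img$pixels + 1e-12))
})

test_that("top-hat equals input minus hand-computed opening on a 5x5", {
  px <- matrix(0, 5, 5)
  px[3, 3] <- 1
  img <- calibrated_image(px, 1)
  # disc of radius 2 px covers the whole bright pixel neighbourhood:
  # erosion kills the single pixel, dilation of zeros stays zero, so the
  # opening is all-zero and the top-hat equals the input
  out <- tophat(img, 2)
  expect_equal(out$pixels, px)
  expect_error(tophat(img, 0.4), "smaller than one pixel")
})

test_that("thresholds match brute-force histogram criteria", {
  # perfectly separable two-valued image
  px <- matrix(c(rep(10, 90), rep(200, 10)), 10)
  th <- threshold_image(calibrated_image(px, 1), "otsu")
  expect_identical(unname(th$mask), unname(px == 200))

  set.seed(7)
  px <- matrix(c(rnorm(3000, 80, 12), rnorm(1000, 180, 15)), 50)
  px <- pmax(px, 0)
  h <- hist(px, breaks = seq(min(px), max(px), length.out = 257),
            plot = FALSE)
  counts <- h$counts
  n <- sum(counts)
  # exhaustive between-class variance maximisation
  best <- -Inf; best_bin <- 1L
  for (t in 1:255) {
    w1 <- sum(counts[1:t]) / n
    w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) next
    mu1 <- sum(counts[1:t] * (1:t)) / sum(counts[1:t])
    mu2 <- sum(counts[(t + 1):256] * ((t + 1):256)) /
      sum(counts[(t + 1):256])
    v <- w1 * w2 * (mu1 - mu2)^2
    if (v > best) { best <- v; best_bin <- t }
  }
  th <- threshold_image(px, "otsu")
  expect_equal(th$threshold, h$breaks[best_bin + 1L], tolerance = 1e-10)

  # triangle: exhaustive maximal perpendicular distance to the chord
  peak <- which.max(counts)
  nz <- which(counts > 0)
  hi <- nz[length(nz)]
  dx <- hi - peak; dy <- counts[hi] - counts[peak]
  d <- abs(dy * ((peak:hi) - peak) - dx * (counts[peak:hi] -
                                             counts[peak])) /
    sqrt(dx^2 + dy^2)
  tri_bin <- (peak:hi)[which.max(d)]
  th2 <- threshold_image(px, "triangle")
  expect_equal(th2$threshold, h$breaks[tri_bin + 1L], tolerance = 1e-10)
})

test_that("thresholding is invariant under affine luminance rescaling", {
  set.seed(3)
  px <- matrix(c(rnorm(500, 50, 8), rnorm(100, 150, 10)), 20)
  for (m in c("otsu", "triangle")) {
    m1 <- threshold_image(px, m)$mask
    m2 <- threshold_image(3.7 * px + 41, m)$mask
    expect_identical(m1, m2)
  }
  expect_error(threshold_image(matrix(5, 4, 4)), "constant")
})

test_that("connected components agree with flood fill and conserve pixels", {
  expect_equal(nrow(connected_components(matrix(FALSE, 4, 4))), 0L)

  diagpair <- matrix(FALSE, 5, 5)
  diagpair[2, 2] <- diagpair[3, 3] <- TRUE
  expect_equal(nrow(connected_components(diagpair, connectivity = 8)), 1L)
  expect_equal(nrow(connected_components(diagpair, connectivity = 4)), 2L)

  set.seed(11)
  for (conn in c(4L, 8L)) {
    mask <- matrix(runif(32 * 32) < 0.35, 32)
    comp <- connected_components(mask, connectivity = conn)
    oracle <- flood_fill_label(mask, conn)
    lab <- attr(comp, "labels")
    # same partition: label images agree up to renumbering
    expect_equal(max(lab), max(oracle))
    expect_true(all(tapply(oracle[mask], lab[mask],
                           function(x) length(unique(x))) == 1))
    expect_equal(sum(comp$pixel_count), sum(mask))
  }
})

test_that("component shape measures behave like ellipse fits", {
  # disc: eccentricity near 0
  xy <- expand.grid(r = 1:41, c = 1:41)
  disc <- matrix((xy$r - 21)^2 + (xy$c - 21)^2 <= 15^2, 41)
  cd <- connected_components(disc, pixel_size = 0.5)
  expect_lt(cd$eccentricity, 0.05)
  expect_equal(cd$area_um2, sum(disc) * 0.25)
  expect_equal(cd$centroid_row, 20, tolerance = 1e-6) # 0-based centre

  # one-pixel-wide line: strongly elongated yet strictly below 1
  line <- matrix(FALSE, 10, 30); line[5, 3:28] <- TRUE
  cl <- connected_components(line)
  expect_gt(cl$eccentricity, 0.99)
  expect_lt(cl$eccentricity, 1)
})

test_that("particle analysis filters by physical size like the component table", {
  expect_equal(particle_analysis(matrix(FALSE, 5, 5), 1)$count, 0L)

  mask <- matrix(FALSE, 10, 20)
  mask[2:3, 2:3] <- TRUE; mask[6:7, 6:7] <- TRUE; mask[2:3, 12:13] <- TRUE
  pa <- particle_analysis(mask, 0.5)
  expect_equal(pa$count, 3L)
  expect_equal(pa$sizes_um2, rep(1, 3))   # 4 px * 0.25 um^2

  set.seed(4)
  mask <- matrix(runif(40 * 40) < 0.3, 40)
  comp <- connected_components(mask, 0.5, 8L)
  pa <- particle_analysis(mask, 0.5, min_size = 0.5, max_size = 3)
  expect_equal(sort(pa$sizes_um2),
               sort(comp$area_um2[comp$area_um2 >= 0.5 &
                                    comp$area_um2 <= 3]))
})

test_that("skeletons of simple paths keep two endpoints per path", {
  mask <- matrix(FALSE, 20, 40)
  mask[9:11, 5:35] <- TRUE
  sk <- skeletonize(mask)
  expect_equal(nrow(skeleton_endpoints(sk)), 2L)

  # forest of k simple paths -> 2k endpoints (graph identity)
  mask <- matrix(FALSE, 40, 40)
  mask[5:6, 3:37] <- TRUE
  mask[20:21, 3:37] <- TRUE
  mask[30:35, 10:11] <- TRUE
  sk <- skeletonize(mask)
  expect_equal(nrow(skeleton_endpoints(sk)), 6L)
})
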