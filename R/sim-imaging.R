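#' Synthetic imaging scenes with ground truth
#'
#' Each generator renders a calibrated scene and returns, alongside it, a
#' `ground_truth` object recording every rendered structure (kind,
#' position, signed speed, size, coupling), so that every analysis stage
#' can be verified by parameter recovery. Objects are isotropic Gaussian
#' blobs (sigma = `psf_sigma`) or hard discs on a linear-ramp background
#' with Gaussian read noise; physical quantities in the truth are pixel
#' quantities times the calibration, exactly.
#'
#' @name synthetic_imaging
NULL

.background_matrix <- function(nr, nc, background, ramp_amplitude) {
  background + ramp_amplitude * matrix(rep(seq(0, 1, length.out = nc),
                                           each = nr), nr, nc)
}

.add_noise <- function(m, noise_sd) {
  if (noise_sd <= 0) return(m)
  out <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
  out[out < 0] <- 0
  out
}

# Add a Gaussian blob of peak `amp` at (r0, c0) [1-based, can be fractional]
.render_blob <- function(img, r0, c0, amp, sigma) {
  w <- ceiling(4 * sigma)
  r_lo <- max(1L, floor(r0 - w)); r_hi <- min(nrow(img), ceiling(r0 + w))
  c_lo <- max(1L, floor(c0 - w)); c_hi <- min(ncol(img), ceiling(c0 + w))
  if (r_hi < r_lo || c_hi < c_lo) return(img)
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  g <- exp(-(outer((rs - r0)^2, (cs - c0)^2, "+")) / (2 * sigma^2))
  img[rs, cs] <- img[rs, cs] + amp * g
  img
}

# Add a hard disc (pixel centres within radius) of uniform amplitude.
.render_disc <- function(img, r0, c0, radius_px, amp) {
  w <- ceiling(radius_px) + 1L
  r_lo <- max(1L, floor(r0 - w)); r_hi <- min(nrow(img), ceiling(r0 + w))
  c_lo <- max(1L, floor(c0 - w)); c_hi <- min(ncol(img), ceiling(c0 + w))
  if (r_hi < r_lo || c_hi < c_lo) return(img)
  rs <- r_lo:r_hi; cs <- c_lo:c_hi
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  sel <- d2 <= radius_px^2
  img[rs, cs][sel] <- img[rs, cs][sel] + amp
  img
}

.disc_pixel_count <- function(r0, c0, radius_px) {
  w <- ceiling(radius_px) + 1L
  rs <- (floor(r0 - w)):(ceiling(r0 + w))
  cs <- (floor(c0 - w)):(ceiling(c0 + w))
  sum(outer((rs - r0)^2, (cs - c0)^2, "+") <= radius_px^2)
}

# Greedy placement of n points in [lo, hi] with minimum separation.
.place_separated <- function(n, lo, hi, min_sep, max_tries = 2000L) {
  xs <- numeric(0)
  tries <- 0L
  while (length(xs) < n && tries < max_tries * max(n, 1L)) {
    cand <- runif(1, lo, hi)
    if (!length(xs) || min(abs(xs - cand)) >= min_sep) xs <- c(xs, cand)
    tries <- tries + 1L
  }
  if (length(xs) < n)
    stop("could not place ", n, " objects with the requested separation")
  xs
}

# 2-D greedy placement with pairwise minimum distance (per-point radius).
.place_separated_2d <- function(n, rlim, clim, radii, gap = 4,
                                max_tries = 4000L) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < max_tries * max(n, 1L)) {
    i <- nrow(pts) + 1L
    cand <- c(runif(1, rlim[1], rlim[2]), runif(1, clim[1], clim[2]))
    ok <- TRUE
    if (nrow(pts)) {
      d <- sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)
      ok <- all(d >= radii[seq_len(nrow(pts))] + radii[i] + gap)
    }
    if (ok) pts <- rbind(pts, cand)
    tries <- tries + 1L
  }
  if (nrow(pts) < n)
    stop("could not place ", n, " objects with the requested separation")
  pts
}

.empty_truth <- function(params, kind) {
  structure(list(objects = data.frame(), kind = kind, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth:%s> %d object record(s)\n", x$kind,
              nrow(x$objects)))
  invisible(x)
}

#' Simulate a TMRM-style tunnel time-lapse
#'
#' Renders `n_frames` frames of `n_tunnels` tunnel segments, each holding
#' `n_stationary` fixed and `n_motile` moving puncta. Motile puncta
#' advance by `speed * frame_interval / pixel_size` columns per frame
#' along the tunnel axis (signed; + = anterograde under the ROI sign
#' convention). Optional `discs` inject stationary uniform discs of a
#' stated physical area, used to exercise size filters with an
#' unambiguous ground-truth footprint.
#'
#' Initial positions are chosen so every trajectory stays inside its
#' tunnel for the whole series; parameters that cannot satisfy this are
#' rejected.
#'
#' @param params a [sim_params].
#' @param discs optional data.frame with columns `tunnel`, `area_um2`
#'   of stationary discs to inject.
#' @return list: `series` ([image_series]), `truth` (`ground_truth` whose
#'   `objects` has kind, tunnel, row, col0 (1-based px), speed_um_s,
#'   motile, amplitude, shape, truth_pixel_count), `rois` (tunnel ROI
#'   table).
#' @export
gen_mito_series <- function(params, discs = NULL) {
  stopifnot(inherits(params, "sim_params"))
  rois <- tunnel_rois(params)
  nr <- max(rois$row1) + params$tunnel_gap_px
  nc <- max(rois$col1)
  L <- nc
  amp <- params$snr * params$noise_sd
  px_per_frame <- params$frame_interval / params$pixel_size
  margin <- ceiling(4 * params$psf_sigma) + 1

  objects <- .with_seed(params$seed, 0L, {
    recs <- list()
    for (ti in seq_len(params$n_tunnels)) {
      roi <- rois[ti, ]
      n_st <- params$n_stationary; n_mo <- params$n_motile
      # signed speeds, um/s
      sp <- if (n_mo == 0) numeric(0)
        else if (!is.null(params$speeds_um_s))
          rep_len(params$speeds_um_s, n_mo)
        else runif(n_mo, params$speed_range[1], params$speed_range[2]) *
          sample(c(-1, 1), n_mo, replace = TRUE)
      travel_px <- sp * px_per_frame * (params$n_frames - 1)
      if (any(abs(travel_px) > L - 2 * margin - 1))
        stop("motile object cannot stay inside the tunnel; reject params")
      # stationary objects: separate along the axis only (distinct
      # kymograph stripes) or across the whole strip (dense scenes)
      if (params$placement == "area" && n_st > 0) {
        pts <- .place_separated_2d(n_st, c(roi$row0 + 2, roi$row1 - 2),
                                   c(margin, L - margin),
                                   rep(params$min_separation_px / 2, n_st),
                                   gap = 0)
        rows_st <- pts[, 1]; cols_st <- pts[, 2]
      } else if (n_st > 0) {
        cols_st <- .place_separated(n_st, margin, L - margin,
                                    params$min_separation_px)
        rows_st <- runif(n_st, roi$row0 + 2, roi$row1 - 2)
      } else {
        cols_st <- numeric(0); rows_st <- numeric(0)
      }
      # motile start columns: whole trajectory inside [margin, L-margin]
      cols_mo <- vapply(travel_px, function(d) {
        lo <- margin + max(0, -d); hi <- (L - margin) - max(0, d)
        runif(1, lo, hi)
      }, numeric(1))
      rows <- c(rows_st, runif(n_mo, roi$row0 + 2, roi$row1 - 2))
      k <- n_st + n_mo
      if (k > 0)
        recs[[length(recs) + 1L]] <- data.frame(
          kind = "mito", tunnel = ti, row = rows,
          col0 = c(cols_st, cols_mo),
          speed_um_s = c(rep(0, n_st), sp),
          motile = rep(c(FALSE, TRUE), c(n_st, n_mo)),
          amplitude = amp, shape = params$object_shape,
          area_um2 = if (params$object_shape == "disc")
            params$object_area_um2 else NA_real_,
          truth_pixel_count = if (params$object_shape == "disc")
            mapply(.disc_pixel_count, rows, c(cols_st, cols_mo),
                   sqrt(params$object_area_um2 / pi) / params$pixel_size)
          else NA_real_)
      if (!is.null(discs)) {
        dd <- discs[discs$tunnel == ti, , drop = FALSE]
        if (nrow(dd)) {
          rad <- sqrt(dd$area_um2 / pi) / params$pixel_size
          cd <- .place_separated(nrow(dd), margin + max(rad),
                                 L - margin - max(rad),
                                 2 * max(rad) + params$min_separation_px)
          rd <- rep((roi$row0 + roi$row1) / 2, nrow(dd))
          recs[[length(recs) + 1L]] <- data.frame(
            kind = "mito", tunnel = ti, row = rd, col0 = cd,
            speed_um_s = 0, motile = FALSE, amplitude = amp,
            shape = "disc", area_um2 = dd$area_um2,
            truth_pixel_count = mapply(.disc_pixel_count, rd, cd, rad))
        }
      }
    }
    if (length(recs)) do.call(rbind, recs) else data.frame()
  })

  frames <- array(0, c(nr, nc, params$n_frames))
  bg <- .background_matrix(nr, nc, params$background, params$ramp_amplitude)
  for (t in seq_len(params$n_frames)) {
    img <- bg
    if (nrow(objects)) for (i in seq_len(nrow(objects))) {
      ob <- objects[i, ]
      ct <- ob$col0 + ob$speed_um_s * px_per_frame * (t - 1)
      img <- if (ob$shape == "disc")
        .render_disc(img, ob$row, ct,
                     sqrt(ob$area_um2 / pi) / params$pixel_size, ob$amplitude)
      else .render_blob(img, ob$row, ct, ob$amplitude, params$psf_sigma)
    }
    frames[, , t] <- .with_seed(params$seed, t, .add_noise(img, params$noise_sd))
  }

  truth <- structure(list(objects = objects, kind = "mito_series",
                          params = params), class = "ground_truth")
  list(series = image_series(frames, params$pixel_size,
                             params$frame_interval),
       truth = truth, rois = rois)
}

#' Simulate a neurite field with terminal boutons
#'
#' Neurites are smooth curvilinear strokes anchored at the image border
#' (the side facing the somata) that wander inward inside disjoint
#' horizontal bands; each free end carries a brighter terminal bouton
#' blob, and optional side branches add further free termini. The truth
#' records every free terminus, so the path-graph terminus count is the
#' oracle for skeleton endpoint detection.
#'
#' @param params a [sim_params].
#' @param n_neurites number of neurites (one free terminus each).
#' @param n_branches number of side branches (one extra terminus each;
#'   at most one per neurite).
#' @param shape image size `c(rows, cols)`.
#' @return list: `image` ([calibrated_image]), `truth` (`objects` has one
#'   row per free terminus with row/col), `mask` (logical rendered
#'   stroke mask, the truth foreground).
#' @export
gen_neurite_image <- function(params, n_neurites = 5L, n_branches = 2L,
                              shape = c(512L, 512L)) {
  stopifnot(inherits(params, "sim_params"), n_neurites >= 0,
            n_branches <= n_neurites)
  nr <- shape[1]; nc <- shape[2]
  amp <- params$snr * params$noise_sd
  stroke_r <- 1.6; bouton_r <- 3.0
  img <- matrix(params$background, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  termini <- list()

  # max-compositing: overlapping strokes stay at a uniform brightness,
  # as a uniformly labelled neurite would
  paint <- function(r, c, rad, a) {
    w <- ceiling(rad) + 1L
    r_lo <- max(1L, floor(r - w)); r_hi <- min(nr, ceiling(r + w))
    c_lo <- max(1L, floor(c - w)); c_hi <- min(nc, ceiling(c + w))
    if (r_hi < r_lo || c_hi < c_lo) return(invisible())
    rs <- r_lo:r_hi; cs <- c_lo:c_hi
    sel <- outer((rs - r)^2, (cs - c)^2, "+") <= rad^2
    img[rs, cs][sel] <<- pmax(img[rs, cs][sel], params$background + a)
    mask[rs, cs][sel] <<- TRUE
  }

  out <- .with_seed(params$seed, 101L, {
    if (n_neurites > 0) {
      band_h <- nr / n_neurites
      branch_in <- if (n_branches > 0)
        sort(sample(seq_len(n_neurites), n_branches)) else integer(0)
      for (i in seq_len(n_neurites)) {
        r0 <- band_h * (i - 0.5)
        from_left <- i %% 2L == 1L
        len <- round(runif(1, 0.55, 0.8) * (nc - 30))
        drift <- cumsum(rnorm(len, 0, 0.35))
        drift <- pmax(pmin(drift, band_h / 2 - 14), -(band_h / 2 - 14))
        rows <- r0 + drift
        cols <- if (from_left) seq_len(len) else nc - seq_len(len) + 1L
        # anchor the root beyond the border so its skeleton end stays at
        # the image edge (a root is not a free terminus)
        for (cb in 0:(-4)) paint(rows[1], if (from_left) cb else nc - cb + 1L,
                                 stroke_r, amp)
        for (j in seq_len(len)) paint(rows[j], cols[j], stroke_r, amp)
        tip <- c(rows[len], cols[len])
        paint(tip[1], tip[2], bouton_r, 1.4 * amp)
        termini[[length(termini) + 1L]] <-
          data.frame(kind = "bouton", neurite = i, row = tip[1],
                     col = tip[2])
        if (i %in% branch_in) {
          j0 <- round(len * runif(1, 0.35, 0.55))
          vdir <- if (drift[j0] > 0) -1 else 1
          blen <- round(min(band_h / 2 - 14 + abs(drift[j0]), 60) * 1.6)
          br <- rows[j0]; bc <- cols[j0]
          hstep <- if (from_left) 0.8 else -0.8
          for (j in seq_len(blen)) {
            br <- br + vdir * 0.6; bc <- bc + hstep
            paint(br, bc, stroke_r, amp)
          }
          paint(br, bc, bouton_r, 1.4 * amp)
          termini[[length(termini) + 1L]] <-
            data.frame(kind = "bouton", neurite = i, row = br, col = bc)
        }
      }
    }
    img <- .add_noise(img, params$noise_sd)
    img
  })

  objects <- if (length(termini)) do.call(rbind, termini) else data.frame()
  truth <- structure(list(objects = objects, kind = "neurites",
                          params = params), class = "ground_truth")
  list(image = calibrated_image(out, params$pixel_size), truth = truth,
       mask = mask)
}

#' Simulate two-channel synaptic marker puncta fields
#'
#' Renders a presynaptic and a postsynaptic channel of disc puncta. A
#' stated number of puncta are drawn with identical footprints in both
#' channels (the co-occurring "synapses", of known equivalent diameter);
#' the rest are channel-unique. The truth marks overlaps whose
#' equivalent diameter exceeds the 15-um upper cut-off applied by the
#' co-occurrence analysis.
#'
#' @param params a [sim_params].
#' @param n_overlap number of co-occurring puncta.
#' @param overlap_diameters_um equivalent diameters (um) recycled over
#'   the overlaps.
#' @param n_unique_a,n_unique_b channel-unique puncta counts.
#' @param unique_diameter_um diameter of channel-unique puncta, um.
#' @param shape image size `c(rows, cols)`.
#' @param cutoff_um upper cut-off recorded in the truth (default 15 um).
#' @return list: `channel_a`, `channel_b` ([calibrated_image]s), `truth`
#'   (`objects`: one row per overlap with centre, `equiv_diameter_um`,
#'   `truth_pixel_count`, `over_cutoff`).
#' @export
gen_synapse_channels <- function(params, n_overlap = 4L,
                                 overlap_diameters_um = 1,
                                 n_unique_a = 6L, n_unique_b = 6L,
                                 unique_diameter_um = 0.8,
                                 shape = c(256L, 256L), cutoff_um = 15) {
  stopifnot(inherits(params, "sim_params"), n_overlap >= 0)
  nr <- shape[1]; nc <- shape[2]
  amp <- params$snr * params$noise_sd
  d_ov <- rep_len(overlap_diameters_um, max(n_overlap, 0L))
  rad_ov <- d_ov / 2 / params$pixel_size
  rad_un <- unique_diameter_um / 2 / params$pixel_size
  n_tot <- n_overlap + n_unique_a + n_unique_b
  radii <- c(rad_ov, rep(rad_un, n_unique_a + n_unique_b))

  res <- .with_seed(params$seed, 202L, {
    m <- max(radii, 1) + 3
    pts <- if (n_tot > 0)
      .place_separated_2d(n_tot, c(m, nr - m), c(m, nc - m), radii)
      else matrix(numeric(0), 0, 2)
    a <- matrix(params$background, nr, nc)
    b <- matrix(params$background, nr, nc)
    i <- 0L
    for (k in seq_len(n_overlap)) {
      i <- i + 1L
      a <- .render_disc(a, pts[i, 1], pts[i, 2], rad_ov[k], amp)
      b <- .render_disc(b, pts[i, 1], pts[i, 2], rad_ov[k], 0.9 * amp)
    }
    for (k in seq_len(n_unique_a)) {
      i <- i + 1L
      a <- .render_disc(a, pts[i, 1], pts[i, 2], rad_un, amp)
    }
    for (k in seq_len(n_unique_b)) {
      i <- i + 1L
      b <- .render_disc(b, pts[i, 1], pts[i, 2], rad_un, 0.9 * amp)
    }
    list(a = .add_noise(a, params$noise_sd),
         b = .add_noise(b, params$noise_sd), pts = pts)
  })

  objects <- if (n_overlap > 0) data.frame(
    kind = "synapse", row = res$pts[seq_len(n_overlap), 1],
    col = res$pts[seq_len(n_overlap), 2],
    equiv_diameter_um = d_ov,
    truth_pixel_count = vapply(seq_len(n_overlap), function(k)
      .disc_pixel_count(res$pts[k, 1], res$pts[k, 2], rad_ov[k]), numeric(1)),
    over_cutoff = d_ov > cutoff_um) else data.frame()
  truth <- structure(list(objects = objects, kind = "synapses",
                          params = params), class = "ground_truth")
  list(channel_a = calibrated_image(res$a, params$pixel_size),
       channel_b = calibrated_image(res$b, params$pixel_size),
       truth = truth)
}

#' Simulate a z-stack with signal confined to known slices
#'
#' Puncta appear (at fixed lateral positions) only in slices
#' `signal_slices[1]..signal_slices[2]`; all other slices carry only
#' background and noise. The truth height is
#' `(last - first + 1) * z_step` um.
#'
#' @param params a [sim_params].
#' @param n_slices total slices.
#' @param signal_slices inclusive slice range `c(first, last)` carrying
#'   signal.
#' @param n_puncta puncta per signal slice.
#' @param shape lateral image size.
#' @return list: `stack` ([zstack]), `truth` (`height_um`, slice range).
#' @export
gen_zstack <- function(params, n_slices = 20L, signal_slices = c(3L, 11L),
                       n_puncta = 25L, shape = c(128L, 128L)) {
  stopifnot(inherits(params, "sim_params"),
            signal_slices[1] >= 1, signal_slices[2] <= n_slices,
            signal_slices[1] <= signal_slices[2])
  nr <- shape[1]; nc <- shape[2]
  amp <- params$snr * params$noise_sd
  arr <- array(0, c(nr, nc, n_slices))
  pts <- .with_seed(params$seed, 303L,
    cbind(runif(n_puncta, 8, nr - 8), runif(n_puncta, 8, nc - 8)))
  for (z in seq_len(n_slices)) {
    img <- matrix(params$background, nr, nc)
    if (z >= signal_slices[1] && z <= signal_slices[2])
      for (k in seq_len(n_puncta))
        img <- .render_blob(img, pts[k, 1], pts[k, 2], amp, params$psf_sigma)
    arr[, , z] <- .with_seed(params$seed, 303L + z,
                             .add_noise(img, params$noise_sd))
  }
  height <- (signal_slices[2] - signal_slices[1] + 1) * params$z_step
  truth <- structure(
    list(objects = data.frame(kind = "zspan", first = signal_slices[1],
                              last = signal_slices[2],
                              height_um = height),
         height_um = height, kind = "zstack", params = params),
    class = "ground_truth")
  list(stack = zstack(arr, params$pixel_size, params$z_step), truth = truth)
}
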