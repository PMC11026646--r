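#' Kymograph construction and track analysis configuration
#'
#' @param stripe_k stationary-stripe threshold in robust SDs of the
#'   detrended column-median profile.
#' @param detrend_window running-median window (columns, odd) used to
#'   remove the background trend from the column-median profile.
#' @param min_rows minimum time extent (rows) of a candidate track.
#' @param min_r2 minimum R^2 of the per-branch line fit.
#' @param min_pixels minimum pixel support of a binarized component.
#' @param min_disp_um net displacement below which a track is labelled
#'   stationary; with path length >= `min_path_um` it is labelled
#'   bidirectional instead (reported separately, excluded from the
#'   motile ratio).
#' @param min_path_um see `min_disp_um`.
#' @param slope_tol_px merge tolerance on fitted slope (px/row) for
#'   branches split at junctions.
#' @param smooth_sigma Gaussian sigma (px) of the matched-filter
#'   smoothing applied to the filtered kymograph before binarization
#'   (0 disables).
#' @param close_radius_px half-length (columns) of the 3-row closing
#'   kernel that bridges the per-frame footprints of fast objects (whose
#'   successive positions need not overlap between rows) into one
#'   connected trace.
#' @param floor_k noise floor for binarization, in MADs above the median
#'   of the (smoothed) filtered kymograph; the effective threshold is
#'   the larger of the Otsu threshold and this floor, which protects the
#'   histogram split when moving objects occupy only a tiny fraction of
#'   the kymograph.
#' @param intercept_tol_px merge tolerance on mid-series fitted column.
#' @param corridor_px half-width of the refit corridor around a
#'   candidate line, px.
#' @param min_coverage minimum fraction of spanned rows with mask
#'   support within 3 px of the fitted line (rejects corridor artefacts
#'   that bridge distinct trajectories).
#' @param min_px_per_row minimum mean refit support (mask pixels per
#'   contributing row) of an accepted track.
#' @param min_continuity minimum fraction of spanned rows in which the
#'   line rides above the noise level of the filtered kymograph (a real
#'   object emits in every frame; lines stitched across crossings of
#'   other trajectories do not).
#' @param min_fill minimum fraction of spanned rows contributing live
#'   mask support to the refit.
#' @return list of class `kymo_cfg`.
#' @export
kymo_cfg <- function(stripe_k = 6, detrend_window = 51L, min_rows = 10L,
                     min_r2 = 0.9, min_pixels = 6L, min_disp_um = 3,
                     min_path_um = 10, slope_tol_px = 0.6,
                     intercept_tol_px = 6, smooth_sigma = 1.5,
                     close_radius_px = 4L, floor_k = 6,
                     corridor_px = 8, min_coverage = 0.5,
                     min_px_per_row = 2.5, min_continuity = 0.8,
                     min_fill = 0.6) {
  structure(as.list(environment()), class = "kymo_cfg")
}

#' Build a kymograph from a tunnel time series
#'
#' Row `t` of the kymograph is the mean luminance across the tunnel
#' width at each position along the tunnel axis in frame `t`; rows are
#' stacked in time order. Stationary objects appear as vertical
#' stripes, moving objects as slanted lines whose slope is their speed.
#'
#' @param series an [image_series].
#' @param roi single-row tunnel ROI (from [tunnel_rois()]); must lie
#'   inside the frames.
#' @return Object of class `kymograph`: `matrix` (rows = time, cols =
#'   distance), `row_interval` (s), `col_size` (um/px), `tunnel`,
#'   `anterograde_sign`.
#' @export
build_kymograph <- function(series, roi) {
  stopifnot(inherits(series, "image_series"), dim(series$frames)[3] >= 2)
  d <- dim(series$frames)
  if (roi$row0 < 1 || roi$row1 > d[1] || roi$col0 < 1 || roi$col1 > d[2])
    stop("ROI lies outside the image")
  m <- t(apply(series$frames[roi$row0:roi$row1, roi$col0:roi$col1, ,
                             drop = FALSE], 3, colMeans))
  structure(list(matrix = m, row_interval = series$frame_interval,
                 col_size = series$pixel_size, tunnel = roi$tunnel,
                 anterograde_sign = roi$anterograde_sign),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> tunnel %s: %d rows (time) x %d cols, %.3g s/row, %.3g um/px\n",
              as.character(x$tunnel %||% "?"), nrow(x$matrix),
              ncol(x$matrix), x$row_interval, x$col_size))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Suppress stationary stripes in a kymograph
#'
#' Subtracts the temporal (per-column) median and clips at zero, which
#' removes vertical stripes — stationary objects — while a moving
#' object, present only briefly in any one column, survives. Stationary
#' objects are counted from the column-median profile: after removing
#' the background trend with a running median, contiguous runs of
#' columns exceeding `stripe_k` robust SDs are merged and counted as one
#' object each.
#'
#' @param kymo a `kymograph` with at least 3 rows.
#' @return list: `filtered` (kymograph), `n_stationary`, `stripe_cols`
#'   (logical per column), `median_profile`.
#' @export
suppress_stationary <- function(kymo) {
  stopifnot(inherits(kymo, "kymograph"), nrow(kymo$matrix) >= 3)
  med <- apply(kymo$matrix, 2, median)
  filt <- sweep(kymo$matrix, 2, med)
  filt[filt < 0] <- 0
  cfg <- kymo_cfg()
  w <- min(cfg$detrend_window, 2L * (ncol(kymo$matrix) %/% 2L) - 1L)
  # background trend of the median profile: a rolling lower quartile is
  # robust even where stripes cover most of the window
  base <- if (w >= 3)
    zoo::rollapply(zoo::zoo(med), width = w, FUN = quantile, probs = 0.25,
                   partial = TRUE)
  else med * 0 + median(med)
  resid <- med - as.numeric(base)
  resid <- resid - median(resid)   # remove the quantile-baseline offset
  # stripes only push the profile upward, so the negative residuals are
  # a contamination-free noise sample
  neg <- resid[resid < 0]
  s <- if (length(neg) >= 10) sqrt(mean(neg^2)) else 0
  thr <- if (s > 0) cfg$stripe_k * s else 0.5 * max(resid)
  stripe <- if (max(resid) > 0) resid > thr else rep(FALSE, length(med))
  runs <- rle(stripe)
  n_stat <- sum(runs$values)
  out <- kymo
  out$matrix <- filt
  list(filtered = out, n_stationary = as.integer(n_stat),
       stripe_cols = stripe, median_profile = med)
}

# least-squares fit col ~ row for a pixel set; returns slope (px/row),
# fitted col at the mid-row of the kymograph, R^2 and row span.
.fit_branch <- function(rows, cols, mid_row) {
  rspan <- diff(range(rows))
  if (rspan == 0)
    return(list(slope = Inf, c_mid = mean(cols), r2 = 0,
                row0 = min(rows), row1 = max(rows)))
  f <- lm(cols ~ rows)
  ss_res <- sum(f$residuals^2)
  ss_tot <- sum((cols - mean(cols))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = unname(coef(f)[2]),
       c_mid = unname(coef(f)[1] + coef(f)[2] * mid_row), r2 = r2,
       row0 = min(rows), row1 = max(rows))
}

#' Detect motile tracks in a filtered kymograph
#'
#' Binarizes the stripe-suppressed kymograph (Otsu with a robust noise
#' floor), closes small gaps (fast objects leave dashed traces),
#' skeletonizes the foreground, splits the skeleton at junction pixels
#' and fits a least-squares line (column vs. time row) to every branch.
#' Branches whose fitted lines agree (e.g. either side of a crossing)
#' are merged, and each candidate track is then refit at subpixel
#' precision from the per-row intensity centroids inside a narrow
#' corridor around its line. Slope sign and the tunnel's
#' `anterograde_sign` give the direction; tracks with net displacement
#' below `min_disp_um` are labelled stationary (or bidirectional if
#' their path length is large) and are not counted as motile.
#'
#' @param filtered stripe-suppressed `kymograph` (from
#'   [suppress_stationary()]).
#' @param cfg a [kymo_cfg()].
#' @return data.frame of class `track_table`: one row per track with
#'   `slope_px_per_row`, `speed_um_s`, `net_displacement_um`,
#'   `direction` (anterograde/retrograde/stationary/bidirectional),
#'   `rows_spanned`, `r2`, `n_pixels`.
#' @export
detect_tracks <- function(filtered, cfg = kymo_cfg()) {
  stopifnot(inherits(filtered, "kymograph"))
  m <- filtered$matrix
  if (cfg$smooth_sigma > 0) m <- EBImage::gblur(m, cfg$smooth_sigma)
  empty <- data.frame(tunnel = integer(), slope_px_per_row = numeric(),
                      speed_um_s = numeric(),
                      net_displacement_um = numeric(),
                      direction = character(), rows_spanned = integer(),
                      r2 = numeric(), n_pixels = integer(),
                      c_mid = numeric(), row0 = integer(),
                      row1 = integer())
  as_table <- function(d) {
    d$c_mid <- NULL; d$row0 <- NULL; d$row1 <- NULL
    structure(d, class = c("track_table", "data.frame"))
  }
  # noise floor from the full filtered kymograph, fixed across passes
  floor_thr <- median(m) + cfg$floor_k * mad(m)
  weak_thr <- median(m) + 2 * mad(m)
  mid_row <- (nrow(m) + 1) / 2
  tt <- seq_len(nrow(m))
  consumed <- matrix(FALSE, nrow(m), ncol(m))
  out <- empty

  build_mask <- function() {
    m_work <- m
    m_work[consumed] <- 0
    # threshold the above-noise values: the clipped zero background
    # would otherwise dominate the histogram and pull Otsu down to the
    # noise level, flooding the mask with structure skirts
    vals <- m_work[m_work > floor_thr]
    thr <- if (length(vals) > 50 && diff(range(vals)) > 0) {
      h <- .intensity_histogram(vals)
      h$edges[.otsu_bin(h$counts) + 1L]
    } else -Inf
    # only let the structure-level split raise the threshold in
    # cluttered scenes, where the mask would otherwise drown in the
    # skirts of bright structures; in sparse scenes the faint traces
    # (SNR ~5 dashes) are the only signal and the floor is the cut
    if (mean(m_work > floor_thr) < 0.05) thr <- -Inf
    mask <- m_work > max(thr, floor_thr)
    comp <- connected_components(mask, connectivity = 8L)
    lab <- attr(comp, "labels")
    mask[lab %in% comp$label[comp$pixel_count < cfg$min_pixels]] <- FALSE
    if (!any(mask)) return(NULL)
    if (cfg$close_radius_px > 0) {
      # anisotropic closing along the distance axis: successive
      # positions of a fast object are offset mainly in columns
      brush <- matrix(1, 3L, 2L * cfg$close_radius_px + 1L)
      mask <- EBImage::closing(mask * 1, brush) > 0.5
    }
    mask & !consumed
  }

  gen_candidates <- function(live) {
    fits <- list()
    skel <- skeletonize(live)
    nb <- .neighbor_count(skel)
    branches <- skel & nb <= 2          # remove junction pixels
    bcomp <- connected_components(branches, connectivity = 8L)
    blab <- attr(bcomp, "labels")
    for (b in bcomp$label[bcomp$pixel_count >= 3]) {
      idx <- which(blab == b, arr.ind = TRUE)
      if (diff(range(idx[, 1])) + 1 < 3) next
      f <- .fit_branch(idx[, 1], idx[, 2], mid_row)
      if (!is.finite(f$slope)) next
      f$n_pixels <- nrow(idx)
      fits[[length(fits) + 1L]] <- f
    }
    # whole-component candidates: a single uncrossed trajectory gives a
    # thin connected component whose pixel cloud fits its line directly
    ccomp <- connected_components(live, connectivity = 8L)
    clab <- attr(ccomp, "labels")
    for (b in ccomp$label) {
      if (ccomp$bbox_row1[b] - ccomp$bbox_row0[b] < cfg$min_rows) next
      idx <- which(clab == b, arr.ind = TRUE)
      f <- .fit_branch(idx[, 1], idx[, 2], mid_row)
      if (!is.finite(f$slope)) next
      f$n_pixels <- nrow(idx)
      fits[[length(fits) + 1L]] <- f
    }
    # exhaustive slope-scan candidates: project the masked intensity
    # along every candidate slope and keep intercepts with strong,
    # extended support; recovers trajectories whose skeleton evidence
    # is fragmented by crossings. Every candidate still has to survive
    # the least-squares refit, fit-quality and coverage checks.
    L <- m * live
    nrm <- nrow(m); ncm <- ncol(m)
    max_slope <- ceiling(2.5 / (filtered$col_size / filtered$row_interval))
    for (sl in seq(-max_slope, max_slope, by = 0.5)) {
      acc <- numeric(ncm)
      cnt <- numeric(ncm)
      for (t in seq_len(nrm)) {
        off <- round(sl * (t - mid_row))
        src <- seq_len(ncm) + off
        ok <- src >= 1L & src <= ncm
        acc[ok] <- acc[ok] + L[t, src[ok]]
        cnt[ok] <- cnt[ok] + (live[t, src[ok]] > 0)
      }
      if (!any(cnt >= cfg$min_rows)) next
      thr_e <- 0.3 * max(acc)
      for (c0 in which(cnt >= cfg$min_rows & acc > thr_e)) {
        lo <- max(1L, c0 - 3L); hi <- min(ncm, c0 + 3L)
        if (acc[c0] < max(acc[lo:hi])) next
        fits[[length(fits) + 1L]] <- list(slope = sl, c_mid = c0,
                                          r2 = NA, row0 = 1, row1 = nrm,
                                          n_pixels = cnt[c0])
      }
    }
    if (!length(fits)) return(list())
    # merge candidates describing the same line (junction/dash splits)
    k <- length(fits)
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
      if (abs(fits[[i]]$slope - fits[[j]]$slope) <= cfg$slope_tol_px &&
          abs(fits[[i]]$c_mid - fits[[j]]$c_mid) <= cfg$intercept_tol_px) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    groups <- vapply(seq_len(k), find, integer(1))
    cands <- lapply(unique(groups), function(g) {
      fs <- fits[groups == g]
      npx <- vapply(fs, function(f) f$n_pixels, numeric(1))
      list(slope = sum(vapply(fs, function(f) f$slope, numeric(1)) * npx) /
             sum(npx),
           c_mid = sum(vapply(fs, function(f) f$c_mid, numeric(1)) * npx) /
             sum(npx),
           support = sum(npx))
    })
    cands[order(-vapply(cands, function(x) x$support, numeric(1)))]
  }

  # detect-and-subtract: extract tracks strongest-first, consume their
  # per-row footprints, and re-threshold the residual kymograph on the
  # next pass so dimmer traces (e.g. the dashed footprints of fast
  # objects) are not lost behind the histogram mass of brighter ones
  for (pass in 1:4) {
    mask <- build_mask()
    if (is.null(mask) || !any(mask)) break
    live <- mask
    accepted <- 0L
    for (cd in gen_candidates(live)) {
      slope <- cd$slope; cmid <- cd$c_mid
      f <- NULL; wsum <- 0; pts_r <- numeric(0)
      for (it in 1:3) {
        pred <- cmid + slope * (tt - mid_row)
        pts_r <- numeric(0); pts_c <- numeric(0); wsum <- 0
        for (t in tt) {
          lo <- max(1L, floor(pred[t] - cfg$corridor_px))
          hi <- min(ncol(m), ceiling(pred[t] + cfg$corridor_px))
          if (lo > hi) next
          seg <- which(live[t, lo:hi])
          if (!length(seg)) next
          # associate the row with the contiguous run nearest the line,
          # so bright structures passing through the corridor do not
          # drag the centroid
          runs <- rle(diff(c(-10L, seg)) > 1L)
          starts <- which(diff(c(-10L, seg)) > 1L)
          bounds <- c(starts, length(seg) + 1L)
          centres <- vapply(seq_len(length(bounds) - 1L), function(k)
            mean(seg[bounds[k]:(bounds[k + 1L] - 1L)]), numeric(1))
          kbest <- which.min(abs(centres + lo - 1 - pred[t]))
          run <- seg[bounds[kbest]:(bounds[kbest + 1L] - 1L)]
          cols <- lo + run - 1L
          w <- m[t, cols]
          pts_r <- c(pts_r, t)
          pts_c <- c(pts_c, sum(cols * w) / sum(w))
          wsum <- wsum + length(run)
        }
        if (length(pts_r) < 2 ||
            diff(range(pts_r)) + 1 < cfg$min_rows) { f <- NULL; break }
        f <- .fit_branch(pts_r, pts_c, mid_row)
        slope <- f$slope; cmid <- f$c_mid
      }
      if (is.null(f) || f$r2 < cfg$min_r2) next
      rspan <- diff(range(pts_r)) + 1
      # a real trajectory has live support in most rows it spans
      if (length(pts_r) / rspan < cfg$min_fill) next
      # a real trajectory contributes its full footprint (several
      # pixels) in every row where it has support; lines stitched
      # through stray pixels and track edges do not
      if (wsum / length(pts_r) < cfg$min_px_per_row) next
      # coverage check: a real trajectory leaves pixels close to its
      # line in most rows it spans; corridor artefacts bridging
      # distinct trajectories do so only near crossings
      pred <- f$c_mid + f$slope * (tt - mid_row)
      span_rows <- min(pts_r):max(pts_r)
      near <- function(t, w) {
        lo <- max(1L, floor(pred[t] - w))
        hi <- min(ncol(m), ceiling(pred[t] + w))
        if (lo > hi) integer(0) else lo:hi
      }
      cov <- mean(vapply(span_rows, function(t) {
        ix <- near(t, 3); length(ix) > 0 && any(mask[t, ix])
      }, logical(1)))
      if (cov < cfg$min_coverage) next
      # temporal continuity: a real object emits in (almost) every
      # frame it spans, so the line must ride above the noise level in
      # nearly all rows; lines stitched across crossings of other
      # trajectories sit on background in between and fail this
      cov_weak <- mean(vapply(span_rows, function(t) {
        ix <- near(t, 2)
        length(ix) > 0 && max(m[t, ix]) > weak_thr
      }, logical(1)))
      if (cov_weak < cfg$min_continuity) next
      # consume this track's per-row footprint: the contiguous run of
      # live pixels containing the fitted line. Removing the whole run
      # leaves no edge strips to seed shadow tracks, while a distinct
      # trajectory's separate run in the same corridor survives.
      for (t in span_rows) {
        ix <- near(t, 3)
        hit <- ix[live[t, ix]]
        if (length(hit)) {
          lo <- min(hit); hi <- max(hit)
          while (lo > 1L && live[t, lo - 1L]) lo <- lo - 1L
          while (hi < ncol(m) && live[t, hi + 1L]) hi <- hi + 1L
          live[t, lo:hi] <- FALSE
        }
        # blank a wider halo for later passes, so the sub-threshold
        # skirt of this track cannot resurface once re-thresholded
        ixw <- near(t, cfg$corridor_px + 4)
        if (length(ixw)) consumed[t, ixw] <- TRUE
      }
      net_um <- f$slope * (rspan - 1) * filtered$col_size
      path_um <- abs(f$slope) * (rspan - 1) * filtered$col_size
      dir <- if (abs(net_um) >= cfg$min_disp_um) {
        if (sign(f$slope) * filtered$anterograde_sign > 0) "anterograde"
        else "retrograde"
      } else if (path_um >= cfg$min_path_um) "bidirectional"
      else "stationary"
      out <- rbind(out, data.frame(
        tunnel = filtered$tunnel %||% NA_integer_,
        slope_px_per_row = f$slope,
        speed_um_s = abs(f$slope) * filtered$col_size /
          filtered$row_interval,
        net_displacement_um = net_um,
        direction = dir,
        rows_spanned = as.integer(rspan),
        r2 = f$r2,
        n_pixels = as.integer(wsum),
        c_mid = f$c_mid, row0 = min(pts_r), row1 = max(pts_r)))
      accepted <- accepted + 1L
    }
    if (accepted == 0L) break
  }
  # two fitted lines that stay within the corridor of each other over
  # the shorter track's span describe the same trajectory (residues and
  # shadows of an already-extracted track), not a new object
  if (nrow(out) > 1) {
    out <- out[order(-out$rows_spanned, -out$n_pixels), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (j in 2:nrow(out)) for (i in seq_len(j - 1L)) {
      if (!keep[i] || !keep[j]) next
      overlap <- min(out$row1[i], out$row1[j]) -
        max(out$row0[i], out$row0[j])
      span <- if (overlap >= 1)
        max(out$row0[i], out$row0[j]):min(out$row1[i], out$row1[j])
      else out$row0[j]:out$row1[j]   # fragment continuation: extrapolate
      di <- out$c_mid[i] + out$slope_px_per_row[i] * (span - mid_row)
      dj <- out$c_mid[j] + out$slope_px_per_row[j] * (span - mid_row)
      # lines closer than the corridor on average are unresolvable at
      # this corridor width and count as one object
      if (abs(out$slope_px_per_row[i] - out$slope_px_per_row[j]) <= 2 &&
          mean(abs(di - dj)) <= cfg$corridor_px) keep[j] <- FALSE
      else if (overlap >= 1 && mean(abs(di - dj)) <= 4) keep[j] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
  }
  out$c_mid <- NULL; out$row0 <- NULL; out$row1 <- NULL
  as_table(out[order(-out$rows_spanned), , drop = FALSE])
}

#' Speed of a track
#'
#' Speed is the change in distance along the tunnel divided by the
#' change in time: `|delta columns| * col_size / (delta rows *
#' row_interval)`.
#'
#' @param track one row of a track table (uses `slope_px_per_row`).
#' @param kymo the kymograph the track came from.
#' @return speed, um/s.
#' @export
track_speed <- function(track, kymo) {
  abs(track$slope_px_per_row) * kymo$col_size / kymo$row_interval
}

#' Motility summary for one kymograph
#'
#' @param tracks track table from [detect_tracks()].
#' @param n_stationary stationary count from [suppress_stationary()].
#' @return list: `n_motile`, `n_stationary`, `n_bidirectional`,
#'   `motile_ratio` = motile / (motile + stationary),
#'   `mean_speed_um_s`, `anterograde_fraction` (NA when undefined),
#'   `undefined` flag.
#' @export
motility_summary <- function(tracks, n_stationary) {
  stopifnot(n_stationary >= 0)
  motile <- tracks[tracks$direction %in% c("anterograde", "retrograde"), ,
                   drop = FALSE]
  n_mo <- nrow(motile)
  denom <- n_mo + n_stationary
  list(n_motile = n_mo, n_stationary = as.integer(n_stationary),
       n_bidirectional = sum(tracks$direction == "bidirectional"),
       motile_ratio = if (denom > 0) n_mo / denom else NA_real_,
       mean_speed_um_s = if (n_mo > 0) mean(motile$speed_um_s) else NA_real_,
       anterograde_fraction = if (n_mo > 0)
         sum(motile$direction == "anterograde") / n_mo else NA_real_,
       undefined = denom == 0)
}
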