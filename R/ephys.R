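#' Configuration for spike detection and connectivity
#'
#' @param threshold_k detection threshold in SDs below the trace median
#'   (default 5: threshold = median - 5 * SD).
#' @param sd_estimator `"sd"` (plain standard deviation of the full
#'   filtered trace) or `"mad"` (robust alternative).
#' @param dead_time_s minimum time between detected events.
#' @param bin_ms spike-train bin width, ms.
#' @param max_lag_ms maximum signal lag scanned for the correlation
#'   peak.
#' @param min_spikes electrodes with fewer spikes per recording are
#'   inactive and excluded.
#' @param alpha pairs with peak-correlation p above this are excluded.
#' @param band band-pass edges, Hz.
#' @param order Butterworth order.
#' @return list of class `ephys_cfg`.
#' @export
ephys_cfg <- function(threshold_k = 5, sd_estimator = c("sd", "mad"),
                      dead_time_s = 0.001, bin_ms = 1, max_lag_ms = 100,
                      min_spikes = 10L, alpha = 0.001,
                      band = c(300, 3000), order = 2L) {
  sd_estimator <- match.arg(sd_estimator)
  structure(list(threshold_k = threshold_k, sd_estimator = sd_estimator,
                 dead_time_s = dead_time_s, bin_ms = bin_ms,
                 max_lag_ms = max_lag_ms, min_spikes = min_spikes,
                 alpha = alpha, band = band, order = order),
            class = "ephys_cfg")
}

#' Band-pass filter a raw recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass, 2nd order,
#' 300-3,000 Hz by default, applied per channel. Zero-phase filtering
#' keeps detection timestamps free of filter delay. The upper band edge
#' must lie below the Nyquist frequency.
#'
#' @param rec an `mea_recording`.
#' @param cfg an [ephys_cfg()].
#' @return The filtered `mea_recording`.
#' @export
bandpass <- function(rec, cfg = ephys_cfg()) {
  stopifnot(inherits(rec, "mea_recording"))
  if (rec$sampling_rate <= 2 * cfg$band[2])
    stop("sampling rate must exceed twice the upper band edge")
  bf <- signal::butter(cfg$order, cfg$band / (rec$sampling_rate / 2),
                       type = "pass")
  for (ch in seq_len(nrow(rec$traces)))
    rec$traces[ch, ] <- signal::filtfilt(bf, rec$traces[ch, ])
  rec
}

#' Detect spikes by a median-anchored amplitude threshold
#'
#' Per channel, the threshold is `median(trace) - k * SD(trace)` (SD of
#' the total signal, not a noise estimate). Each negative-going
#' excursion below the threshold yields one spike, timestamped at its
#' local minimum; a dead time after each event suppresses re-triggering.
#' Zero-variance traces yield no spikes.
#'
#' @param rec a filtered `mea_recording`.
#' @param cfg an [ephys_cfg()].
#' @return list of class `spike_trains`: `times` (list of timestamp
#'   vectors, s), `thresholds_uV`, `duration_s`, `electrode` ids.
#' @export
detect_spikes <- function(rec, cfg = ephys_cfg()) {
  stopifnot(inherits(rec, "mea_recording"))
  fs <- rec$sampling_rate
  dead <- round(cfg$dead_time_s * fs)
  times <- vector("list", nrow(rec$traces))
  thr <- numeric(nrow(rec$traces))
  for (ch in seq_len(nrow(rec$traces))) {
    x <- rec$traces[ch, ]
    s <- if (cfg$sd_estimator == "mad") mad(x) else sd(x)
    if (!is.finite(s) || s == 0) {
      times[[ch]] <- numeric(0); thr[ch] <- -Inf
      next
    }
    th <- median(x) - cfg$threshold_k * s
    thr[ch] <- th
    below <- x < th
    if (!any(below)) {
      times[[ch]] <- numeric(0)
      next
    }
    r <- rle(below)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    mins <- vapply(runs, function(i) {
      seg <- starts[i]:ends[i]
      seg[which.min(x[seg])]
    }, integer(1))
    # dead time between event minima
    keep <- logical(length(mins))
    last <- -Inf
    for (i in seq_along(mins)) {
      if (mins[i] - last >= dead) {
        keep[i] <- TRUE
        last <- mins[i]
      }
    }
    times[[ch]] <- (mins[keep] - 1L) / fs
  }
  structure(list(times = times, thresholds_uV = thr,
                 duration_s = rec$duration_s,
                 electrode = rec$channel_map$electrode),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains> %d electrodes, %d spikes over %.1f s\n",
              length(x$times), sum(lengths(x$times)), x$duration_s))
  invisible(x)
}

#' Bin a spike train into counts
#'
#' Half-open 1-ms bins `[k, k+1)` by default; counts, not occupancy.
#' The binned counts always sum to the number of spikes.
#'
#' @param t spike timestamps, s.
#' @param duration_s recording duration, s.
#' @param bin_ms bin width, ms.
#' @return integer vector of length `ceiling(duration / bin)`.
#' @export
bin_spikes <- function(t, duration_s, bin_ms = 1) {
  n_bins <- ceiling(duration_s * 1000 / bin_ms)
  idx <- floor(t * 1000 / bin_ms) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  tabulate(idx, n_bins)
}

#' Mean firing rates
#'
#' Per-electrode rate = spikes / duration; the network MFR is the mean
#' over all recorded electrodes (set `active_only = TRUE` to average
#' over active electrodes instead).
#'
#' @param trains a `spike_trains` (or list of timestamp vectors).
#' @param duration_s recording duration, s.
#' @param active_only average the network MFR over electrodes with at
#'   least `min_spikes` spikes only.
#' @param min_spikes activity criterion used when `active_only = TRUE`.
#' @return list: `per_electrode` (spikes/s), `network_mfr`, `network_sd`.
#' @export
mean_firing_rate <- function(trains, duration_s, active_only = FALSE,
                             min_spikes = 10L) {
  stopifnot(duration_s > 0)
  tt <- if (inherits(trains, "spike_trains")) trains$times else trains
  per <- vapply(tt, length, integer(1)) / duration_s
  sel <- if (active_only) vapply(tt, length, integer(1)) >= min_spikes
  else rep(TRUE, length(per))
  list(per_electrode = per,
       network_mfr = if (any(sel)) mean(per[sel]) else NA_real_,
       network_sd = if (sum(sel) > 1) sd(per[sel]) else NA_real_)
}

# Sums needed for Pearson r at every non-negative lag 0..max_lag between
# x (fixed) and y (shifted later), via FFT cross-correlation and prefix
# sums; exact up to floating point.
.lag_r_onesided <- function(x, y, max_lag) {
  n <- length(x)
  N <- nextn(n + max_lag + 1L, 2)
  fx <- fft(c(x, rep(0, N - n)))
  fy <- fft(c(y, rep(0, N - n)))
  cc <- Re(fft(Conj(fx) * fy, inverse = TRUE)) / N
  sxy <- cc[1:(max_lag + 1L)]          # sum_i x_i * y_{i+L}, L = 0..max_lag
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  L <- 0:max_lag
  m <- n - L
  sx <- cx[n - L]                      # sum x_i, i = 1..n-L
  sx2 <- cx2[n - L]
  sy <- cy[n] - c(0, cy[L[-1]])        # sum y_i, i = L+1..n
  sy2 <- cy2[n] - c(0, cy2[L[-1]])
  num <- m * sxy - sx * sy
  den2 <- (m * sx2 - sx^2) * (m * sy2 - sy^2)
  r <- ifelse(den2 > 0, num / sqrt(den2), NA_real_)
  list(lag = L, r = r, m = m)
}

#' Lagged Pearson correlation between two binned trains
#'
#' Pearson's r between train `a` and train `b` shifted by every integer
#' lag in `[-max_lag, +max_lag]` ms (non-overlapping bins dropped). The
#' reported correlation is the signed maximum over lags ("peak lag");
#' ties break toward the smaller |lag|. The p-value is the two-sided
#' t-distribution transform of r at the peak with `n_overlap - 2`
#' degrees of freedom, applied to the peak only (the lag scan is not
#' corrected for, matching the procedure this implements). A
#' positive peak lag means `b` follows `a`.
#'
#' @param a,b binned count vectors of equal length (1-ms bins).
#' @param max_lag_ms maximum lag, ms (bins).
#' @param full return the whole lag profile as well.
#' @return list: `peak_r`, `peak_lag_ms`, `p`, `n_overlap`; with
#'   `full = TRUE` also `lags_ms` and `r` vectors.
#' @export
lagged_correlation <- function(a, b, max_lag_ms = 100, full = FALSE) {
  stopifnot(length(a) == length(b), length(a) > max_lag_ms + 2)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(peak_r = NA_real_, peak_lag_ms = NA_real_, p = NA_real_,
                n_overlap = NA_integer_, degenerate = TRUE))
  pos <- .lag_r_onesided(a, b, max_lag_ms)     # b follows a: lag >= 0
  neg <- .lag_r_onesided(b, a, max_lag_ms)     # a follows b: lag <= 0
  lags <- c(-rev(neg$lag[-1]), pos$lag)
  r <- c(rev(neg$r[-1]), pos$r)
  m <- c(rev(neg$m[-1]), pos$m)
  ok <- is.finite(r)
  # peak = max signed r; ties toward smaller |lag|
  ord <- order(-r[ok], abs(lags[ok]))
  best <- which(ok)[ord[1]]
  pr <- r[best]; pm <- m[best]
  tstat <- pr * sqrt((pm - 2) / max(1 - pr^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), pm - 2)
  out <- list(peak_r = pr, peak_lag_ms = lags[best], p = p,
              n_overlap = pm, degenerate = FALSE)
  if (full) {
    out$lags_ms <- lags
    out$r <- r
  }
  out
}

#' Network functional connectivity from binned trains
#'
#' Excludes inactive electrodes (fewer than `min_spikes` spikes), then
#' computes the peak-lag Pearson correlation for every unordered pair
#' of active electrodes, excludes non-significant pairs
#' (p > `alpha`), and reports the total network correlation as the mean
#' peak r over included pairs. With fewer than two active electrodes
#' the total is undefined and flagged.
#'
#' @param trains a `spike_trains` object, or a list of binned count
#'   vectors.
#' @param duration_s recording duration, s (needed to bin timestamp
#'   trains).
#' @param cfg an [ephys_cfg()].
#' @return list of class `connectivity`: `pairs` (data.frame a, b,
#'   n_spikes_a/b, r, lag_ms, p, included), `total_network_correlation`,
#'   `n_active`, `undefined` flag.
#' @export
network_correlation <- function(trains, duration_s = NULL,
                                cfg = ephys_cfg()) {
  if (inherits(trains, "spike_trains")) {
    duration_s <- trains$duration_s
    counts <- vapply(trains$times, length, integer(1))
    binned <- lapply(trains$times, bin_spikes, duration_s = duration_s,
                     bin_ms = cfg$bin_ms)
  } else {
    stopifnot(!is.null(duration_s))
    binned <- trains
    counts <- vapply(binned, sum, numeric(1))
  }
  n <- length(binned)
  stopifnot(n >= 2)
  active <- which(counts >= cfg$min_spikes)
  pairs <- list()
  if (length(active) >= 2) {
    cmb <- utils::combn(active, 2)
    for (k in seq_len(ncol(cmb))) {
      i <- cmb[1, k]; j <- cmb[2, k]
      lc <- lagged_correlation(binned[[i]], binned[[j]], cfg$max_lag_ms)
      pairs[[k]] <- data.frame(
        a = i, b = j, n_spikes_a = counts[i], n_spikes_b = counts[j],
        r = lc$peak_r, lag_ms = lc$peak_lag_ms, p = lc$p,
        included = isFALSE(lc$degenerate) && !is.na(lc$p) &&
          lc$p <= cfg$alpha)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a = integer(), b = integer(), n_spikes_a = integer(),
               n_spikes_b = integer(), r = numeric(), lag_ms = numeric(),
               p = numeric(), included = logical())
  undefined <- length(active) < 2
  total <- if (!undefined && any(pairs$included))
    mean(pairs$r[pairs$included]) else NA_real_
  structure(list(pairs = pairs, total_network_correlation = total,
                 n_active = length(active), undefined = undefined),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> %d active electrodes, %d/%d pairs included, total r = %.4g\n",
              x$n_active, sum(x$pairs$included), nrow(x$pairs),
              x$total_network_correlation))
  invisible(x)
}
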