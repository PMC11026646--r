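#' Biphasic extracellular spike template
#'
#' A fixed 1-ms template (at the given sampling rate) with a dominant
#' negative phase followed by a smaller positive rebound, scaled so its
#' minimum equals `amplitude_uV`. The truth timestamp of an injected
#' spike is the time of the template minimum.
#'
#' @param sampling_rate Hz.
#' @param amplitude_uV peak (negative) amplitude, uV.
#' @return numeric vector of template samples; attribute `peak_index`
#'   marks the minimum (1-based).
#' @export
spike_template <- function(sampling_rate = 10000, amplitude_uV = -60) {
  n <- max(6L, round(sampling_rate / 1000))   # 1 ms worth of samples
  t <- seq(0, 1, length.out = n)
  w <- -exp(-((t - 0.3) / 0.12)^2) + 0.35 * exp(-((t - 0.62) / 0.16)^2)
  w <- w / max(abs(w)) * abs(amplitude_uV) * sign(amplitude_uV) * -1
  # sign convention: template minimum equals amplitude_uV (< 0)
  w <- w / min(w) * amplitude_uV
  structure(w, peak_index = which.min(w))
}

.poisson_train <- function(rate_hz, duration_s, refractory_s, t_margin) {
  if (rate_hz <= 0) return(numeric(0))
  n <- rpois(1, rate_hz * duration_s)
  if (n == 0) return(numeric(0))
  t <- sort(runif(n, t_margin, duration_s - t_margin))
  keep <- c(TRUE, diff(t) >= refractory_s)
  # iterate: removing a spike can expose a new too-close pair
  while (!all(keep)) {
    t <- t[keep]
    keep <- c(TRUE, diff(t) >= refractory_s)
  }
  t
}

#' Simulate a raw MEA recording with known spike times
#'
#' Each channel is Gaussian noise plus a fixed biphasic negative-peak
#' waveform injected at Poisson times (with a refractory gap enforced in
#' the truth). Coupled pairs defined in `params$coupled_pairs` share
#' co-spikes: every spike on electrode `a` is echoed on electrode `b`
#' at the stated lag with the stated probability. The truth lists every
#' injected spike time (time of the waveform minimum).
#'
#' @param params a [sim_params] (uses `sampling_rate`, `duration_s`,
#'   `n_channels`, `rate_hz`, `noise_sd_uV`, `spike_amplitude_uV`,
#'   `refractory_s`, `coupled_pairs`, `seed`).
#' @return list: `recording` (class `mea_recording`: `traces` channels x
#'   samples matrix in uV, `sampling_rate`, `duration_s`, `channel_map`),
#'   `truth` (`spike_times`: list per channel; `objects`: long table).
#' @export
gen_mea_recording <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  fs <- params$sampling_rate
  ns <- round(params$duration_s * fs)
  nch <- params$n_channels
  if (abs(params$spike_amplitude_uV) < 5 * params$noise_sd_uV)
    warning("spike amplitude below 5x noise floor: detection underpowered")
  tmpl <- spike_template(fs, params$spike_amplitude_uV)
  pk <- attr(tmpl, "peak_index")
  rates <- rep_len(params$rate_hz, nch)
  t_margin <- 0.01

  spike_times <- vector("list", nch)
  for (ch in seq_len(nch))
    spike_times[[ch]] <- .with_seed(params$seed, 1000L + ch,
      .poisson_train(rates[ch], params$duration_s, params$refractory_s,
                     t_margin))
  # couplings: echo a's spikes onto b at lag
  for (k in seq_along(params$coupled_pairs)) {
    cp <- params$coupled_pairs[[k]]
    echo <- .with_seed(params$seed, 2000L + k, {
      src <- spike_times[[cp$a]]
      src <- src[runif(length(src)) <= cp$prob]
      src + cp$lag_ms / 1000
    })
    echo <- echo[echo > t_margin & echo < params$duration_s - t_margin]
    tb <- sort(c(spike_times[[cp$b]], echo))
    keep <- c(TRUE, diff(tb) >= params$refractory_s)
    while (!all(keep)) {
      tb <- tb[keep]
      keep <- c(TRUE, diff(tb) >= params$refractory_s)
    }
    spike_times[[cp$b]] <- tb
  }

  traces <- matrix(0, nch, ns)
  for (ch in seq_len(nch)) {
    x <- .with_seed(params$seed, 3000L + ch,
                    rnorm(ns, 0, params$noise_sd_uV))
    for (t0 in spike_times[[ch]]) {
      i0 <- round(t0 * fs) - pk + 1L
      idx <- i0:(i0 + length(tmpl) - 1L)
      ok <- idx >= 1L & idx <= ns
      x[idx[ok]] <- x[idx[ok]] + tmpl[ok]
    }
    # truth timestamp = sample of template minimum
    spike_times[[ch]] <- round(spike_times[[ch]] * fs) / fs
    traces[ch, ] <- x
  }

  objects <- if (any(lengths(spike_times) > 0)) do.call(rbind, lapply(
    seq_len(nch), function(ch) if (length(spike_times[[ch]]))
      data.frame(kind = "spike", electrode = ch, time_s = spike_times[[ch]])
    else NULL)) else data.frame()
  truth <- structure(list(objects = objects, spike_times = spike_times,
                          kind = "mea", params = params),
                     class = "ground_truth")
  rec <- structure(list(
    traces = traces, sampling_rate = fs, duration_s = params$duration_s,
    channel_map = data.frame(electrode = seq_len(nch),
                             chamber = paste0("chamber",
                                              (seq_len(nch) - 1L) %/%
                                                max(1L, nch %/% 2L) + 1L))),
    class = "mea_recording")
  list(recording = rec, truth = truth)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d ch x %d samples @ %g Hz (%.1f s), uV\n",
              nrow(x$traces), ncol(x$traces), x$sampling_rate,
              x$duration_s))
  invisible(x)
}

#' Read and write raw recordings (flat binary + sidecars)
#'
#' Traces are stored channel-major as little-endian float32 (`.raw`),
#' with acquisition metadata in `<path>.json` (sampling rate, channel
#' and sample counts, units) and the electrode-to-chamber map in
#' `<path>.channels.csv`.
#'
#' @param rec an `mea_recording`.
#' @param path base path of the `.raw` file.
#' @return `write_recording()` returns `path` invisibly;
#'   `read_recording()` an `mea_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$traces)), con, size = 4L, endian = "little")
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate,
                            duration_s = rec$duration_s,
                            n_channels = nrow(rec$traces),
                            n_samples = ncol(rec$traces), units = "uV"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  write.csv(rec$channel_map, paste0(path, ".channels.csv"),
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), meta$n_channels * meta$n_samples, size = 4L,
               endian = "little")
  structure(list(
    traces = matrix(x, meta$n_channels, meta$n_samples, byrow = TRUE),
    sampling_rate = meta$sampling_rate, duration_s = meta$duration_s,
    channel_map = read.csv(paste0(path, ".channels.csv"))),
    class = "mea_recording")
}
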