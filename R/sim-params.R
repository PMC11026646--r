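#' Simulation parameters
#'
#' One validated parameter set drives every synthetic scenario. Defaults
#' encode the acquisition geometry the analysis stages assume: 145-um
#' tunnel segments sampled at 0.2 um/px, time-lapse at 1 frame/s for
#' 60 s, and 7-min MEA recordings at 10 kHz. A single `seed` fixes all
#' randomness; per-frame and per-channel substreams are derived from it
#' so partial regeneration is reproducible.
#'
#' Imaging intensities are unitless luminance on an arbitrary linear
#' scale; the puncta amplitude is `snr * noise_sd`, so `snr` is the peak
#' signal-to-noise ratio of a rendered object over the Gaussian read
#' noise.
#'
#' @param pixel_size um/px.
#' @param frame_interval s/frame.
#' @param n_frames frames per time-lapse series.
#' @param psf_sigma Gaussian blob sigma, px (diffraction-limited puncta).
#' @param background flat background level.
#' @param ramp_amplitude peak-to-peak amplitude of the linear background
#'   ramp along the tunnel axis (non-uniform illumination).
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param snr peak object amplitude over `noise_sd`.
#' @param object_shape `"gauss"` (diffraction-limited blob) or `"disc"`
#'   (uniform disc of area `object_area_um2`, whose thresholded footprint
#'   is unambiguous; used for size-recovery scenarios).
#' @param object_area_um2 disc area when `object_shape = "disc"`, um^2.
#' @param n_stationary,n_motile mitochondria per tunnel.
#' @param speeds_um_s optional signed speeds (um/s, + = anterograde)
#'   recycled over motile objects; if `NULL`, speeds are drawn uniformly
#'   from `speed_range` with random sign.
#' @param speed_range range (um/s) for drawn speeds.
#' @param tunnel_length_um,tunnel_width_px,n_tunnels,tunnel_gap_px tunnel
#'   segment geometry.
#' @param min_separation_px minimum centre-to-centre object separation.
#' @param placement `"columns"` separates objects along the tunnel axis
#'   only (so each stationary object forms its own kymograph stripe);
#'   `"area"` separates them in 2-D across the tunnel strip (for dense
#'   static counting scenes).
#' @param z_step um per z-slice.
#' @param sampling_rate Hz (MEA).
#' @param duration_s recording length, s.
#' @param n_channels electrodes.
#' @param spike_amplitude_uV peak (negative) spike amplitude, uV.
#' @param noise_sd_uV trace noise SD, uV.
#' @param rate_hz per-electrode Poisson firing rate (recycled).
#' @param refractory_s minimum inter-spike interval enforced in truth.
#' @param coupled_pairs list of `list(a, b, lag_ms, prob)` couplings:
#'   each spike on electrode `a` triggers a co-spike on `b`, `lag_ms`
#'   later, with probability `prob`. Lags must lie in [-100, 100] ms.
#' @param seed integer seed fixing all randomness.
#' @return A validated list of class `sim_params`.
#' @export
sim_params <- function(pixel_size = 0.2, frame_interval = 1, n_frames = 60L,
                       psf_sigma = 1.5, background = 0.08,
                       ramp_amplitude = 0.05, noise_sd = 0.003, snr = 16,
                       object_shape = c("gauss", "disc"),
                       object_area_um2 = 0.5,
                       n_stationary = 10L, n_motile = 1L,
                       speeds_um_s = NULL, speed_range = c(0.2, 2.0),
                       tunnel_length_um = 145, tunnel_width_px = 11L,
                       n_tunnels = 1L, tunnel_gap_px = 6L,
                       min_separation_px = 10,
                       placement = c("columns", "area"),
                       z_step = 1,
                       sampling_rate = 10000, duration_s = 420,
                       n_channels = 12L, spike_amplitude_uV = -60,
                       noise_sd_uV = 5, rate_hz = 1,
                       refractory_s = 0.002, coupled_pairs = list(),
                       seed = 1L) {
  object_shape <- match.arg(object_shape)
  placement <- match.arg(placement)
  p <- as.list(environment())
  stopifnot(p$pixel_size > 0, p$frame_interval > 0, p$n_frames >= 1,
            p$sampling_rate > 0, p$duration_s > 0, p$noise_sd >= 0,
            p$psf_sigma > 0, p$tunnel_length_um > 0, p$z_step > 0,
            p$n_stationary >= 0, p$n_motile >= 0, p$snr >= 0)
  for (cp in p$coupled_pairs) {
    stopifnot(all(c("a", "b", "lag_ms", "prob") %in% names(cp)))
    if (abs(cp$lag_ms) > 100) stop("coupling lags must lie in [-100, 100] ms")
  }
  p$seed <- as.integer(seed)
  structure(p, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(paste0("<sim_params> %d tunnel(s) x %.0f um @ %.3g um/px, ",
                     "%d frames @ %.3g s | MEA %d ch @ %g Hz, %g s | seed %d\n"),
              x$n_tunnels, x$tunnel_length_um, x$pixel_size, x$n_frames,
              x$frame_interval, x$n_channels, x$sampling_rate, x$duration_s,
              x$seed))
  invisible(x)
}

#' Read/write simulation parameters as YAML
#' @param params a [sim_params] object.
#' @param path YAML file path.
#' @return `write_sim_params()` returns `path` invisibly;
#'   `read_sim_params()` a [sim_params].
#' @export
write_sim_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_sim_params
#' @export
read_sim_params <- function(path) {
  do.call(sim_params, yaml::read_yaml(path))
}

# Deterministic substream: set the RNG from (seed, k) without disturbing
# the caller's stream (caller must save/restore via .with_seed).
.substream <- function(seed, k = 0L) {
  set.seed((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

# Evaluate expr with a private RNG stream; restores the caller's state.
.with_seed <- function(seed, k, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  }
  .substream(seed, k)
  expr
}

#' Tunnel ROI table for a parameter set
#'
#' Tunnels are horizontal strips stacked down the image; columns run
#' along the tunnel axis. `anterograde_sign = +1` declares that the
#' somata face the low-column end, so increasing column index is
#' anterograde.
#'
#' @param params a [sim_params].
#' @return data.frame: `tunnel`, `row0`, `row1`, `col0`, `col1` (1-based,
#'   inclusive), `anterograde_sign`.
#' @export
tunnel_rois <- function(params) {
  w <- params$tunnel_width_px; g <- params$tunnel_gap_px
  L <- round(params$tunnel_length_um / params$pixel_size)
  data.frame(
    tunnel = seq_len(params$n_tunnels),
    row0 = g + (seq_len(params$n_tunnels) - 1L) * (w + g) + 1L,
    row1 = g + (seq_len(params$n_tunnels) - 1L) * (w + g) + w,
    col0 = 1L, col1 = as.integer(L),
    anterograde_sign = 1L)
}

#' Read/write tunnel ROIs as JSON
#' @param rois ROI data.frame from [tunnel_rois()].
#' @param path JSON file path.
#' @return `write_rois()` returns `path` invisibly; `read_rois()` the
#'   ROI data.frame.
#' @export
write_rois <- function(rois, path) {
  jsonlite::write_json(rois, path, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
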