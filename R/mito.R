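#' Configuration for mitochondria detection
#'
#' @param tophat_radius_um disc radius for background removal, um.
#' @param max_area_um2 components larger than this are rejected as
#'   artefacts (default 5 um^2).
#' @param max_eccentricity components more elongated than this are
#'   rejected (default 0.995); both rules target large, elongated
#'   image-edge artefacts.
#' @param min_area_um2 per-slice foreground area (um^2) required to call
#'   a z-slice "signal" in [zstack_height()].
#' @param floor_k robust noise floor for binarization: the effective
#'   threshold is the larger of the Otsu threshold and
#'   `median + floor_k * MAD` of the top-hatted frame. On a frame with
#'   no real foreground Otsu splits the noise; the floor keeps such
#'   frames empty. Set 0 to disable.
#' @return list of class `mito_cfg`.
#' @export
mito_cfg <- function(tophat_radius_um = 2, max_area_um2 = 5,
                     max_eccentricity = 0.995, min_area_um2 = 0.5,
                     floor_k = 6) {
  structure(list(tophat_radius_um = tophat_radius_um,
                 max_area_um2 = max_area_um2,
                 max_eccentricity = max_eccentricity,
                 min_area_um2 = min_area_um2, floor_k = floor_k),
            class = "mito_cfg")
}

#' Detect mitochondria in a calibrated frame
#'
#' Detection chain: white top-hat background removal, Otsu
#' thresholding, 8-connected component extraction, then artefact
#' rejection of components whose area exceeds `max_area_um2` or whose
#' eccentricity exceeds `max_eccentricity`. The count is the number of
#' retained components; each size is its pixel count times the squared
#' pixel size. A constant (e.g. blank) frame yields zero detections.
#'
#' @param frame a [calibrated_image].
#' @param cfg a [mito_cfg()].
#' @param roi optional single-row tunnel ROI (restricts analysis to the
#'   tunnel rectangle).
#' @return list of class `mito_detection`: `components` (retained),
#'   `rejected`, `count`, `sizes_um2`.
#' @export
detect_mitochondria <- function(frame, cfg = mito_cfg(), roi = NULL) {
  stopifnot(inherits(frame, "calibrated_image"))
  if (!is.null(roi))
    frame <- calibrated_image(
      frame$pixels[roi$row0:roi$row1, roi$col0:roi$col1, drop = FALSE],
      frame$pixel_size)
  flat <- tophat(frame, cfg$tophat_radius_um)
  th <- tryCatch(threshold_image(flat, "otsu"), error = function(e) NULL)
  if (is.null(th)) {
    comp <- connected_components(matrix(FALSE, 1, 1), frame$pixel_size)
    return(structure(list(components = comp, rejected = comp, count = 0L,
                          sizes_um2 = numeric(0)),
                     class = "mito_detection"))
  }
  floor_thr <- median(flat$pixels) + cfg$floor_k * mad(flat$pixels)
  mask <- flat$pixels > max(th$threshold, floor_thr)
  comp <- connected_components(mask, frame$pixel_size, connectivity = 8L)
  keep <- comp$area_um2 <= cfg$max_area_um2 &
    comp$eccentricity <= cfg$max_eccentricity
  structure(list(components = comp[keep, , drop = FALSE],
                 rejected = comp[!keep, , drop = FALSE],
                 count = sum(keep),
                 sizes_um2 = comp$area_um2[keep]),
            class = "mito_detection")
}

#' @export
print.mito_detection <- function(x, ...) {
  cat(sprintf("<mito_detection> %d retained, %d rejected\n", x$count,
              nrow(x$rejected)))
  invisible(x)
}

#' Paired mitochondria counts over timepoints
#'
#' Counts mitochondria per tunnel at each timepoint (the same tunnel
#' ROIs are applied at every timepoint, as when re-imaging the same
#' field), returning a table ready for paired statistics.
#'
#' @param frames_per_timepoint list (one element per timepoint) of
#'   [calibrated_image]s covering the same tunnels.
#' @param rois tunnel ROI table ([tunnel_rois()]).
#' @param cfg a [mito_cfg()].
#' @return data.frame: `tunnel`, one `count_t<k>` column per timepoint,
#'   and `diff` (last minus first) when there are exactly two.
#' @export
count_over_timepoints <- function(frames_per_timepoint, rois,
                                  cfg = mito_cfg()) {
  counts <- lapply(frames_per_timepoint, function(fr)
    vapply(seq_len(nrow(rois)), function(i)
      detect_mitochondria(fr, cfg, rois[i, ])$count, integer(1)))
  out <- data.frame(tunnel = rois$tunnel)
  for (k in seq_along(counts)) out[[paste0("count_t", k)]] <- counts[[k]]
  if (length(counts) == 2L) out$diff <- counts[[2]] - counts[[1]]
  out
}

#' Height of a structure from a z-stack
#'
#' A slice carries signal if its foreground area exceeds
#' `cfg$min_area_um2`, where foreground is defined by the Otsu threshold
#' of the maximum-intensity projection applied to every slice (a single
#' global threshold, so empty slices are not re-thresholded into
#' noise). Height is `(last - first + 1) * z_step` um over the signal
#' slices; a stack with no signal slice returns 0 with a warning.
#'
#' @param stack a [zstack].
#' @param cfg a [mito_cfg()] (uses `min_area_um2`).
#' @return list: `height_um`, `first`, `last`, `signal_area_um2` per
#'   slice.
#' @export
zstack_height <- function(stack, cfg = mito_cfg()) {
  stopifnot(inherits(stack, "zstack"))
  mip <- apply(stack$slices, c(1, 2), max)
  th <- tryCatch(threshold_image(mip, "otsu"), error = function(e) NULL)
  if (is.null(th)) {
    warning("constant stack: no signal slices")
    return(list(height_um = 0, first = NA_integer_, last = NA_integer_,
                signal_area_um2 = numeric(0)))
  }
  px2 <- stack$pixel_size^2
  areas <- vapply(seq_len(dim(stack$slices)[3]), function(z)
    sum(stack$slices[, , z] > th$threshold) * px2, numeric(1))
  sig <- which(areas > cfg$min_area_um2)
  if (!length(sig)) {
    warning("no slice exceeds the signal area criterion")
    return(list(height_um = 0, first = NA_integer_, last = NA_integer_,
                signal_area_um2 = areas))
  }
  list(height_um = (max(sig) - min(sig) + 1) * stack$z_step,
       first = min(sig), last = max(sig), signal_area_um2 = areas)
}

#' Foreground area ratio between two channels
#'
#' Otsu-binarizes each channel and returns the ratio of foreground
#' areas A/B (e.g. mitochondria over total alpha-synuclein coverage).
#'
#' @param chan_a,chan_b [calibrated_image]s of identical shape and
#'   calibration.
#' @return list: `ratio`, `area_a_um2`, `area_b_um2`, `undefined` flag
#'   (TRUE with `ratio = NA` when channel B has no foreground).
#' @export
area_ratio <- function(chan_a, chan_b) {
  stopifnot(inherits(chan_a, "calibrated_image"),
            inherits(chan_b, "calibrated_image"),
            all(dim(chan_a$pixels) == dim(chan_b$pixels)),
            chan_a$pixel_size == chan_b$pixel_size)
  px2 <- chan_a$pixel_size^2
  fg <- function(ci) tryCatch(sum(threshold_image(ci, "otsu")$mask),
                              error = function(e) 0L)
  a <- fg(chan_a) * px2
  b <- fg(chan_b) * px2
  if (b == 0)
    return(list(ratio = NA_real_, area_a_um2 = a, area_b_um2 = b,
                undefined = TRUE))
  list(ratio = a / b, area_a_um2 = a, area_b_um2 = b, undefined = FALSE)
}
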