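#' Configuration for bouton counting and synapse co-occurrence
#'
#' @param tophat_radius_um top-hat disc radius for background removal.
#' @param clahe_tiles CLAHE tile grid (n x n) for adaptive histogram
#'   equalization.
#' @param clahe_limit CLAHE contrast (clip) limit; 1 is close to a
#'   linear rescale, larger values allow stronger local equalization.
#' @param median_radius_px radius of the salt-noise median filter
#'   (1 = 3x3).
#' @param closing_radius_px disc radius of the morphological closing
#'   joining neurite fragments.
#' @param prune_px skeleton spurs up to this length are treated as
#'   junction artefacts and removed.
#' @param floor_k robust noise floor (MADs above the median of the
#'   top-hatted image) gating the binarized mask, so empty CLAHE tiles
#'   do not contribute equalized noise; 0 disables.
#' @param border_margin_px skeleton endpoints within this margin of the
#'   image border are ignored (neurites anchored at the field edge end
#'   there, not at a bouton).
#' @param cutoff_um upper limit on co-occurrence particle size; by
#'   default interpreted as an equivalent diameter in um
#'   (`cutoff_is_area = FALSE`); set `cutoff_is_area = TRUE` to read it
#'   as an area in um^2 instead.
#' @param cutoff_is_area see `cutoff_um`.
#' @return list of class `morpho_cfg`.
#' @export
morpho_cfg <- function(tophat_radius_um = 5, clahe_tiles = 8L,
                       clahe_limit = 2, median_radius_px = 1L,
                       closing_radius_px = 2L, prune_px = 6L, floor_k = 6,
                       border_margin_px = 12L, cutoff_um = 15,
                       cutoff_is_area = FALSE) {
  structure(as.list(environment()), class = "morpho_cfg")
}

# CLAHE with reflective padding so image dims divide the tile grid.
.clahe_padded <- function(px, tiles, limit) {
  nr <- nrow(px); nc <- ncol(px)
  pr <- (tiles - nr %% tiles) %% tiles
  pc <- (tiles - nc %% tiles) %% tiles
  if (pr > 0) px <- rbind(px, px[nr:(nr - pr + 1L), , drop = FALSE])
  if (pc > 0) px <- cbind(px, px[, (nc + 0L):(nc - pc + 1L)][,
                          seq_len(pc), drop = FALSE])
  hi <- max(px, 1e-12)
  out <- EBImage::clahe(px / hi, nx = tiles, ny = tiles, limit = limit)
  out[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Count neuritic boutons as skeleton endpoints
#'
#' Processing chain: top-hat background removal, contrast enhancement by
#' tiled adaptive histogram equalization, Otsu binarization, median
#' filtering of salt noise, morphological closing to join neurite
#' fragments, hole filling, thinning to a skeleton, then endpoint
#' detection (skeleton pixels with exactly one 8-neighbour, short spurs
#' pruned, border endpoints ignored). The preliminary automated count
#' can be augmented with manually curated additions from a review of
#' the overlay (`manual` data.frame of points).
#'
#' @param img a [calibrated_image].
#' @param cfg a [morpho_cfg()].
#' @param manual optional data.frame of manually added boutons (columns
#'   `row`, `col`), mirroring a visual-review step.
#' @return list of class `bouton_result`: `n_boutons` (automated),
#'   `n_manual_added`, `n_total`, `endpoints` (matrix row/col),
#'   `skeleton`, `mask`, `neurite_area_um2`, `density_per_um2`.
#' @export
count_boutons <- function(img, cfg = morpho_cfg(), manual = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  blank <- list(n_boutons = 0L, n_manual_added = 0L, n_total = 0L,
                endpoints = matrix(numeric(0), 0, 2),
                skeleton = matrix(FALSE, nrow(img$pixels),
                                  ncol(img$pixels)),
                mask = matrix(FALSE, nrow(img$pixels), ncol(img$pixels)),
                neurite_area_um2 = 0, density_per_um2 = NA_real_)
  flat <- tophat(img, cfg$tophat_radius_um)
  if (diff(range(flat$pixels)) == 0)
    return(structure(blank, class = "bouton_result"))
  enh <- .clahe_padded(flat$pixels, cfg$clahe_tiles, cfg$clahe_limit)
  mask <- threshold_image(enh, "otsu")$mask
  # tiles without structure get their noise equalized to full range;
  # gate the mask with a robust floor on the pre-equalization image
  floor_thr <- median(flat$pixels) + cfg$floor_k * mad(flat$pixels)
  mask <- mask & flat$pixels > floor_thr
  mask <- EBImage::medianFilter(mask * 1, cfg$median_radius_px) > 0.5
  brush <- EBImage::makeBrush(2L * cfg$closing_radius_px + 1L, "disc")
  mask <- EBImage::closing(mask * 1, brush) > 0.5
  mask <- EBImage::fillHull(mask * 1) > 0.5
  if (!any(mask)) return(structure(blank, class = "bouton_result"))
  skel <- skeletonize(mask)
  skel <- prune_spurs(skel, cfg$prune_px)
  skel <- skeletonize(skel)   # restore 1-px width after pruning
  ep <- skeleton_endpoints(skel, cfg$border_margin_px)
  n_manual <- if (is.null(manual)) 0L else nrow(manual)
  area <- sum(mask) * img$pixel_size^2
  n_total <- nrow(ep) + n_manual
  structure(list(n_boutons = nrow(ep), n_manual_added = n_manual,
                 n_total = n_total, endpoints = ep, skeleton = skel,
                 mask = mask, neurite_area_um2 = area,
                 density_per_um2 = if (area > 0) n_total / area
                 else NA_real_),
            class = "bouton_result")
}

#' @export
print.bouton_result <- function(x, ...) {
  cat(sprintf("<bouton_result> %d automated + %d manual boutons, %.1f um2 neurite area\n",
              x$n_boutons, x$n_manual_added, x$neurite_area_um2))
  invisible(x)
}

#' Neurite coverage area
#'
#' Total foreground area after Otsu binarization, measured by particle
#' analysis with no size bounds. A blank (constant) image returns 0
#' with a warning.
#'
#' @param img a [calibrated_image].
#' @return area, um^2.
#' @export
neurite_area <- function(img) {
  stopifnot(inherits(img, "calibrated_image"))
  th <- tryCatch(threshold_image(img, "otsu"), error = function(e) NULL)
  if (is.null(th)) {
    warning("constant image: area 0")
    return(0)
  }
  particle_analysis(th$mask, img$pixel_size)$total_area_um2
}

#' Pre/postsynaptic marker co-occurrence
#'
#' Thresholds the presynaptic channel with Otsu and the postsynaptic
#' channel with Triangle, intersects the two masks (logical AND), and
#' runs particle analysis on the overlap regions. Particles above the
#' upper cut-off (15 um equivalent diameter by default) are excluded.
#'
#' @param pre,post [calibrated_image]s sharing shape and calibration
#'   (e.g. Piccolo and PSD95 channels).
#' @param cfg a [morpho_cfg()].
#' @return list of class `synapse_overlap`: `n_overlaps`, `sizes_um2`,
#'   `equiv_diameters_um`, `mean_size_um2`, `n_excluded` (over cut-off).
#' @export
synapse_cooccurrence <- function(pre, post, cfg = morpho_cfg()) {
  stopifnot(inherits(pre, "calibrated_image"),
            inherits(post, "calibrated_image"),
            all(dim(pre$pixels) == dim(post$pixels)),
            pre$pixel_size == post$pixel_size)
  mask <- threshold_image(pre, "otsu")$mask &
    threshold_image(post, "triangle")$mask
  pa <- particle_analysis(mask, pre$pixel_size)
  max_area <- if (cfg$cutoff_is_area) cfg$cutoff_um
  else pi * (cfg$cutoff_um / 2)^2
  keep <- pa$sizes_um2 <= max_area
  structure(list(n_overlaps = sum(keep),
                 sizes_um2 = pa$sizes_um2[keep],
                 equiv_diameters_um = 2 * sqrt(pa$sizes_um2[keep] / pi),
                 mean_size_um2 = if (any(keep)) mean(pa$sizes_um2[keep])
                 else NA_real_,
                 n_excluded = sum(!keep)),
            class = "synapse_overlap")
}

#' @export
print.synapse_overlap <- function(x, ...) {
  cat(sprintf("<synapse_overlap> %d overlaps (mean %.3g um2), %d excluded by cut-off\n",
              x$n_overlaps, x$mean_size_um2, x$n_excluded))
  invisible(x)
}
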