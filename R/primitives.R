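#' White top-hat background removal
#'
#' Removes smooth non-uniform background illumination by subtracting the
#' grayscale morphological opening with a disc structuring element of the
#' given physical radius. Structures smaller than the disc survive; a
#' flat or slowly varying background maps to (approximately) zero. The
#' output never exceeds the input.
#'
#' @param img a [calibrated_image].
#' @param radius_um radius of the disc structuring element, um. Must be
#'   at least one pixel after conversion.
#' @return A [calibrated_image] of the same size.
#' @export
tophat <- function(img, radius_um) {
  stopifnot(inherits(img, "calibrated_image"), radius_um > 0)
  r_px <- radius_um / img$pixel_size
  if (r_px < 1) stop("top-hat radius is smaller than one pixel")
  brush <- EBImage::makeBrush(2L * as.integer(round(r_px)) + 1L, "disc")
  out <- img$pixels - EBImage::opening(img$pixels, brush)
  out[out < 0] <- 0
  calibrated_image(out, img$pixel_size)
}

# 256-bin histogram over the observed intensity range (Fiji-style).
# Returns counts and the bin centres/edges on the intensity scale.
.intensity_histogram <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) stop("image is constant: no two intensity classes")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins)
  list(counts = counts, edges = edges,
       centers = (edges[-1] + edges[-(nbins + 1L)]) / 2)
}

.otsu_bin <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  omega <- cumsum(p)
  mu <- cumsum(p * seq_along(p))
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b) # threshold bin: class 1 = bins <= this
}

.triangle_bin <- function(counts) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  # span from the peak toward the longer tail, flipping so the tail is
  # always to the right of the peak
  flip <- (peak - lo) > (hi - peak)
  h <- if (flip) rev(counts) else counts
  peak <- if (flip) length(counts) - peak + 1L else peak
  tail_end <- if (flip) length(counts) - lo + 1L else hi
  if (tail_end <= peak) return(if (flip) length(counts) - peak + 1L else peak)
  # perpendicular distance from each bin on [peak, tail_end] to the chord
  bx <- peak:tail_end
  dx <- tail_end - peak
  dy <- h[tail_end] - h[peak]
  d <- abs(dy * (bx - peak) - dx * (h[bx] - h[peak])) / sqrt(dx^2 + dy^2)
  best <- bx[which.max(d)]
  if (flip) length(counts) - best + 1L else best
}

#' Automatic histogram thresholding (Otsu / Triangle)
#'
#' Selects a global threshold from a 256-bin histogram of the observed
#' intensity range and returns the foreground mask of pixels strictly
#' above it. `"otsu"` maximises the between-class variance of the two
#' intensity classes; `"triangle"` takes the histogram bin farthest from
#' the chord joining the histogram peak to the end of its longer tail.
#' Both choices are invariant under affine rescaling of the intensities.
#'
#' @param img a [calibrated_image] (or bare numeric matrix).
#' @param method `"otsu"` or `"triangle"`.
#' @return A list with `mask` (logical matrix) and `threshold` (on the
#'   intensity scale; foreground is `> threshold`).
#' @export
threshold_image <- function(img, method = c("otsu", "triangle")) {
  method <- match.arg(method)
  px <- if (inherits(img, "calibrated_image")) img$pixels else img
  h <- .intensity_histogram(px)
  bin <- switch(method, otsu = .otsu_bin(h$counts),
                triangle = .triangle_bin(h$counts))
  thr <- h$edges[bin + 1L] # upper edge of the threshold bin
  list(mask = px > thr, threshold = thr)
}

#' Connected-component extraction with per-component shape measures
#'
#' Labels foreground pixels of a binary mask with 4- or 8-connectivity
#' and measures each component: pixel count, physical area, centroid,
#' bounding box and eccentricity. Eccentricity comes from the second
#' central moments of the pixel set (best-fit ellipse, with the 1/12
#' per-pixel variance of a unit square added so a one-pixel-wide line
#' stays strictly below 1); a perfect disc gives 0.
#'
#' @param mask logical (or 0/1) matrix.
#' @param pixel_size pixel size, um/px (area is `pixel_count *
#'   pixel_size^2`).
#' @param connectivity 4 or 8 (default 8, diagonal neighbours join).
#' @return A data.frame with one row per component: `label`,
#'   `pixel_count`, `area_um2`, `eccentricity`, `centroid_row`,
#'   `centroid_col`, `bbox_row0/row1/col0/col1` (0-based, half-open).
#'   The label matrix is attached as attribute `"labels"`.
#' @export
connected_components <- function(mask, pixel_size = 1, connectivity = 8L) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  lab <- .label_components_cpp(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    out <- data.frame(label = integer(), pixel_count = integer(),
                      area_um2 = numeric(), eccentricity = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      bbox_row0 = integer(), bbox_row1 = integer(),
                      bbox_col0 = integer(), bbox_col1 = integer())
    attr(out, "labels") <- lab
    return(out)
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- (idx - 1L) %% nrow(mask)      # 0-based row
  c <- (idx - 1L) %/% nrow(mask)     # 0-based col
  cnt <- tabulate(l, n)
  sr <- rowsum(r, l)[, 1]; sc <- rowsum(c, l)[, 1]
  mr <- sr / cnt; mc <- sc / cnt
  # second central moments with the unit-square pixel correction
  srr <- rowsum(r^2, l)[, 1] / cnt - mr^2 + 1 / 12
  scc <- rowsum(c^2, l)[, 1] / cnt - mc^2 + 1 / 12
  src <- rowsum(r * c, l)[, 1] / cnt - mr * mc
  tr <- srr + scc
  det <- srr * scc - src^2
  disc <- pmax(tr^2 / 4 - det, 0)
  l1 <- tr / 2 + sqrt(disc)
  l2 <- tr / 2 - sqrt(disc)
  ecc <- sqrt(pmax(1 - l2 / l1, 0))
  out <- data.frame(
    label = seq_len(n), pixel_count = cnt,
    area_um2 = cnt * pixel_size^2, eccentricity = ecc,
    centroid_row = mr, centroid_col = mc,
    bbox_row0 = tapply(r, l, min),
    bbox_row1 = tapply(r, l, max) + 1L,
    bbox_col0 = tapply(c, l, min),
    bbox_col1 = tapply(c, l, max) + 1L,
    row.names = NULL)
  attr(out, "labels") <- lab
  out
}

#' Particle analysis: count and size components within physical bounds
#'
#' Counts 8-connected particles whose area falls in
#' `[min_size, max_size]` (um^2) and reports their sizes and summed area,
#' mirroring the particle-analyzer style of measurement used for
#' foreground coverage and punctum statistics.
#'
#' @param mask logical matrix.
#' @param pixel_size um/px.
#' @param min_size,max_size inclusive area bounds, um^2.
#' @return A list: `count`, `sizes_um2` (sorted by label), `total_area_um2`,
#'   and the surviving `components` table.
#' @export
particle_analysis <- function(mask, pixel_size, min_size = 0,
                              max_size = Inf) {
  stopifnot(min_size <= max_size)
  comp <- connected_components(mask, pixel_size, connectivity = 8L)
  keep <- comp$area_um2 >= min_size & comp$area_um2 <= max_size
  comp <- comp[keep, , drop = FALSE]
  list(count = nrow(comp), sizes_um2 = comp$area_um2,
       total_area_um2 = sum(comp$area_um2), components = comp)
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical matrix.
#' @return Logical matrix: one-pixel-wide 8-connected skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  .thin_cpp(m) > 0L
}

# number of 8-neighbours of each foreground pixel
.neighbor_count <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  s <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- s + p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  s
}

#' Skeleton endpoints
#'
#' Endpoints are skeleton pixels with exactly one 8-neighbour. Optionally
#' ignores a margin at the image border (anchored structures entering the
#' field of view end at the border, not at a biological terminus).
#'
#' @param skel logical skeleton matrix.
#' @param border_margin_px margin, px, within which endpoints are ignored.
#' @return Two-column matrix of endpoint coordinates (row, col), 1-based.
#' @export
skeleton_endpoints <- function(skel, border_margin_px = 0L) {
  nb <- .neighbor_count(skel)
  ep <- skel & nb == 1
  if (border_margin_px > 0L) {
    nr <- nrow(ep); nc <- ncol(ep)
    b <- border_margin_px
    ep[c(seq_len(min(b, nr)), seq.int(max(nr - b + 1L, 1L), nr)), ] <- FALSE
    ep[, c(seq_len(min(b, nc)), seq.int(max(nc - b + 1L, 1L), nc))] <- FALSE
  }
  which(ep, arr.ind = TRUE)
}

#' Prune short skeleton spurs
#'
#' Iteratively removes endpoint pixels `n` times, then restores
#' single-pixel erosion of real branch tips by re-thinning. Branches
#' shorter than `n` pixels disappear entirely; long branches keep one
#' endpoint each. Used to suppress junction artefacts of thinning.
#'
#' @param skel logical skeleton matrix.
#' @param n number of pruning iterations (max spur length removed).
#' @return Pruned logical skeleton.
#' @export
prune_spurs <- function(skel, n = 5L) {
  s <- skel
  for (i in seq_len(n)) {
    nb <- .neighbor_count(s)
    tips <- s & nb <= 1
    if (!any(tips)) break
    s[tips] <- FALSE
  }
  s
}
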