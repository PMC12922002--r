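# Segmentation: minimum cross-entropy thresholding of the edge-enhanced
# image, reconstruction of solid objects from edge rings, declumping of
# touching spheroids and size/border filtering.

#' Segmentation parameter set
#'
#' Tunables of the object-identification stage. Defaults follow the
#' brightfield spheroid protocol: diameter gates 250--3000 px, minimum
#' cross-entropy threshold with smoothing scale 0 and correction factor
#' 0.7, threshold bounds \[0.02, 1.0\] (lower bound 0.015 captures thin
#' spike projections), border objects discarded.
#'
#' @param min_diameter,max_diameter Equivalent-circle diameter gates (px).
#' @param threshold_smoothing_scale Pre-threshold smoothing sigma; 0 = none.
#' @param threshold_correction Multiplier on the raw automatic threshold.
#' @param threshold_lower_bound,threshold_upper_bound Clamp for the
#'   corrected threshold, on the \[0, 1\] edge-mask intensity scale.
#' @param discard_border_objects Drop objects touching the image border.
#' @param fill_holes Fill interior holes after closing.
#' @param rim_correction Erode filled objects by half the estimated edge
#'   band thickness so the outline follows the gradient-ridge centerline
#'   rather than the band's outer edge (default TRUE).
#' @param closing_radius Structuring-element radius (px) for the closing
#'   that seals edge rings; default `min_diameter / 50`.
#' @param declump_sigma Extra smoothing (px) of the intensity image before
#'   seed detection; default `min_diameter / 25`.
#' @param declump_min_separation Minimum distance between declump seeds
#'   (px); default `min_diameter / 2`.
#' @param declump_min_depth Minimum distance-transform depth (px) for a
#'   seed; default `min_diameter / 4`. Prevents thin projections from
#'   seeding spurious splits.
#' @param declump_intensity_weight Blend between the smoothed-intensity
#'   surface (1) and the negated distance transform (0) used for seed
#'   detection; default 0.5.
#' @param perimeter_method `"chain_smooth"` (smoothed boundary polygon,
#'   default) or `"crofton"` (4-direction Crofton estimator), consumed by
#'   the measurement stage.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(min_diameter = 250,
                                max_diameter = 3000,
                                threshold_smoothing_scale = 0,
                                threshold_correction = 0.7,
                                threshold_lower_bound = 0.02,
                                threshold_upper_bound = 1.0,
                                discard_border_objects = TRUE,
                                fill_holes = TRUE,
                                rim_correction = TRUE,
                                closing_radius = NULL,
                                declump_sigma = NULL,
                                declump_min_separation = NULL,
                                declump_min_depth = NULL,
                                declump_intensity_weight = 0.5,
                                perimeter_method = c("chain_smooth", "crofton")) {
  stopifnot_scalar(min_diameter, "min_diameter", lo = 1)
  stopifnot_scalar(max_diameter, "max_diameter", lo = min_diameter + 1e-9)
  stopifnot_scalar(threshold_correction, "threshold_correction", lo = 1e-12)
  stopifnot_scalar(threshold_lower_bound, "threshold_lower_bound", 0, 1)
  stopifnot_scalar(threshold_upper_bound, "threshold_upper_bound",
                   threshold_lower_bound, 1)
  stopifnot_scalar(threshold_smoothing_scale, "threshold_smoothing_scale", lo = 0)
  stopifnot_scalar(declump_intensity_weight, "declump_intensity_weight", 0, 1)
  structure(list(
    min_diameter = min_diameter,
    max_diameter = max_diameter,
    threshold_method = "minimum_cross_entropy",
    threshold_smoothing_scale = threshold_smoothing_scale,
    threshold_correction = threshold_correction,
    threshold_lower_bound = threshold_lower_bound,
    threshold_upper_bound = threshold_upper_bound,
    discard_border_objects = isTRUE(discard_border_objects),
    declump_seed_method = "intensity",
    declump_divide_method = "shape",
    fill_holes = isTRUE(fill_holes),
    rim_correction = isTRUE(rim_correction),
    closing_radius = closing_radius %||% max(1, round(min_diameter / 50)),
    declump_sigma = declump_sigma %||% max(1, min_diameter / 25),
    declump_min_separation = declump_min_separation %||% (min_diameter / 2),
    declump_min_depth = declump_min_depth %||% (min_diameter / 4),
    declump_intensity_weight = declump_intensity_weight,
    perimeter_method = match.arg(perimeter_method)
  ), class = "segmentation_params")
}

#' Minimum cross-entropy (Li) threshold
#'
#' Selects the threshold minimizing Li's cross-entropy criterion between
#' the image and its two-level (below-mean / above-mean) representation.
#' The criterion is evaluated on a 256-bin histogram of the \[0, 1\]
#' intensities over every interior bin-edge candidate, so the result is
#' deterministic and dtype-independent; ties resolve to the smallest
#' threshold (favoring capture of thin projections).
#'
#' @param image Single-channel image in \[0, 1\].
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold value in (0, 1): the selected bin edge.
#' @export
min_cross_entropy_threshold <- function(image, n_bins = 256L) {
  px <- as.vector(as_pixels(image))
  if (length(unique(px)) < 2L)
    stop(structure(class = c("degenerate_image_error", "error", "condition"),
                   list(message = "constant image: no threshold exists",
                        call = sys.call(-1))))
  n_bins <- as.integer(n_bins)
  idx <- pmin(pmax(floor(px * n_bins), 0), n_bins - 1L)  # bin 0..n_bins-1
  h <- tabulate(idx + 1L, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  w <- h * centers                       # intensity mass per bin
  cw0 <- cumsum(h)                       # counts below edge k (bins 1..k)
  cm0 <- cumsum(w)
  n <- cw0[n_bins]; m <- cm0[n_bins]
  ks <- seq_len(n_bins - 1L)             # candidate edges k/n_bins
  n0 <- cw0[ks];       m0 <- cm0[ks]
  n1 <- n - n0;        m1 <- m - m0
  valid <- n0 > 0 & n1 > 0 & m0 > 0 & m1 > 0
  crit <- rep(Inf, length(ks))
  mu0 <- m0[valid] / n0[valid]
  mu1 <- m1[valid] / n1[valid]
  crit[valid] <- -(m0[valid] * log(mu0) + m1[valid] * log(mu1))
  k_best <- ks[which.min(crit)]          # which.min takes the first minimum
  k_best / n_bins
}

#' Apply correction factor and bounds to a raw threshold
#'
#' Effective threshold = `clamp(raw * correction, lower, upper)`; the mask
#' is `image > effective`. With `threshold_smoothing_scale > 0` the image
#' is Gaussian-smoothed at that scale before comparison (the protocol
#' setting is 0: no smoothing).
#'
#' @param image Single-channel image in \[0, 1\].
#' @param raw_threshold Raw automatic threshold in \[0, 1\].
#' @param params A [segmentation_params()] object.
#' @return List with `mask` (logical matrix) and `threshold` (effective
#'   scalar).
#' @export
apply_threshold <- function(image, raw_threshold, params = segmentation_params()) {
  stopifnot_scalar(raw_threshold, "raw_threshold", 0, 1)
  px <- as_pixels(image)
  eff <- min(max(raw_threshold * params$threshold_correction,
                 params$threshold_lower_bound), params$threshold_upper_bound)
  if (params$threshold_smoothing_scale > 0)
    px <- gaussian_smooth(px, params$threshold_smoothing_scale)
  list(mask = px > eff, threshold = eff)
}

#' Reconstruct solid objects from an edge-ring mask
#'
#' The thresholded Sobel mask outlines spheroids as bright rings. A
#' morphological closing (disc structuring element, radius
#' `params$closing_radius`) seals small gaps in the rings, then hole
#' filling converts closed rings into solid objects. Because the gradient
#' band straddles the true object boundary roughly symmetrically, filling
#' to the band's outer edge inflates objects by half the band thickness;
#' when `params$rim_correction` (default) the filled mask is eroded by
#' half the estimated band thickness to recover the rim centerline. Masks
#' that are already solid (band covering most of the filled area) are
#' returned unchanged apart from hole filling.
#'
#' @param mask Logical or 0/1 matrix.
#' @param params A [segmentation_params()] object.
#' @return Logical matrix of solid foreground.
#' @export
solidify <- function(mask, params = segmentation_params()) {
  m0 <- (as_pixels(mask * 1) > 0) * 1
  if (!any(m0 > 0)) return(m0 > 0)
  m <- m0
  r <- params$closing_radius
  if (r >= 1) {
    brush <- EBImage::makeBrush(2L * as.integer(round(r)) + 1L, shape = "disc")
    # pad so closing cannot clip objects at the frame
    p <- as.integer(round(r)) + 1L
    nr <- nrow(m); nc <- ncol(m)
    mp <- matrix(0, nr + 2L * p, nc + 2L * p)
    mp[(p + 1L):(p + nr), (p + 1L):(p + nc)] <- m
    mp <- EBImage::closing(mp, brush)
    m <- mp[(p + 1L):(p + nr), (p + 1L):(p + nc)]
  }
  if (params$fill_holes) m <- EBImage::fillHull(m)
  filled <- m > 0
  if (params$rim_correction) {
    a_band <- sum(m0)
    a_fill <- sum(filled)
    if (a_fill > 0 && a_band / a_fill < 0.5) {   # ring-like input only
      # band thickness ~ band area / outline length
      per <- sum(boundary_pixels(filled))
      if (per > 0) {
        k <- floor(a_band / per / 2)
        if (k >= 1) {
          br <- EBImage::makeBrush(2L * as.integer(k) + 1L, shape = "disc")
          filled <- EBImage::erode(filled * 1, br) > 0
        }
      }
    }
  }
  filled
}

# Logical matrix marking foreground pixels with a 4-neighbour background.
boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
  mask & !interior
}

# Seed detection for declumping: local minima of a blend of the smoothed
# intensity (dark spheroid interiors) and the negated normalized distance
# transform (shape cue for flat interiors), greedily thinned to the minimum
# separation. Returns an integer seed label matrix.
declump_seeds <- function(mask, intensity, params) {
  sm <- gaussian_smooth(intensity, params$declump_sigma)
  dm <- EBImage::distmap(mask * 1)
  dmx <- max(dm)
  wI <- params$declump_intensity_weight
  surf <- wI * sm + (1 - wI) * (1 - dm / max(dmx, 1e-12))
  surf[!mask] <- Inf
  # a credible spheroid center in a clump lies at distance-transform depth
  # ~ its radius >= min_diameter / 2; thin projections (spikes) are far
  # shallower and must not seed a split
  deep_enough <- dm >= params$declump_min_depth
  nr <- nrow(surf); nc <- ncol(surf)
  # 3x3 non-strict local minima via shifted comparisons
  pad <- matrix(Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- surf
  is_min <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
    is_min <- is_min & (surf <= nb)
  }
  is_min <- is_min & mask & is.finite(surf) & deep_enough
  cand <- which(is_min, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(NULL)
  ord <- order(surf[is_min])
  cand <- cand[ord, , drop = FALSE]
  sep2 <- params$declump_min_separation^2
  keep <- matrix(0, 0L, 2L)
  while (nrow(cand) > 0L) {
    p0 <- cand[1L, ]
    keep <- rbind(keep, p0)
    d2 <- (cand[, 1L] - p0[1L])^2 + (cand[, 2L] - p0[2L])^2
    cand <- cand[d2 > sep2, , drop = FALSE]
  }
  seeds <- matrix(0L, nr, nc)
  seeds[keep] <- seq_len(nrow(keep))
  seeds
}

#' Split clumped objects
#'
#' Seeds are intensity-guided local minima within the mask (spheroid
#' interiors are dark in brightfield), regularized by the distance
#' transform and thinned to a minimum separation of
#' `params$declump_min_separation`. Dividing lines follow the shape of the
#' mask: pixels are assigned to the geodesically nearest seed within the
#' foreground, so two equal touching discs split along the perpendicular
#' bisector of their centers. Connected regions that received no seed keep
#' one seed at their distance-transform maximum.
#'
#' @param mask Solidified logical mask.
#' @param intensity Smoothed grayscale image (pre-Sobel).
#' @param params A [segmentation_params()] object.
#' @return A `label_map`: list with `labels` (integer matrix, 0 background)
#'   and `n_objects`.
#' @export
declump <- function(mask, intensity, params = segmentation_params()) {
  mask <- as_pixels(mask * 1) > 0
  if (!any(mask)) return(new_label_map(matrix(0L, nrow(mask), ncol(mask))))
  seeds <- declump_seeds(mask, as_pixels(intensity), params)
  comp <- label8(mask)
  if (is.null(seeds)) seeds <- matrix(0L, nrow(mask), ncol(mask))
  # guarantee one seed per connected component
  seeded <- unique(comp[seeds > 0L])
  for (id in setdiff(seq_len(max(comp)), seeded)) {
    sub <- comp == id
    dm <- EBImage::distmap(sub * 1)
    pk <- which.max(dm)
    seeds[pk] <- max(seeds) + 1L
  }
  lab <- EBImage::propagate(matrix(0, nrow(mask), ncol(mask)), seeds,
                            mask = mask, lambda = 1e-4)
  lab <- relabel_contiguous(matrix(as.integer(round(lab)), nrow(lab), ncol(lab)))
  new_label_map(lab)
}

new_label_map <- function(labels) {
  structure(list(labels = labels, n_objects = max(labels, 0L)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("label_map: %d x %d px, %d object(s)\n",
              nrow(x$labels), ncol(x$labels), x$n_objects))
  invisible(x)
}

#' Filter objects by size and border contact
#'
#' Removes objects whose equivalent-circle diameter `2 * sqrt(area / pi)`
#' lies outside `[min_diameter, max_diameter]` and, when
#' `discard_border_objects`, objects with any pixel on the image boundary.
#' Survivors are relabeled contiguously from 1.
#'
#' @param label_map A `label_map` from [declump()].
#' @param params A [segmentation_params()] object.
#' @return Filtered `label_map`.
#' @export
filter_objects <- function(label_map, params = segmentation_params()) {
  lab <- label_map$labels
  n <- label_map$n_objects
  if (n == 0L) return(label_map)
  areas <- tabulate(lab[lab > 0L], nbins = n)
  eqd <- 2 * sqrt(areas / pi)
  drop <- eqd < params$min_diameter | eqd > params$max_diameter
  if (params$discard_border_objects) {
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
    drop[border[border > 0L]] <- TRUE
  }
  if (any(drop)) {
    out <- lab
    out[out %in% which(drop)] <- 0L
    return(new_label_map(relabel_contiguous(out)))
  }
  label_map
}

#' Segment a preprocessed image
#'
#' Full segmentation chain on the outputs of [preprocess_image()]:
#' threshold the edge image by minimum cross-entropy (with correction and
#' bounds), solidify edge rings, declump, and filter by diameter and
#' border contact. A constant edge image (nothing in the frame) yields an
#' empty label map.
#'
#' @param pre List from [preprocess_image()] (`smoothed` and `edges` used).
#' @param params A [segmentation_params()] object.
#' @return List with `label_map`, `raw_threshold`, `threshold`.
#' @export
segment_image <- function(pre, params = segmentation_params()) {
  raw <- tryCatch(min_cross_entropy_threshold(pre$edges),
                  degenerate_image_error = function(e) NA_real_)
  if (is.na(raw)) {
    empty <- new_label_map(matrix(0L, nrow(pre$edges), ncol(pre$edges)))
    return(list(label_map = empty, raw_threshold = NA_real_, threshold = NA_real_))
  }
  th <- apply_threshold(pre$edges, raw, params)
  solid <- solidify(th$mask, params)
  lm <- declump(solid, pre$smoothed, params)
  lm <- filter_objects(lm, params)
  list(label_map = lm, raw_threshold = raw, threshold = th$threshold)
}
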