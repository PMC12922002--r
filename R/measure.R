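# Per-object shape descriptors. Coordinates in all outputs are 0-based
# pixel centers, row-major, origin at the top-left corner.

#' Form factor (circularity)
#'
#' `4 * pi * area / perimeter^2`: equals 1 for a perfect circle and is
#' below 1 for any other shape (the isoperimetric inequality); lower values
#' indicate a more irregular outline.
#'
#' @param area Object area (px^2).
#' @param perimeter Object perimeter (px), > 0.
#' @return Dimensionless form factor.
#' @examples
#' form_factor(pi * 300^2, 2 * pi * 300)  # circle -> 1
#' form_factor(1, 4)                      # unit square -> pi/4
#' @export
form_factor <- function(area, perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Solidity
#'
#' Ratio of object area to convex hull area, in (0, 1\]: near 1 for compact
#' convex objects, lower for spiky or indented outlines.
#'
#' @param area Object area (px^2), > 0.
#' @param hull_area Convex hull area (px^2), >= `area`.
#' @return Dimensionless solidity.
#' @export
solidity <- function(area, hull_area) {
  if (any(area <= 0)) stop("area must be positive")
  if (any(hull_area < area))
    stop("convex hull area smaller than object area: hull computation bug")
  area / hull_area
}

#' Mesenchymal morphology score
#'
#' `1 / (form_factor * solidity)`. A perfectly circular, convex object
#' scores 1; spike formation and loss of compactness drive both factors
#' down and the score up, so higher scores indicate a more
#' mesenchymal-looking morphology.
#'
#' @param form_factor Form factor, > 0.
#' @param solidity Solidity, > 0.
#' @return Dimensionless score >= ~1.
#' @export
mesenchymal_score <- function(form_factor, solidity) {
  if (any(form_factor <= 0) || any(solidity <= 0))
    stop("form factor and solidity must be positive")
  1 / (form_factor * solidity)
}

# Perimeter of one object from its 0-based 8-connected boundary contour.
# "chain_smooth": circular moving-average smoothing (window 5) of the
# contour polygon removes rasterization staircase jitter; + pi corrects the
# half-pixel inward offset of pixel-center contours (offsetting a simple
# closed curve outward by d adds 2*pi*d). "crofton": 4-direction Crofton
# estimator from directed crossing counts.
perimeter_from_contour <- function(contour, method = "chain_smooth", window = 5L) {
  n <- nrow(contour)
  if (n == 1L) return(4)   # single pixel, unit-square boundary
  if (n == 2L) return(6)
  if (method == "chain_smooth" && n > window) {
    h <- (window - 1L) %/% 2L
    sm <- contour * 0
    for (k in -h:h) {
      idx <- ((seq_len(n) - 1L + k) %% n) + 1L
      sm <- sm + contour[idx, , drop = FALSE]
    }
    sm <- sm / window
    return(polygon_perimeter(sm) + pi)
  }
  polygon_perimeter(contour) + pi
}

crofton_perimeter <- function(obj_mask) {
  m <- obj_mask * 1
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L); p[2:(nr + 1L), 2:(nc + 1L)] <- m
  crossings <- function(a, b) sum(abs(a - b))
  n_h <- crossings(p[, -1L], p[, -(nc + 2L)])
  n_v <- crossings(p[-1L, ], p[-(nr + 2L), ])
  n_d1 <- crossings(p[-1L, -1L], p[-(nr + 2L), -(nc + 2L)])
  n_d2 <- crossings(p[-1L, -(nc + 2L)], p[-(nr + 2L), -1L])
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# Convex hull area of an object given boundary pixel centers (lattice
# points). Reported area is the lattice-point count of the hull polygon
# (Pick's theorem: shoelace + boundary/2 + 1), i.e. the pixel-rasterized
# hull area, which is guaranteed >= the object's pixel count.
hull_area_from_contour <- function(contour) {
  pts <- unique(contour)
  if (nrow(pts) == 1L) return(1)
  if (nrow(pts) == 2L)
    return(lattice_boundary_points(pts[c(1L, 2L), , drop = FALSE]) / 2 + 1)
  hull <- grDevices::chull(pts[, 1L], pts[, 2L])
  v <- pts[hull, , drop = FALSE]
  if (nrow(v) < 3L) {
    ends <- pts[c(which.min(pts[, 1L] + pts[, 2L]), which.max(pts[, 1L] + pts[, 2L])), ]
    return(lattice_boundary_points(ends) / 2 + 1)
  }
  polygon_area(v) + lattice_boundary_points(v) / 2 + 1
}

#' Measure all objects in a label map
#'
#' Computes, per object: area (pixel count), perimeter (smoothed
#' boundary-polygon estimator by default, Crofton optional), convex hull
#' area (lattice-point count of the hull of boundary pixel centers),
#' solidity, form factor, ellipse-equivalent major axis length from second
#' central moments, centroid (0-based), and the mesenchymal morphology
#' score. Objects smaller than 5 px are skipped with a warning (moments and
#' hulls degenerate).
#'
#' @param label_map A `label_map`.
#' @param params A [segmentation_params()] (perimeter method is read from
#'   it).
#' @return A data.frame with one row per measured object: `object_id`,
#'   `area`, `perimeter`, `convex_hull_area`, `solidity`, `form_factor`,
#'   `major_axis_length`, `centroid_row`, `centroid_col`,
#'   `mesenchymal_score`.
#' @export
measure_objects <- function(label_map, params = segmentation_params()) {
  lab <- label_map$labels
  n <- label_map$n_objects
  empty <- data.frame(object_id = integer(), area = double(),
                      perimeter = double(), convex_hull_area = double(),
                      solidity = double(), form_factor = double(),
                      major_axis_length = double(), centroid_row = double(),
                      centroid_col = double(), mesenchymal_score = double())
  if (n == 0L) return(empty)
  contours <- EBImage::ocontour(lab)   # 0-based (row, col) per object
  fg <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[lab > 0L]
  rows_by_id <- split(seq_len(nrow(fg)), ids)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    px <- fg[rows_by_id[[as.character(i)]], , drop = FALSE]
    a <- nrow(px)
    if (a < 5L) {
      warning("object ", i, " smaller than 5 px: skipped")
      next
    }
    if (params$perimeter_method == "crofton") {
      sub <- lab[min(px[, 1L]):max(px[, 1L]), min(px[, 2L]):max(px[, 2L]), drop = FALSE]
      per <- crofton_perimeter(sub == i)
    } else {
      per <- perimeter_from_contour(contours[[i]])
    }
    hull_a <- hull_area_from_contour(contours[[i]])
    hull_a <- max(hull_a, a)   # guard against sub-pixel discretization slack
    r0 <- px[, 1L] - 1; c0 <- px[, 2L] - 1
    mr <- mean(r0); mc <- mean(c0)
    mu20 <- mean((r0 - mr)^2) + 1 / 12
    mu02 <- mean((c0 - mc)^2) + 1 / 12
    mu11 <- mean((r0 - mr) * (c0 - mc))
    common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
    lam1 <- (mu20 + mu02) / 2 + common
    ff <- form_factor(a, per)
    sol <- solidity(a, hull_a)
    out[[i]] <- data.frame(object_id = i, area = a, perimeter = per,
                           convex_hull_area = hull_a, solidity = sol,
                           form_factor = ff,
                           major_axis_length = 4 * sqrt(lam1),
                           centroid_row = mr, centroid_col = mc,
                           mesenchymal_score = mesenchymal_score(ff, sol))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Measure a single object
#'
#' @param label_map A `label_map`.
#' @param object_id Positive object id present in the map.
#' @param params A [segmentation_params()].
#' @return One-row data.frame as in [measure_objects()].
#' @export
measure_object <- function(label_map, object_id, params = segmentation_params()) {
  if (!object_id %in% label_map$labels)
    stop("object id ", object_id, " not present in label map")
  m <- measure_objects(label_map, params)
  m[m$object_id == object_id, , drop = FALSE]
}
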