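# Synthetic brightfield spheroid images with exact geometric ground truth.
# Discs emulate the compact epithelial morphology; star polygons (alternating
# outer/inner radii) emulate mesenchymal spike formation while keeping
# closed-form area, perimeter and convex hull. Truth values come from the
# continuous geometry, never from the rasterized mask, so estimator bias is
# measurable independently of rasterization error.

#' Shape specification for a synthetic spheroid
#'
#' @param kind `"disc"` or `"star"`.
#' @param outer_radius Outer radius in px (disc radius for `"disc"`).
#' @param inner_radius Star inner (valley) radius, 0 < inner < outer.
#' @param n_spikes Number of star spikes (>= 3).
#' @param center `(row, col)` center in 0-based pixel coordinates.
#' @param rotation Rotation in radians.
#' @return A list of class `shape_spec`.
#' @export
shape_spec <- function(kind = c("disc", "star"), outer_radius,
                       inner_radius = NULL, n_spikes = NULL,
                       center, rotation = 0) {
  kind <- match.arg(kind)
  stopifnot_scalar(outer_radius, "outer_radius", lo = 1)
  if (kind == "star") {
    stopifnot_scalar(inner_radius, "inner_radius", lo = 1e-9,
                     hi = outer_radius - 1e-9)
    if (is.null(n_spikes) || n_spikes < 3L) stop("star needs n_spikes >= 3")
  }
  structure(list(kind = kind, outer_radius = outer_radius,
                 inner_radius = inner_radius, n_spikes = n_spikes,
                 center = center, rotation = rotation),
            class = "shape_spec")
}

# Vertices of the star polygon (2k points alternating outer/inner radius),
# in (row, col) coordinates.
star_vertices <- function(spec) {
  k <- spec$n_spikes
  ang <- spec$rotation + (0:(2 * k - 1)) * pi / k
  rad <- rep(c(spec$outer_radius, spec$inner_radius), k)
  cbind(spec$center[1L] + rad * sin(ang), spec$center[2L] + rad * cos(ang))
}

# Closed-form geometry of the continuous shape.
shape_truth_values <- function(spec) {
  if (spec$kind == "disc") {
    r <- spec$outer_radius
    list(area = pi * r^2, perimeter = 2 * pi * r, hull_area = pi * r^2,
         form_factor = 1, solidity = 1, ms = 1)
  } else {
    v <- star_vertices(spec)
    a <- polygon_area(v)
    p <- polygon_perimeter(v)
    # hull of all vertices: the outer regular k-gon for spiky stars
    # (inner_radius <= outer * cos(pi/k)); for shallower stars the inner
    # vertices protrude and join the hull
    hv <- grDevices::chull(v[, 1L], v[, 2L])
    hull <- polygon_area(v[hv, , drop = FALSE])
    ff <- form_factor(a, p)
    sol <- solidity(a, hull)
    list(area = a, perimeter = p, hull_area = hull,
         form_factor = ff, solidity = sol, ms = mesenchymal_score(ff, sol))
  }
}

# Even-odd point-in-polygon test, vectorized over points.
points_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vr[i] > pr) != (vr[j] > pr)
    if (any(crosses)) {
      cint <- (vc[j] - vc[i]) * (pr - vr[i]) / (vr[j] - vr[i]) + vc[i]
      inside <- xor(inside, crosses & (pc < cint))
    }
    j <- i
  }
  inside
}

#' Rasterize a shape and compute its exact ground truth
#'
#' The mask uses a pixel-center inclusion test against the continuous
#' shape; the ground-truth descriptors are closed forms of the continuous
#' geometry (disc: `pi r^2`, `2 pi r`, form factor = solidity = score = 1;
#' star: shoelace area / edge-length perimeter of the 2k-vertex polygon,
#' hull = outer regular k-gon).
#'
#' @param spec A [shape_spec()].
#' @param image_size `(H, W)` in px.
#' @param border_safe Error if the shape's outer radius crosses the frame.
#' @return A list of class `shape_truth`: `mask` (logical H x W), `spec`,
#'   and exact `area`, `perimeter`, `hull_area`, `form_factor`, `solidity`,
#'   `ms`.
#' @export
make_shape <- function(spec, image_size, border_safe = TRUE) {
  H <- image_size[1L]; W <- image_size[2L]
  cr <- spec$center[1L]; cc <- spec$center[2L]
  if (border_safe &&
      (cr - spec$outer_radius < 0 || cr + spec$outer_radius > H - 1 ||
       cc - spec$outer_radius < 0 || cc + spec$outer_radius > W - 1))
    stop("shape exceeds the image frame (border_safe = TRUE)")
  rows <- matrix(0:(H - 1), H, W)
  cols <- matrix(0:(W - 1), H, W, byrow = TRUE)
  if (spec$kind == "disc") {
    mask <- (rows - cr)^2 + (cols - cc)^2 <= spec$outer_radius^2
  } else {
    v <- star_vertices(spec)
    # restrict the polygon test to the bounding box for speed
    bb <- rows >= cr - spec$outer_radius & rows <= cr + spec$outer_radius &
          cols >= cc - spec$outer_radius & cols <= cc + spec$outer_radius
    mask <- matrix(FALSE, H, W)
    idx <- which(bb)
    mask[idx] <- points_in_polygon(rows[idx], cols[idx], v[, 1L], v[, 2L])
  }
  tv <- shape_truth_values(spec)
  structure(list(mask = mask, spec = spec, area = tv$area,
                 perimeter = tv$perimeter, hull_area = tv$hull_area,
                 form_factor = tv$form_factor, solidity = tv$solidity,
                 ms = tv$ms),
            class = "shape_truth")
}

#' Rendering specification for synthetic brightfield frames
#'
#' @param image_size `(H, W)` px.
#' @param background_level Background intensity (bright), default 0.85.
#' @param object_level Object intensity (dark), must be below background;
#'   default 0.25.
#' @param gradient_amplitude Peak-to-peak linear illumination gradient
#'   across columns, default 0.08.
#' @param noise_sd Additive Gaussian noise SD, default 0.02.
#' @param blur_sigma Gaussian blur of the object mask (optical softness of
#'   the rim), default 3 px.
#' @param seed RNG seed for the noise.
#' @return A list of class `render_spec`.
#' @export
render_spec <- function(image_size = c(600, 600), background_level = 0.85,
                        object_level = 0.25, gradient_amplitude = 0.08,
                        noise_sd = 0.02, blur_sigma = 3, seed = 1L) {
  if (object_level >= background_level)
    stop("object_level must be below background_level (dark object on bright field)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(image_size = image_size,
                 background_level = background_level,
                 object_level = object_level,
                 gradient_amplitude = gradient_amplitude,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 seed = as.integer(seed)),
            class = "render_spec")
}

#' Render a synthetic brightfield image
#'
#' `image = background + gradient - (background - object) * soft_mask +
#' noise`, clipped to \[0, 1\]; the soft mask is the shape mask blurred by
#' `blur_sigma`. Deterministic for a fixed seed.
#'
#' @param truth A `shape_truth` (or bare logical mask).
#' @param spec A [render_spec()]; its `image_size` must match the mask.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
render_brightfield <- function(truth, spec = render_spec()) {
  mask <- if (inherits(truth, "shape_truth")) truth$mask else truth
  H <- nrow(mask); W <- ncol(mask)
  soft <- mask * 1
  if (spec$blur_sigma > 0) soft <- conv2_reflect(soft, gaussian_kernel(spec$blur_sigma))
  grad <- matrix(seq(-0.5, 0.5, length.out = W), H, W, byrow = TRUE) *
    spec$gradient_amplitude
  img <- spec$background_level + grad -
    (spec$background_level - spec$object_level) * soft
  if (spec$noise_sd > 0)
    img <- img + with_seed(spec$seed,
                           function() matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W))
  pmin(pmax(img, 0), 1)
}

#' Default longitudinal treatment schedules
#'
#' Maps each treatment condition and day to shape parameters emulating the
#' study design: a BSA control staying compact (disc) and three oleic-acid
#' doses whose spikes grow at increasing rates. The spike depth is
#' parameterized by the star inner/outer radius ratio, which decreases
#' linearly in day from a dose-specific start.
#'
#' @param conditions Condition names; the first is the compact control.
#' @return Named list of functions `f(day)` returning a parameter list
#'   (`kind`, `outer_radius`, `inner_ratio`, `n_spikes`).
#' @export
default_schedules <- function(conditions = c("BSA", "OA50", "OA75", "OA150")) {
  # spike-growth presets keyed by condition name: inner/outer ratio start
  # and linear decline per day (steeper = faster EMT-like progression)
  presets <- list(OA50 = c(start = 0.90, rate = 0.0056),
                  OA75 = c(start = 0.87, rate = 0.0167),
                  OA150 = c(start = 0.84, rate = 0.0300))
  star_schedule <- function(s0, r0) {
    force(s0); force(r0)
    function(day) list(kind = "star", outer_radius = 230,
                       inner_ratio = max(0.35, s0 - r0 * (day - 1)),
                       n_spikes = 8L)
  }
  out <- list()
  out[[conditions[1L]]] <- function(day)
    list(kind = "disc", outer_radius = 160, inner_ratio = NA, n_spikes = NA)
  treated <- conditions[-1L]
  for (j in seq_along(treated)) {
    nm <- treated[j]
    p <- presets[[nm]] %||%
      c(start = 0.90 - 0.03 * (j - 1), rate = 0.0056 + 0.012 * (j - 1))
    out[[nm]] <- star_schedule(p[["start"]], p[["rate"]])
  }
  out
}

#' Generate a synthetic longitudinal imaging folder
#'
#' Writes one 16-bit grayscale TIFF per spheroid per day, named
#' `{experiment}_{condition}-s{nn}-d{dd}_TRANS.tiff` (parseable by the
#' default filename pattern), together with a sidecar `metadata.csv`
#' (`spheroid_id,day,condition`) and a `groundtruth.csv` holding the exact
#' continuous-geometry descriptors of every image. Per-spheroid jitter of
#' shape parameters is drawn from per-image RNG streams fanned out from the
#' global seed by a stable hash of (spheroid id, day), so outputs are fully
#' reproducible.
#'
#' @param outdir Output directory (created).
#' @param schedules Named list of condition schedules, see
#'   [default_schedules()].
#' @param days Integer imaging days.
#' @param n_spheroids Spheroids per condition.
#' @param seed Global seed.
#' @param image_size `(H, W)` of each frame.
#' @param experiment Experiment tag used in filenames.
#' @param noise_sd,blur_sigma,gradient_amplitude Render settings.
#' @return Data.frame (invisible) with one row per image: `file`,
#'   `spheroid_id`, `condition`, `day` and exact `ms`, `area`, `form_factor`,
#'   `solidity`.
#' @export
generate_timecourse <- function(outdir,
                                schedules = default_schedules(),
                                days = c(1L, 3L, 5L, 7L, 10L),
                                n_spheroids = 15L,
                                seed = 1L,
                                image_size = c(600, 600),
                                experiment = "SIM",
                                noise_sd = 0.02,
                                blur_sigma = 3,
                                gradient_amplitude = 0.08) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  ids_seen <- character()
  for (cond in names(schedules)) {
    for (s in seq_len(n_spheroids)) {
      for (d in days) {
        sph <- sprintf("%s-s%02d-d%02d", cond, s, d)
        if (sph %in% ids_seen) stop("duplicate spheroid id: ", sph)
        ids_seen <- c(ids_seen, sph)
        pars <- schedules[[cond]](d)
        stream <- (seed * 7907L + stable_hash(sph)) %% 2147483647L
        jit <- with_seed(stream, function()
          list(r = stats::runif(1, -0.04, 0.04),
               q = stats::runif(1, -0.015, 0.015),
               rot = stats::runif(1, 0, 2 * pi),
               dc = stats::runif(2, -8, 8)))
        ctr <- c((image_size[1L] - 1) / 2, (image_size[2L] - 1) / 2) + jit$dc
        outer <- pars$outer_radius * (1 + jit$r)
        spec <- if (pars$kind == "disc")
          shape_spec("disc", outer, center = ctr)
        else
          shape_spec("star", outer,
                     inner_radius = outer * min(0.99, max(0.05, pars$inner_ratio + jit$q)),
                     n_spikes = pars$n_spikes, center = ctr,
                     rotation = jit$rot)
        truth <- make_shape(spec, image_size)
        rs <- render_spec(image_size = image_size, noise_sd = noise_sd,
                          blur_sigma = blur_sigma,
                          gradient_amplitude = gradient_amplitude,
                          seed = stream)
        img <- render_brightfield(truth, rs)
        fn <- sprintf("%s_%s_TRANS.tiff", experiment, sph)
        write_tiff(img, file.path(outdir, fn), bits = 16L)
        rows[[length(rows) + 1L]] <- data.frame(
          file = fn, spheroid_id = sph, condition = cond, day = d,
          ms = truth$ms, area = truth$area,
          form_factor = truth$form_factor, solidity = truth$solidity,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest[, c("spheroid_id", "day", "condition")],
                   file.path(outdir, "metadata.csv"), row.names = FALSE)
  utils::write.csv(manifest, file.path(outdir, "groundtruth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
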