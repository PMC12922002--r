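# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Rasterized disc mask (logical) with 0-based center coordinates.
disc_mask <- function(radius, size, center = (size - 1) / 2 * c(1, 1)) {
  make_shape(shape_spec("disc", radius, center = center), c(size, size),
             border_safe = FALSE)$mask
}

# Wrap a single mask as a one-object label map.
mask_label_map <- function(mask) {
  structure(list(labels = matrix(as.integer(mask), nrow(mask)),
                 n_objects = 1L),
            class = "label_map")
}

# Measure the single object of a mask.
measure_mask <- function(mask, params = segmentation_params()) {
  measure_objects(mask_label_map(mask), params)
}

# Write a [0,1] matrix as a temporary TIFF and return the path.
tmp_tiff <- function(pixels, bits = 16L, name = NULL) {
  f <- if (is.null(name)) tempfile(fileext = ".tiff")
       else file.path(tempdir(), name)
  tiff::writeTIFF(pixels, f, bits.per.sample = bits)
  f
}

# Independent brute-force evaluation of the Li cross-entropy objective on a
# 256-bin histogram: loops over every interior bin edge and computes the
# criterion straight from its definition.
brute_force_li <- function(px, n_bins = 256L) {
  idx <- pmin(pmax(floor(px * n_bins), 0), n_bins - 1L)
  h <- tabulate(idx + 1L, nbins = n_bins)
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  best_k <- NA_integer_; best <- Inf
  for (k in seq_len(n_bins - 1L)) {
    lo <- seq_len(k); hi <- (k + 1L):n_bins
    n0 <- sum(h[lo]); n1 <- sum(h[hi])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(h[lo] * centers[lo]) / n0
    mu1 <- sum(h[hi] * centers[hi]) / n1
    if (mu0 <= 0 || mu1 <= 0) next
    crit <- -(sum(h[lo] * centers[lo]) * log(mu0) +
              sum(h[hi] * centers[hi]) * log(mu1))
    if (crit < best - 1e-12) { best <- crit; best_k <- k }
  }
  best_k / n_bins
}

# Shoelace area / perimeter of a closed polygon, written independently of
# the package internals.
shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
edge_length <- function(v) {
  d <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE]) - v
  sum(sqrt(rowSums(d^2)))
}
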