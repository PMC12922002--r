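# Preprocessing chain: grayscale -> sharpen -> Gaussian smooth -> Sobel.
# All operations map [0,1] images to [0,1] images and use reflective
# boundary handling so the image frame never generates spurious edges.

#' Convert an image to grayscale
#'
#' RGB inputs are reduced by a convex channel weighting; the default equal
#' weights (1/3, 1/3, 1/3) equalize the relative contribution of the
#' channels rather than applying a perceptual luma weighting. Grayscale
#' inputs pass through unchanged.
#'
#' @param image A `spheroid_image`, matrix, or H x W x 3 array in \[0, 1\].
#' @param weights Length-3 nonnegative weights summing to 1.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
to_grayscale <- function(image, weights = c(1, 1, 1) / 3) {
  px <- as_pixels(image)
  if (length(dim(px)) == 2L) return(px)
  if (dim(px)[3L] != 3L) stop("expected 1 or 3 channels, got ", dim(px)[3L])
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be 3 nonnegative values summing to 1")
  px[, , 1L] * weights[1L] + px[, , 2L] * weights[2L] + px[, , 3L] * weights[3L]
}

#' Sharpen an image by unsharp masking
#'
#' Computes `original + amount * (original - blur(original, sigma))`,
#' emphasizing object contours. The result is clipped back to \[0, 1\] by
#' default. Constant images are fixed points of the operator.
#'
#' @param image Single-channel image in \[0, 1\].
#' @param amount Strength of the high-frequency boost, >= 0. 0 is identity.
#' @param sigma Standard deviation (pixels) of the internal Gaussian blur.
#' @param clip Clip the result to \[0, 1\] (default TRUE).
#' @return Sharpened matrix.
#' @export
sharpen <- function(image, amount = 1, sigma = 1, clip = TRUE) {
  px <- as_pixels(image)
  if (length(dim(px)) != 2L) stop("sharpen expects a single-channel image")
  stopifnot_scalar(amount, "amount", lo = 0)
  if (amount == 0) return(px)
  blur <- conv2_reflect(px, gaussian_kernel(sigma))
  out <- px + amount * (px - blur)
  if (clip) out <- pmin(pmax(out, 0), 1)
  out
}

#' Gaussian smoothing
#'
#' 2-D Gaussian convolution with reflective boundaries. A sigma of 1.5--2 px
#' suppresses high-frequency noise ahead of edge detection while leaving
#' spheroid-scale boundaries intact; the package default is 2.
#'
#' @param image Single-channel image.
#' @param sigma Gaussian standard deviation in pixels, 0 < sigma <= 50.
#' @return Smoothed matrix.
#' @export
gaussian_smooth <- function(image, sigma = 2) {
  px <- as_pixels(image)
  if (length(dim(px)) != 2L) stop("gaussian_smooth expects a single-channel image")
  stopifnot_scalar(sigma, "sigma", lo = 1e-9, hi = 50)
  conv2_reflect(px, gaussian_kernel(sigma))
}

#' Sobel edge magnitude
#'
#' Gradient magnitude `sqrt(Gx^2 + Gy^2)` from the 3 x 3 Sobel operator
#' pair, rescaled to \[0, 1\] by its per-image maximum (an all-flat image
#' maps to all zeros). The output is the edge mask the segmentation stage
#' thresholds: bright object rims on a dark background.
#'
#' @param image Single-channel image.
#' @param normalize Rescale by the per-image maximum (default TRUE); set
#'   FALSE to obtain the raw gradient magnitude.
#' @return Edge-magnitude matrix, in \[0, 1\] when normalized.
#' @export
sobel_edges <- function(image, normalize = TRUE) {
  px <- as_pixels(image)
  if (length(dim(px)) != 2L) stop("sobel_edges expects a single-channel image")
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv2_reflect(px, kx)
  gy <- conv2_reflect(px, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  if (normalize) {
    mx <- max(mag)
    # magnitudes at floating-point roundoff level are flat images, not edges
    if (mx > 1e-9) mag <- mag / mx else mag[] <- 0
  }
  mag
}

#' Preprocessing parameter set
#'
#' @param gray_weights RGB-to-gray channel weights (sum 1).
#' @param sharpen_amount Unsharp-mask strength (>= 0).
#' @param sharpen_sigma Unsharp-mask internal blur sigma (px).
#' @param gaussian_sigma Smoothing sigma (px); 1.5--2 is the working range,
#'   default 2.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(gray_weights = c(1, 1, 1) / 3,
                              sharpen_amount = 1,
                              sharpen_sigma = 1,
                              gaussian_sigma = 2) {
  stopifnot_scalar(sharpen_amount, "sharpen_amount", lo = 0)
  stopifnot_scalar(gaussian_sigma, "gaussian_sigma", lo = 1e-9, hi = 50)
  structure(list(gray_weights = gray_weights,
                 sharpen_amount = sharpen_amount,
                 sharpen_sigma = sharpen_sigma,
                 gaussian_sigma = gaussian_sigma),
            class = "preprocess_params")
}

#' Run the full preprocessing chain
#'
#' grayscale -> unsharp sharpen -> Gaussian smooth -> Sobel edges.
#'
#' @param image Input image (RGB or grayscale, \[0, 1\]).
#' @param params A [preprocess_params()] object.
#' @return A list with matrices `gray`, `sharpened`, `smoothed`, `edges`.
#' @export
preprocess_image <- function(image, params = preprocess_params()) {
  gray <- to_grayscale(image, params$gray_weights)
  shp <- sharpen(gray, params$sharpen_amount, params$sharpen_sigma)
  sm <- gaussian_smooth(shp, params$gaussian_sigma)
  list(gray = gray, sharpened = shp, smoothed = sm, edges = sobel_edges(sm))
}
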