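#' Load a brightfield TIFF image
#'
#' Reads a single-plane grayscale or RGB TIFF and returns intensities
#' normalized to \[0, 1\] by the source bit-depth maximum (255 or 65535),
#' the scale on which all downstream thresholds are defined. Only the first
#' page of a multi-page TIFF is read (one focal plane per file is assumed),
#' with a warning.
#'
#' @param path Path to a `.tif`/`.tiff` file.
#' @return An object of class `spheroid_image`: a list with `pixels`
#'   (H x W numeric matrix, or H x W x 3 array for RGB sources, values in
#'   \[0, 1\]), `source_path`, `original_bit_depth` and `is_rgb_source`.
#' @examples
#' f <- tempfile(fileext = ".tiff")
#' tiff::writeTIFF(matrix(runif(64), 8, 8), f, bits.per.sample = 16)
#' img <- load_tiff(f)
#' range(img$pixels)
#' @export
load_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("not a TIFF file (extension): ", path)
  raw <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                  error = function(e) stop("cannot read TIFF '", path, "': ",
                                           conditionMessage(e)))
  if (length(raw) > 1L)
    warning("multi-page TIFF '", path, "': reading first page only")
  px <- raw[[1L]]
  bits <- as.integer(attr(px, "bits.per.sample") %||% 8L)[1L]
  if (!bits %in% c(8L, 16L))
    stop("unsupported bits per sample (", bits, ") in ", path)
  is_rgb <- length(dim(px)) == 3L
  if (is_rgb) {
    if (dim(px)[3L] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(px)[3L] != 3L)
      stop("unsupported channel count (", dim(px)[3L], ") in ", path)
  }
  # tiff::readTIFF already rescales integer samples to [0,1] by the dtype max
  px[] <- pmin(pmax(px, 0), 1)
  structure(list(pixels = px, source_path = path,
                 original_bit_depth = bits, is_rgb_source = is_rgb),
            class = "spheroid_image")
}

#' @export
print.spheroid_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("spheroid_image: %d x %d px, %s, %d-bit source\n  %s\n",
              d[1L], d[2L], if (x$is_rgb_source) "RGB" else "grayscale",
              x$original_bit_depth, x$source_path))
  invisible(x)
}

#' Write a \[0,1\] image matrix to a 16-bit grayscale TIFF
#'
#' @param pixels Numeric matrix with values in \[0, 1\].
#' @param path Output path.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pixels, path, bits = 16L) {
  pixels <- as_pixels(pixels)
  tiff::writeTIFF(pmin(pmax(pixels, 0), 1), path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# Accept a spheroid_image or a bare matrix/array.
as_pixels <- function(image) {
  if (inherits(image, "spheroid_image")) image$pixels
  else if (is.numeric(image) && length(dim(image)) %in% c(2L, 3L)) image
  else stop("expected a spheroid_image or a numeric matrix/array")
}

#' Default filename metadata pattern
#'
#' Named-group regular expression for filenames of the form
#' `Experiment_SpheroidID_Channel.tiff` with the channel fixed to the
#' brightfield/transmitted-light tag `TRANS`.
#' @return A character scalar (PCRE with Python-style named groups).
#' @export
default_metadata_pattern <- function() {
  "(?P<Experiment>.*)_(?P<SpheroidID>.*(_\\d+)?)_(?P<Channel>TRANS)\\.tiff"
}

#' Parse image metadata from a filename
#'
#' Applies a named-group regular expression, anchored to the whole filename,
#' and returns the captured fields. The groups `Experiment`, `SpheroidID`
#' and `Channel` are required; optional `Day` and `Condition` groups are
#' picked up when the pattern defines them. Greedy-quantifier semantics are
#' those of the PCRE engine: in the default pattern the leading `Experiment`
#' group captures as much as it can, so `"OA50_sph_03_TRANS.tiff"` parses as
#' experiment `"OA50_sph"`, spheroid id `"03"`.
#'
#' @param filename Base filename (not a path).
#' @param pattern Named-group regular expression; defaults to
#'   [default_metadata_pattern()].
#' @return A list of class `image_metadata` with fields `experiment`,
#'   `spheroid_id`, `channel`, and optional `day` (integer) / `condition`.
#' @examples
#' parse_metadata("ExpA_sph01_TRANS.tiff")
#' @export
parse_metadata <- function(filename, pattern = default_metadata_pattern()) {
  stopifnot(is.character(filename), length(filename) == 1L)
  anchored <- paste0("^(?:", pattern, ")$")
  m <- regexpr(anchored, filename, perl = TRUE)
  if (m < 0L)
    stop(structure(class = c("metadata_parse_error", "error", "condition"),
                   list(message = sprintf(
                     "filename '%s' does not match pattern '%s'",
                     filename, pattern), call = sys.call(-1))))
  st <- attr(m, "capture.start")[1L, ]
  ln <- attr(m, "capture.length")[1L, ]
  nm <- names(st)
  grab <- function(g) {
    i <- match(g, nm)
    if (is.na(i) || st[i] <= 0L) NA_character_
    else substr(filename, st[i], st[i] + ln[i] - 1L)
  }
  need <- c("Experiment", "SpheroidID", "Channel")
  if (!all(need %in% nm))
    stop("pattern must define named groups Experiment, SpheroidID, Channel")
  out <- list(experiment = grab("Experiment"),
              spheroid_id = grab("SpheroidID"),
              channel = grab("Channel"),
              day = {
                d <- grab("Day")
                if (is.na(d)) NA_integer_ else as.integer(d)
              },
              condition = grab("Condition"))
  if (any(!nzchar(unlist(out[c("experiment", "spheroid_id", "channel")]))))
    stop("pattern matched but a required field is empty in '", filename, "'")
  structure(out, class = "image_metadata")
}

#' List candidate input images in a folder
#'
#' Returns lexicographically sorted file paths whose names end with
#' `extension` (case-insensitive). Set `extension = NULL` to disable
#' filtering and return every file.
#'
#' @param folder Directory to scan.
#' @param extension Filename suffix filter, e.g. `".tiff"`; `NULL` disables.
#' @return Character vector of full paths, sorted.
#' @export
list_inputs <- function(folder, extension = ".tiff") {
  if (!dir.exists(folder)) stop("not a directory: ", folder)
  f <- list.files(folder, full.names = TRUE)
  f <- f[!dir.exists(f)]
  if (!is.null(extension))
    f <- f[endsWith(tolower(basename(f)), tolower(extension))]
  sort(f, method = "radix")
}

#' Read a sidecar metadata table
#'
#' Reads a CSV with header `spheroid_id,day,condition` mapping spheroid ids
#' (as captured from filenames) to imaging day and treatment condition, for
#' filename schemes that do not encode day/condition directly.
#'
#' @param path CSV path.
#' @return A data.frame with columns `spheroid_id`, `day` (integer),
#'   `condition`.
#' @export
read_metadata_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("spheroid_id", "day", "condition")
  if (!all(need %in% names(d)))
    stop("metadata CSV must have columns: ", paste(need, collapse = ", "))
  d$day <- as.integer(d$day)
  d$spheroid_id <- as.character(d$spheroid_id)
  d$condition <- as.character(d$condition)
  d
}
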