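# Fluorescence image container and contrast normalization.

REGIONS <- c("anterior", "posterior", "unknown")
CONDITIONS <- c("young", "aged", "cold_shock", "recovery", "control")

#' Construct a fluorescence image
#'
#' The universal input record of the pipeline: a 2-D non-negative intensity
#' matrix (one channel, a maximum-intensity projection in the intended use)
#' plus acquisition/biology metadata. Coordinates are 1-based `(row, col)`
#' with the origin at the top-left; all distances are in pixel units.
#'
#' @param pixels numeric matrix of finite, non-negative intensities.
#' @param meta list with optional entries `animal_id` (character), `region`
#'   (one of `"anterior"`, `"posterior"`, `"unknown"`), `condition` (one of
#'   `"young"`, `"aged"`, `"cold_shock"`, `"recovery"`, `"control"`),
#'   `age_day` (integer days) and `temperature_C` (numeric).
#' @return an object of class `fluor_image` with elements `pixels` and
#'   `meta`.
#' @export
fluor_image <- function(pixels, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have height >= 1 and width >= 1")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("all intensities must be finite and >= 0")
  meta$region <- match.arg(meta$region %||% "unknown", REGIONS)
  if (!is.null(meta$condition))
    meta$condition <- match.arg(meta$condition, CONDITIONS)
  structure(list(pixels = pixels, meta = meta), class = "fluor_image")
}

#' @export
print.fluor_image <- function(x, ...) {
  cat(sprintf("<fluor_image> %d x %d, intensity range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.fluor_image <- function(x) dim(x$pixels)

#' Load a single-channel image from PNG or TIFF
#'
#' Reads 8- or 16-bit PNG/TIFF rasters and preserves the stored integer
#' values bit-exactly. Multi-channel rasters are accepted only when all
#' channels are identical (a grayscale image saved as RGB); channel 1 is
#' then used.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param meta metadata list, attached unchanged (see [fluor_image()]).
#' @return a [fluor_image()].
#' @export
load_image <- function(path, meta = list()) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    raw <- png::readPNG(path, info = TRUE)
    depth <- attr(raw, "info")$bit.depth %||% 8
    m <- collapse_channels(raw, path)
    m <- round(m * (2^depth - 1))
  } else if (ext %in% c("tif", "tiff")) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    m <- collapse_channels(raw, path)
  } else {
    stop("unsupported image format: ", ext)
  }
  fluor_image(m, meta)
}

collapse_channels <- function(a, path) {
  if (length(dim(a)) == 2L) return(a)
  if (length(dim(a)) == 3L) {
    ch1 <- a[, , 1L]
    for (k in seq_len(dim(a)[3L])[-1L]) {
      if (!isTRUE(all.equal(ch1, a[, , k], tolerance = 0)))
        stop("multi-channel image with differing channels: ", path)
    }
    return(ch1)
  }
  stop("unsupported raster dimensionality in ", path)
}

#' Write an image to disk
#'
#' Writes a 16-bit single-channel raster (TIFF) or an 8/16-bit PNG depending
#' on the file extension. Intensities are clipped to the target range.
#'
#' @param img a [fluor_image()].
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param max_value full-scale value the image is scaled against (default:
#'   the image maximum, or 1 for a constant zero image).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, max_value = NULL) {
  m <- img$pixels
  mv <- max_value %||% max(max(m), 1)
  m <- pmin(pmax(m / mv, 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = 16)
  } else if (ext == "png") {
    png::writePNG(m, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Contrast normalization by quantile stretching
#'
#' Linearly rescales intensities so the `low_frac` quantile maps to 0 and
#' the `1 - high_frac` quantile maps to 1, with clipping; the same
#' saturation-based stretch used to equalize contrast across a dataset
#' before segmentation. A constant image is returned unchanged.
#'
#' @param img a [fluor_image()].
#' @param low_frac,high_frac fractions of pixels saturated at the low/high
#'   end; defaults 0.01 each; `low_frac + high_frac` must be < 1.
#' @return a [fluor_image()] with intensities in `[0, 1]`; metadata
#'   untouched.
#' @export
normalize_contrast <- function(img, low_frac = 0.01, high_frac = 0.01) {
  stopifnot(low_frac >= 0, high_frac >= 0, low_frac + high_frac < 1)
  m <- img$pixels
  lo <- stats::quantile(m, low_frac, names = FALSE, type = 7)
  hi <- stats::quantile(m, 1 - high_frac, names = FALSE, type = 7)
  if (hi <= lo) return(img)  # zero dynamic range
  out <- (m - lo) / (hi - lo)
  out <- pmin(pmax(out, 0), 1)
  fluor_image(out, img$meta)
}
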