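#' Read a grayscale PNG or TIFF image
#'
#' Reads single-channel PNG/TIFF rasters into a [gray_image()]. Integer
#' data keep their native scale (`L = 255` for 8-bit, `L = 65535` for
#' 16-bit) unless `normalize = TRUE`, which maps the maximum level to
#' exactly 1. Multi-channel images are an error unless a `collapse` rule
#' is given (`"mean"` of the channels, or `"luminance"` =
#' 0.299 R + 0.587 G + 0.114 B).
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param normalize Return intensities on `[0, 1]` (default `FALSE`).
#' @param collapse `"error"` (default), `"mean"` or `"luminance"` for
#'   multi-channel input.
#' @return A [gray_image()].
#' @export
read_gray <- function(path, normalize = FALSE,
                      collapse = c("error", "mean", "luminance")) {
  collapse <- match.arg(collapse)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path, info = TRUE)
    bits <- attr(a, "info")$bit.depth %||% 8L
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(a, "bits.per.sample") %||% 8L
  } else {
    stop("unsupported image format: .", ext)
  }
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    if (collapse == "error")
      stop("multi-channel image; pass collapse = \"mean\" or \"luminance\"")
    a <- if (collapse == "mean") {
      apply(a[, , seq_len(min(nc, 3L)), drop = FALSE], c(1, 2), mean)
    } else {
      w <- c(0.299, 0.587, 0.114)[seq_len(min(nc, 3L))]
      m <- a[, , 1] * 0
      for (ch in seq_along(w)) m <- m + w[ch] * a[, , ch]
      m / sum(w)
    }
  }
  a <- matrix(as.numeric(a), nrow(a), ncol(a))
  L <- 2^bits - 1
  if (normalize) gray_image(a, ceiling = 1)
  else gray_image(round(a * L), ceiling = L)
}

#' Write a grayscale image as PNG or TIFF
#'
#' Writes a [gray_image()] to an 8- or 16-bit grayscale raster.
#' Intensities are scaled by the image's level ceiling; integer data on
#' a matching ceiling round-trip losslessly through [read_gray()].
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @param bits Output bit depth, 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path, bits = 8L) {
  img <- as_gray_image(img)
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16")
  v <- as.matrix(img) / img_ceiling(img)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bits != 8L) stop("PNG output is 8-bit; use TIFF for 16-bit data")
    png::writePNG(v, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v, where = path, bits.per.sample = bits)
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

#' Write a synthetic fixture with a provenance manifest
#'
#' Saves an image (and optionally its mask) as PNG plus a JSON sidecar
#' recording the generator parameters and seed, so synthetic fixtures
#' are reproducible from their manifests alone.
#'
#' @param img A [gray_image()].
#' @param path Output PNG path; the manifest is written to
#'   `paste0(path, ".json")` and a mask, if given, to
#'   `*_mask.png`.
#' @param manifest Named list of provenance fields (parameters, seed).
#' @param mask Optional [region_mask()].
#' @return `path`, invisibly.
#' @export
write_fixture <- function(img, path, manifest = list(), mask = NULL) {
  write_gray(img, path)
  if (!is.null(mask)) {
    mpath <- sub("\\.png$", "_mask.png", path)
    write_gray(gray_image(as_mask_matrix(mask) * 1, ceiling = 1), mpath)
    manifest$mask <- basename(mpath)
  }
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
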