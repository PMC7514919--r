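#' Histogram equalization
#'
#' Classical cumulative-histogram intensity mapping: intensities are
#' binned into `nbins` equal-width bins over `[0, L]` and each pixel is
#' mapped to `L * cdf(bin)`, a monotone non-decreasing transfer curve
#' that flattens the output histogram. Applying the map twice moves no
#' pixel by more than one quantization step.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param nbins Number of histogram bins, `>= 2` (default 256).
#' @return A [gray_image()] with the same shape and ceiling.
#' @examples
#' eq <- histogram_equalize(gaussian_scene())
#' @export
histogram_equalize <- function(img, nbins = 256L) {
  img <- as_gray_image(img)
  stopifnot(nbins >= 2)
  L <- img_ceiling(img)
  m <- as.matrix(img)
  b <- intensity_bins(m, L, nbins)
  cdf <- cumsum(tabulate(b + 1L, nbins)) / length(m)
  out <- matrix(L * cdf[b + 1L], nrow(m), ncol(m))
  gray_image(out, ceiling = L)
}

# common binning rule: floor(v / L * (nbins - 1)), bit-exact across depths
intensity_bins <- function(m, L, nbins) {
  pmin.int(floor(m / L * (nbins - 1)), nbins - 1L)
}

#' Gray-level slicing (intensity windowing)
#'
#' Maps the window `[low, high]` linearly onto `[0, L]`. Outside the
#' window, `mode = "clamp"` saturates to 0 / `L` while `mode = "reject"`
#' zeroes the pixel. The default window spans the image's 2nd to 98th
#' intensity percentiles, excluding the extreme intensity ranges.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param low,high Window endpoints, `0 <= low < high <= L`; default the
#'   2nd / 98th percentiles of the image.
#' @param mode `"clamp"` (default) or `"reject"`.
#' @return A [gray_image()] with the same shape and ceiling.
#' @examples
#' sl <- slicing(gaussian_scene(), low = 0.1, high = 0.9)
#' @export
slicing <- function(img, low = NULL, high = NULL,
                    mode = c("clamp", "reject")) {
  img <- as_gray_image(img)
  mode <- match.arg(mode)
  L <- img_ceiling(img)
  m <- as.matrix(img)
  if (is.null(low) || is.null(high)) {
    qs <- stats::quantile(m, c(0.02, 0.98), names = FALSE)
    if (is.null(low)) low <- qs[1]
    if (is.null(high)) high <- qs[2]
  }
  if (!(low >= 0 && high <= L)) stop("window must lie within [0, L]")
  if (low >= high) stop("`low` must be strictly below `high`")
  out <- (m - low) / (high - low) * L
  if (mode == "clamp") {
    out <- pmin(pmax(out, 0), L)
  } else {
    out[m < low | m > high] <- 0
  }
  gray_image(matrix(out, nrow(m), ncol(m)), ceiling = L)
}

#' Otsu threshold and foreground mask
#'
#' Chooses the binarization threshold maximizing the between-class
#' intensity variance of the `nbins`-bin histogram (bins by
#' `floor(v / L * (nbins - 1))`, identical for any bit depth). Ties are
#' broken toward the lower threshold. The returned threshold is the
#' lower edge of the first foreground bin, expressed on the image's
#' intensity scale; the mask marks pixels `>= threshold`.
#'
#' @param img A [gray_image()] or numeric matrix with at least two
#'   distinct quantized levels.
#' @param nbins Number of histogram bins (default 256).
#' @return A list with `threshold` (intensity) and `mask` (a
#'   [region_mask()]).
#' @examples
#' ot <- otsu_threshold(gaussian_scene())
#' ot$threshold
#' @export
otsu_threshold <- function(img, nbins = 256L) {
  img <- as_gray_image(img)
  stopifnot(nbins >= 2)
  L <- img_ceiling(img)
  m <- as.matrix(img)
  b <- intensity_bins(m, L, nbins)
  counts <- tabulate(b + 1L, nbins)
  if (sum(counts > 0) < 2)
    stop("Otsu threshold undefined: image has fewer than 2 quantized levels")
  p <- counts / length(m)
  lev <- 0:(nbins - 1)
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  muT <- mu[nbins]
  # candidate k: background = bins 0..k-1, foreground = bins k..nbins-1
  k <- seq_len(nbins - 1L)
  W0 <- w0[k]; W1 <- 1 - W0
  bc <- ifelse(W0 > 0 & W1 > 0,
               (muT * W0 - mu[k])^2 / (W0 * W1), -Inf)
  kstar <- k[which.max(bc)]          # which.max takes the first (lowest) tie
  thr <- kstar / (nbins - 1) * L
  list(threshold = thr, mask = region_mask(m >= thr))
}
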