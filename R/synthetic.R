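#' Geometry of the synthetic Gaussian phantom
#'
#' Describes the radially symmetric Gaussian test scene: raster size,
#' center position and spread. The default reproduces the study scene —
#' a 256x256 raster with the peak at pixel (175, 175) and a spread of 30
#' pixels, amplitude normalized to `[0, 1]`. `delta` is read as a
#' standard deviation in pixels; set `delta_is_variance = TRUE` to read
#' it as a variance instead (spread `sqrt(delta)`).
#'
#' @param height,width Raster size in pixels.
#' @param center Numeric `(row, col)` of the peak, inside the raster.
#' @param delta Spread in pixels (standard deviation unless
#'   `delta_is_variance`).
#' @param delta_is_variance Interpret `delta` as a variance.
#' @return A `gaussian_scene_spec` object.
#' @examples
#' gaussian_scene_spec()
#' @export
gaussian_scene_spec <- function(height = 256, width = 256,
                                center = c(175, 175), delta = 30,
                                delta_is_variance = FALSE) {
  stopifnot(height >= 1, width >= 1, length(center) == 2L,
            is.numeric(delta), delta > 0)
  if (center[1] < 1 || center[1] > height || center[2] < 1 || center[2] > width)
    stop("`center` must lie inside the raster")
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = as.numeric(center),
                 sd = if (delta_is_variance) sqrt(delta) else delta),
            class = "gaussian_scene_spec")
}

#' @export
print.gaussian_scene_spec <- function(x, ...) {
  cat(sprintf("<gaussian_scene_spec %dx%d, center (%g, %g), sd %g px>\n",
              x$height, x$width, x$center[1], x$center[2], x$sd))
  invisible(x)
}

# squared pixel-center distance to the scene center
scene_dist2 <- function(spec) {
  outer((seq_len(spec$height) - spec$center[1])^2,
        (seq_len(spec$width) - spec$center[2])^2, "+")
}

#' Generate the Gaussian phantom image
#'
#' Pixel value `exp(-d^2 / (2 sd^2))` with `d` the Euclidean distance of
#' the pixel center to the scene center, renormalized so the maximum is
#' exactly 1. The scene is rotationally symmetric about its center up to
#' raster discretization and is a pure function of its spec.
#'
#' @param spec A [gaussian_scene_spec()].
#' @return A [gray_image()] with ceiling 1.
#' @examples
#' img <- gaussian_scene()
#' img[175, 175]  # 1 at the center
#' @export
gaussian_scene <- function(spec = gaussian_scene_spec()) {
  stopifnot(inherits(spec, "gaussian_scene_spec"))
  v <- exp(-scene_dist2(spec) / (2 * spec$sd^2))
  gray_image(v / max(v), ceiling = 1)
}

#' Ground-truth disc of the phantom's region of interest
#'
#' The region to be highlighted: all pixels within `k` spreads of the
#' scene center (`d <= k * sd`), clipped at the raster borders. With the
#' default `k = 3` this is the 3-sigma disc. `mode = "intensity"`
#' instead thresholds the phantom at the equivalent intensity level
#' `exp(-k^2 / 2)`, which coincides with the disc away from clipping.
#'
#' @param spec A [gaussian_scene_spec()].
#' @param k Radius in spread units, `> 0` (default 3).
#' @param mode `"disc"` (spatial, default) or `"intensity"`.
#' @return A [region_mask()] of the scene's shape.
#' @examples
#' m <- ground_truth_mask(gaussian_scene_spec(), k = 2)
#' sum(m)
#' @export
ground_truth_mask <- function(spec = gaussian_scene_spec(), k = 3,
                              mode = c("disc", "intensity")) {
  stopifnot(inherits(spec, "gaussian_scene_spec"), is.numeric(k), k > 0)
  mode <- match.arg(mode)
  if (mode == "disc") {
    region_mask(scene_dist2(spec) <= (k * spec$sd)^2)
  } else {
    img <- gaussian_scene(spec)
    region_mask(as.matrix(img) >= exp(-k^2 / 2))
  }
}

#' Add seeded Gaussian noise at a target signal-to-noise ratio
#'
#' Adds zero-mean Gaussian noise with variance `mean(signal^2) / snr`
#' (linear power-ratio convention, not dB) and clips the result to
#' `[0, L]`. The same `(img, snr, seed)` always produces the identical
#' output; the global RNG state is advanced by the internal
#' `set.seed()`/draw.
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param snr Target signal-to-noise power ratio, `> 0`.
#' @param seed Integer seed.
#' @return A [gray_image()] of the same shape and ceiling.
#' @examples
#' noisy <- add_gaussian_noise(gaussian_scene(), snr = 10, seed = 1)
#' @export
add_gaussian_noise <- function(img, snr, seed) {
  img <- as_gray_image(img)
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop("`snr` must be a single positive number")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  L <- img_ceiling(img)
  m <- as.matrix(img)
  sigma <- sqrt(mean(m^2) / snr)
  set.seed(as.integer(seed))
  noisy <- m + stats::rnorm(length(m), mean = 0, sd = sigma)
  gray_image(matrix(pmin(pmax(noisy, 0), L), nrow(m), ncol(m)), ceiling = L)
}

#' Seeded noisy-phantom series
#'
#' Generates `n` noise-degraded copies of a scene across a range of
#' signal-to-noise ratios, paired with the scene's ground-truth mask —
#' the synthetic counterpart of a noise-robustness study. SNR values are
#' spaced linearly from `snr_min` to `snr_max`; a nominal lower endpoint
#' of 0 is mapped to the smallest positive value of the series.
#'
#' @param spec A [gaussian_scene_spec()].
#' @param n Number of images.
#' @param snr_min,snr_max SNR range (linear power ratio).
#' @param seed Integer seed; image `i` uses `seed + i - 1`.
#' @param k Ground-truth disc radius in spread units.
#' @return A list with elements `image` (list of [gray_image()]), `snr`
#'   (numeric), and `truth` (the shared [region_mask()]).
#' @examples
#' s <- noisy_phantom_series(n = 3, snr_min = 1, snr_max = 100, seed = 1)
#' length(s$image)
#' @export
noisy_phantom_series <- function(spec = gaussian_scene_spec(), n = 100,
                                 snr_min = 0, snr_max = 100, seed = 1, k = 3) {
  stopifnot(n >= 1, snr_max > 0, snr_min >= 0, snr_min <= snr_max)
  snrs <- if (n == 1) snr_max else seq(snr_min, snr_max, length.out = n)
  pos <- snrs[snrs > 0]
  if (length(pos) == 0) stop("the SNR series must contain a positive value")
  snrs[snrs <= 0] <- min(pos)   # degenerate 0 endpoint -> smallest positive
  base <- gaussian_scene(spec)
  list(image = lapply(seq_len(n), function(i)
         add_gaussian_noise(base, snrs[i], seed = seed + i - 1)),
       snr = snrs,
       truth = ground_truth_mask(spec, k = k))
}

#' Synthetic speckled-lesion scene
#'
#' An ultrasound-like fixture: a darker elliptical lesion on a brighter
#' background, multiplied by unit-mean gamma speckle with shape `looks`
#' (larger `looks` means milder speckle; `looks -> Inf` recovers the
#' noiseless piecewise scene). This is a qualitative stand-in for real
#' speckle-corrupted scans, not a physical ultrasound simulation. The
#' result is clipped to `[0, 1]` and is a pure function of its
#' arguments.
#'
#' @param height,width Raster size.
#' @param lesion_center Numeric `(row, col)` of the lesion center.
#' @param lesion_axes Numeric `(semi_row, semi_col)` ellipse semi-axes in
#'   pixels.
#' @param background_level,lesion_level Noiseless intensities in `[0, 1]`.
#' @param looks Gamma shape of the speckle, `>= 1`.
#' @param seed Integer seed.
#' @return A list with `image` (a [gray_image()]) and `mask` (the true
#'   lesion [region_mask()]).
#' @examples
#' sc <- speckled_lesion_scene(seed = 1)
#' mean(sc$image)
#' @export
speckled_lesion_scene <- function(height = 256, width = 256,
                                  lesion_center = c(128, 128),
                                  lesion_axes = c(40, 55),
                                  background_level = 0.6,
                                  lesion_level = 0.2,
                                  looks = 4, seed = 1) {
  stopifnot(height >= 1, width >= 1, length(lesion_center) == 2L,
            length(lesion_axes) == 2L, all(lesion_axes > 0),
            background_level >= 0, background_level <= 1,
            lesion_level >= 0, lesion_level <= 1, looks >= 1)
  if (lesion_center[1] - lesion_axes[1] < 1 ||
      lesion_center[1] + lesion_axes[1] > height ||
      lesion_center[2] - lesion_axes[2] < 1 ||
      lesion_center[2] + lesion_axes[2] > width)
    stop("lesion ellipse must lie inside the raster")
  r <- seq_len(height); cc <- seq_len(width)
  inside <- outer(((r - lesion_center[1]) / lesion_axes[1])^2,
                  ((cc - lesion_center[2]) / lesion_axes[2])^2, "+") <= 1
  base <- matrix(background_level, height, width)
  base[inside] <- lesion_level
  set.seed(as.integer(seed))
  speckle <- matrix(stats::rgamma(height * width, shape = looks, rate = looks),
                    height, width)
  img <- pmin(pmax(base * speckle, 0), 1)
  list(image = gray_image(img, ceiling = 1), mask = region_mask(inside))
}
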