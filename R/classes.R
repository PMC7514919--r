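#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of finite intensities in `[0, L]`
#' together with its level ceiling `L` (1 for normalized data, 255 for
#' 8-bit, 65535 for 16-bit). All transforms and metrics in this package
#' take and return `gray_image` objects; plain matrices are accepted by
#' most functions and coerced with a ceiling of 1 or `max(x)`.
#'
#' @param pixels Numeric matrix of intensities.
#' @param ceiling Maximum representable intensity `L` (default 1).
#' @return A `gray_image` object (a matrix with attributes `ceiling` and,
#'   optionally, `family` recording the transform that produced it).
#' @examples
#' img <- gray_image(matrix(seq(0, 1, length.out = 16), 4, 4))
#' img_ceiling(img)
#' @export
gray_image <- function(pixels, ceiling = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  if (!all(is.finite(pixels)))
    stop("all pixel values must be finite")
  if (!is.numeric(ceiling) || length(ceiling) != 1L || ceiling <= 0)
    stop("`ceiling` must be a single positive number")
  if (any(pixels < 0) || any(pixels > ceiling))
    stop("pixel values must lie in [0, ceiling]")
  structure(pixels, ceiling = as.numeric(ceiling), class = "gray_image")
}

#' @rdname gray_image
#' @param x Object to query or coerce.
#' @export
img_ceiling <- function(x) {
  L <- attr(x, "ceiling")
  if (is.null(L)) max(1, max(x)) else L
}

#' @rdname gray_image
#' @param ... Unused.
#' @export
as.matrix.gray_image <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, L = %g, range [%.4g, %.4g]>\n",
              nrow(x), ncol(x), img_ceiling(x), min(x), max(x)))
  fam <- attr(x, "family")
  if (!is.null(fam)) cat("  produced by family:", fam, "\n")
  invisible(x)
}

# coerce matrices / EBImage-like arrays, defaulting L to 1 when data fit
as_gray_image <- function(x, ceiling = NULL) {
  if (inherits(x, "gray_image")) return(x)
  if (!is.matrix(x)) stop("expected a gray_image or a numeric matrix")
  if (is.null(ceiling)) ceiling <- if (max(x) <= 1) 1 else max(x)
  gray_image(x, ceiling)
}

#' Boolean region-of-interest mask
#'
#' A logical matrix marking a region of interest, paired by shape with a
#' [gray_image()].
#'
#' @param m Logical matrix (or numeric, coerced by `!= 0`).
#' @return A `region_mask` object.
#' @examples
#' region_mask(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
#' @export
region_mask <- function(m) {
  if (!is.matrix(m)) stop("`m` must be a matrix")
  if (!is.logical(m)) m <- m != 0
  if (anyNA(m)) stop("mask must not contain NA")
  structure(m, class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %dx%d, %d pixels set>\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

as_mask_matrix <- function(m) {
  if (!is.matrix(m)) stop("expected a matrix mask")
  if (!is.logical(m)) m <- m != 0
  attributes(m) <- list(dim = dim(m))
  m
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("inputs must have identical dimensions")
  invisible(TRUE)
}

#' Transform parameter bundle
#'
#' Collects the four parameters of the sigmoid / q-sigmoid transform
#' family: the target intensity `beta` (the intensity mapped to 1), the
#' scale `alpha > 0` giving the half-width of the highlighted band
#' `[beta - alpha, beta + alpha]` in intensity units, the dimensionless
#' gain `lam > 0` controlling the decay away from `beta`, and the
#' entropic index `q >= 0` of the Tsallis deformation (`q = 1` restores
#' the classical exponentials).
#'
#' `family` selects the functional form: `"sigmoid"` and
#' `"modified_sigmoid"` are the classical forms with background
#' asymptotes 0 and 1/2; `"qsig_low"` (intended for `q < 1`) and
#' `"qsig_high"` (intended for `q > 1`) are their q-deformations.
#' `"auto"` resolves to `qsig_low` for `q < 1`, `qsig_high` for `q > 1`
#' and `sigmoid` at `q = 1`. Values of `q` within `1e-9` of 1 always use
#' the classical closed forms.
#'
#' Out-of-intent index ranges (`qsig_low` with `q > 1`, `qsig_high` with
#' `q < 1`) are rejected unless `extend = TRUE`: with the extension,
#' `qsig_low` maps pixels where the deformed base is non-positive to 0
#' (the one-sided limit of the expression), and `qsig_high` applies the
#' literal q-exponential cutoff there, giving value 1.
#'
#' @param beta Target intensity (same scale as the image).
#' @param alpha Scale, `> 0`, intensity units.
#' @param lam Gain, `> 0`, dimensionless.
#' @param q Entropic index, `>= 0`.
#' @param family One of `"auto"`, `"sigmoid"`, `"modified_sigmoid"`,
#'   `"qsig_low"`, `"qsig_high"`.
#' @param extend Enable the out-of-intent q-range extensions described
#'   above (default `FALSE`).
#' @return A `transform_params` object.
#' @examples
#' transform_params(beta = 1, alpha = 0.03, lam = 1, q = 0.7)
#' @export
transform_params <- function(beta, alpha, lam = 1, q = 1,
                             family = c("auto", "sigmoid", "modified_sigmoid",
                                        "qsig_low", "qsig_high"),
                             extend = FALSE) {
  family <- match.arg(family)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(lam), length(lam) == 1L, is.finite(lam),
            is.numeric(q), length(q) == 1L, is.finite(q))
  if (alpha <= 0) stop("`alpha` must be > 0")
  if (lam <= 0) stop("`lam` must be > 0")
  if (q < 0) stop("`q` must be >= 0")
  p <- structure(list(beta = beta, alpha = alpha, lam = lam, q = q,
                      family = family, extend = isTRUE(extend)),
                 class = "transform_params")
  resolve_family(p)  # validates the family/q combination
  p
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf(
    "<transform_params beta=%g alpha=%g lam=%g q=%g family=%s%s -> %s>\n",
    x$beta, x$alpha, x$lam, x$q, x$family,
    if (x$extend) " (extended)" else "", resolve_family(x)))
  invisible(x)
}

# tolerance below which q is treated as exactly 1 (classical forms)
Q_ONE_TOL <- 1e-9

#' Resolve the effective transform family of a parameter set
#'
#' Applies the `auto` dispatch rule (`q < 1` to `qsig_low`, `q > 1` to
#' `qsig_high`, `q = 1` to `sigmoid`) and checks q-range/family
#' compatibility.
#'
#' @param p A [transform_params()] object.
#' @return One of `"sigmoid"`, `"modified_sigmoid"`, `"qsig_low"`,
#'   `"qsig_high"`.
#' @export
resolve_family <- function(p) {
  stopifnot(inherits(p, "transform_params"))
  q1 <- abs(p$q - 1) < Q_ONE_TOL
  fam <- p$family
  if (fam == "auto") {
    fam <- if (q1) "sigmoid" else if (p$q < 1) "qsig_low" else "qsig_high"
  }
  if (fam == "qsig_low" && p$q > 1 && !q1 && !p$extend)
    stop("qsig_low with q > 1 requires `extend = TRUE` (continuity extension)")
  if (fam == "qsig_high" && p$q < 1 && !q1 && !p$extend)
    stop("qsig_high with q < 1 requires `extend = TRUE` (cutoff extension)")
  fam
}
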