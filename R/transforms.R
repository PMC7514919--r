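#' Tsallis q-exponential
#'
#' The deformed exponential `[1 + (1-q) x]^(1/(1-q))` with the cutoff
#' convention: the value is 0 wherever the base `1 + (1-q) x` is
#' non-positive. For `q` within `1e-9` of 1 the classical `exp(x)` is
#' returned (its `q -> 1` limit). The deformed power is evaluated as
#' `exp(log1p((1-q) x) / (1-q))`; overflow yields `Inf` and underflow 0,
#' both of which downstream sigmoid forms absorb gracefully.
#'
#' @param x Numeric vector (finite).
#' @param q Entropic index, a single value `>= 0`.
#' @return Numeric vector of the same length as `x`, values `>= 0`.
#' @examples
#' q_exp(1, 0.5)   # (1 + 0.5)^2 = 2.25
#' q_exp(-3, 0.5)  # cutoff: 0
#' q_exp(1, 1)     # exp(1)
#' @export
q_exp <- function(x, q) {
  stopifnot(is.numeric(x), is.numeric(q), length(q) == 1L, is.finite(q))
  if (q < 0) stop("`q` must be >= 0")
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (abs(q - 1) < Q_ONE_TOL) return(exp(x))
  omq <- 1 - q
  arg <- omq * x
  out <- x * 0
  pos <- arg > -1          # base 1 + (1-q) x > 0
  out[pos] <- exp(log1p(arg[pos]) / omq)
  out
}

# |I - beta| / alpha with domain checks shared by the family kernels
scaled_dev <- function(I, p) {
  stopifnot(inherits(p, "transform_params"))
  if (!is.numeric(I) || !all(is.finite(I))) stop("intensities must be finite")
  abs(I - p$beta) / p$alpha
}

#' Classical bell-shaped sigmoid transform
#'
#' `2 / (1 + exp(lam * |I - beta| / alpha))`: peaks at exactly 1 when
#' `I = beta`, is symmetric about `beta`, and decays to 0 as
#' `|I - beta|` grows.
#'
#' @param I Numeric vector of intensities.
#' @param p A [transform_params()] object (only `beta`, `alpha`, `lam`
#'   are used).
#' @return Values in `(0, 1]`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30)
#' sigmoid_i1(143, p)  # 2 / (1 + exp(0.5))
#' @export
sigmoid_i1 <- function(I, p) {
  u <- scaled_dev(I, p)
  2 / (1 + exp(p$lam * u))
}

#' Modified sigmoid transform with 1/2 background
#'
#' For `I != beta` returns `1 / (1 + exp(-lam * (|I - beta|/alpha)^(-1)))`
#' and exactly 1 at `I = beta`. The reciprocal deviation in the exponent
#' makes the peak flat (one-sided slope 0 at `beta`) and the background
#' tend to 1/2 instead of 0 as `|I - beta|` grows.
#'
#' @inheritParams sigmoid_i1
#' @return Values in `(1/2, 1]`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30)
#' modified_sigmoid_i2(158, p)  # 1 / (1 + exp(-1))
#' @export
modified_sigmoid_i2 <- function(I, p) {
  u <- scaled_dev(I, p)
  out <- I * 0 + 1
  nz <- u > 0
  out[nz] <- 1 / (1 + exp(-p$lam / u[nz]))
  out
}

#' q-sigmoid transform for q < 1 (heavy-tailed peak)
#'
#' Substitutes the q-exponential into the bell sigmoid:
#' `2 / (1 + expq(lam * |I - beta| / alpha))`. For `q < 1` the deformed
#' base is always positive, the tail is heavier than the classical
#' sigmoid's (the value dominates [sigmoid_i1()] pointwise), and the
#' value is non-increasing in `q`. At `q = 1` it dispatches to the
#' classical form. `q > 1` requires `extend = TRUE` in the parameters;
#' pixels where the deformed base is non-positive then map to 0.
#'
#' @inheritParams sigmoid_i1
#' @return Values in `[0, 1]`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30, q = 0.5)
#' q_sigmoid_low(143, p)  # 2 / (1 + 1.25^2)
#' @export
q_sigmoid_low <- function(I, p) {
  stopifnot(inherits(p, "transform_params"))
  if (abs(p$q - 1) < Q_ONE_TOL) return(sigmoid_i1(I, p))
  if (p$q > 1 && !p$extend)
    stop("q_sigmoid_low with q > 1 requires `extend = TRUE`")
  u <- scaled_dev(I, p)
  E <- q_exp(p$lam * u, p$q)
  out <- 2 / (1 + E)
  # continuity extension: cutoff region maps to the one-sided limit 0
  if (p$q > 1) out[E == 0] <- 0
  out
}

#' q-sigmoid transform for q > 1 (1/2 background)
#'
#' The q-deformation of [modified_sigmoid_i2()]:
#' `1 / (1 + expq(lam * F))` with `F = -1 / (|I - beta| / alpha)` for
#' `I != beta`, and exactly 1 at `I = beta`. For `q > 1` the deformed
#' base `1 + lam (1-q) F` exceeds 1 for every `I != beta`, the peak is
#' lighter than the classical form's, and the value tends to 1/2 as
#' `|I - beta|` grows. At `q = 1` it dispatches to
#' [modified_sigmoid_i2()]. `q < 1` requires `extend = TRUE`; the literal
#' q-exponential cutoff then applies near `beta` (deformed exponential 0,
#' transform value 1).
#'
#' @inheritParams sigmoid_i1
#' @return Values in `[1/2, 1]`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30, q = 1.5)
#' q_sigmoid_high(158, p)  # 1 / (1 + 1.5^-2) = 9/13
#' @export
q_sigmoid_high <- function(I, p) {
  stopifnot(inherits(p, "transform_params"))
  if (abs(p$q - 1) < Q_ONE_TOL) return(modified_sigmoid_i2(I, p))
  if (p$q < 1 && !p$extend)
    stop("q_sigmoid_high with q < 1 requires `extend = TRUE`")
  u <- scaled_dev(I, p)
  out <- I * 0 + 1
  nz <- u > 0
  out[nz] <- 1 / (1 + q_exp(-p$lam / u[nz], p$q))
  out
}

family_fun <- function(fam) {
  switch(fam,
         sigmoid = sigmoid_i1,
         modified_sigmoid = modified_sigmoid_i2,
         qsig_low = q_sigmoid_low,
         qsig_high = q_sigmoid_high,
         stop("unknown family: ", fam))
}

#' Evaluate the resolved transform family pointwise
#'
#' Dispatches on [resolve_family()] and evaluates the corresponding
#' kernel at the given intensities. `q = 1` inside a q-family falls back
#' to its classical limit form.
#'
#' @inheritParams sigmoid_i1
#' @return Transform values in `[0, 1]`.
#' @export
eval_transform <- function(I, p) {
  family_fun(resolve_family(p))(I, p)
}

#' Apply a sigmoid / q-sigmoid transform to an image
#'
#' Maps every pixel through the resolved transform family. The
#' parameters `beta` and `alpha` must be on the image's intensity scale
#' (the transforms themselves are scale-agnostic). The output codomain
#' is `[0, 1]` (level ceiling 1); set `rescale = TRUE` to multiply the
#' result back to the input's ceiling, e.g. before writing an integer
#' format.
#'
#' @param img A [gray_image()] (or numeric matrix).
#' @param p A [transform_params()] object.
#' @param rescale Rescale the output to the input level ceiling
#'   (default `FALSE`).
#' @return A [gray_image()] of identical shape, with attribute `family`
#'   recording the resolved family.
#' @examples
#' img <- gaussian_scene()
#' out <- apply_transform(img, transform_params(1, 0.03, q = 0.7))
#' range(out)
#' @export
apply_transform <- function(img, p, rescale = FALSE) {
  img <- as_gray_image(img)
  fam <- resolve_family(p)
  v <- eval_transform(as.matrix(img), p)
  L <- 1
  if (isTRUE(rescale)) {
    L <- img_ceiling(img)
    v <- v * L
  }
  out <- gray_image(v, ceiling = L)
  attr(out, "family") <- fam
  out
}

#' Fractional logistic function and its q-generalization
#'
#' The S- or well-shaped curve
#' `D(I) = Dmax / (1 + C * exp(-k * |I - I0|^b))`, with the exponential
#' replaced by the q-exponential [q_exp()] when `q != 1`. For `b = 2`
#' (the quadratic case) `I = I0` is the unique minimum, with value
#' `Dmax / (1 + C)`, and the curve tends to `Dmax` in both tails; its
#' negative `1 - D(I)` is bell-shaped like [modified_sigmoid_i2()]. The
#' even extension `|I - I0|^b` is used so that non-integer exponents are
#' defined on both sides of `I0`.
#'
#' @param I Numeric vector of intensities.
#' @param Dmax Upper asymptote, `> 0`.
#' @param C Offset coefficient, `> 0`.
#' @param k Rate, `> 0`.
#' @param b Exponent, in `(0.5, 3)`.
#' @param I0 Location of the extremum.
#' @param q Entropic index (default 1, the classical form).
#' @return Numeric vector of the same length as `I`.
#' @examples
#' fractional_logistic(128, Dmax = 1, C = 1, k = 0.05, b = 2, I0 = 128)
#' @export
fractional_logistic <- function(I, Dmax, C, k, b, I0, q = 1) {
  stopifnot(is.numeric(I), all(is.finite(I)))
  if (!(Dmax > 0 && C > 0 && k > 0)) stop("Dmax, C, k must be > 0")
  if (!(b > 0.5 && b < 3.0)) stop("`b` must lie in (0.5, 3.0)")
  Dmax / (1 + C * q_exp(-k * abs(I - I0)^b, q))
}
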