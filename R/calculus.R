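#' Closed-form derivative of a transform family
#'
#' Evaluates `dF/dI` of the resolved family at `I` using the analytic
#' expressions for `I > beta`; for `I < beta` the sign-flipped expression
#' applies by the symmetry of every family about `beta`.
#'
#' At `I = beta` only one-sided limits exist for the bell sigmoid and the
#' low-q family: both equal `-lam / (2 alpha)` from the right (and its
#' negative from the left), independent of `q`. By convention the
#' right-hand value is returned there, with attribute `side = "right"`.
#' The flat-peak families (`modified_sigmoid`, `qsig_high`) have no
#' closed form at `beta`; evaluation there is an error directing callers
#' to [difference_quotient_d()] (their empirical slope at `beta` is 0 for
#' moderate `q`).
#'
#' @param I Numeric vector of intensities.
#' @param p A [transform_params()] object.
#' @return Numeric vector of derivatives; carries attribute
#'   `side = "right"` if any entry is the one-sided value at `beta`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30, q = 0.5)
#' analytic_derivative(128, p)  # one-sided limit -lam/(2 alpha)
#' @export
analytic_derivative <- function(I, p) {
  stopifnot(inherits(p, "transform_params"))
  if (!is.numeric(I) || !all(is.finite(I))) stop("intensities must be finite")
  fam <- resolve_family(p)
  if (abs(p$q - 1) < Q_ONE_TOL)
    fam <- switch(fam, qsig_low = "sigmoid", qsig_high = "modified_sigmoid",
                  fam)
  at_beta <- I == p$beta
  if (any(at_beta) && fam %in% c("modified_sigmoid", "qsig_high"))
    stop("no analytic derivative at I = beta for family ", fam,
         "; use difference_quotient_d()")
  u <- abs(I - p$beta) / p$alpha
  lam <- p$lam; a <- p$alpha; q <- p$q
  d <- switch(fam,
    sigmoid = {
      E <- exp(lam * u)
      -(2 * lam / a) * E / (1 + E)^2
    },
    modified_sigmoid = {
      g <- exp(-lam / u)
      -(lam / a) * u^-2 * g / (1 + g)^2
    },
    qsig_low = {
      base <- 1 + lam * (1 - q) * u
      h <- exp(log(base) / (1 - q))          # base^{1/(1-q)}
      hp <- exp(log(base) * q / (1 - q))     # base^{q/(1-q)}
      -(2 * lam / a) * hp / (1 + h)^2
    },
    qsig_high = {
      base <- 1 + lam * (1 - q) * (-1 / u)
      h <- exp(log(base) / (1 - q))
      hp <- exp(log(base) * q / (1 - q))
      -(lam / a) * u^-2 * hp / (1 + h)^2
    })
  # symmetry: sign flips on the left branch
  d <- d * ifelse(I < p$beta, -1, 1)
  if (any(at_beta)) {
    d[at_beta] <- -lam / (2 * a)  # one-sided limit, same for sigmoid/qsig_low
    attr(d, "side") <- "right"
  }
  d
}

#' Ratio of the low-q q-sigmoid to its first-order Taylor approximation
#'
#' Near the peak the low-q family is approximately linear:
#' `1 - (lam / (2 alpha)) (I - beta)`. This function returns the ratio
#' of the exact transform to that approximation for `I >= beta`. The
#' ratio equals 1 at `I = beta` and grows slowly with `I`; its maximum
#' over `q` in `(0, 1)` at `I = beta + alpha/2` stays below about 1.07
#' for `lam = 1`, quantifying how nearly linear the peak decay is.
#'
#' @param I Intensities `>= beta` with positive Taylor denominator.
#' @param p A [transform_params()] with `q < 1`.
#' @return Ratio values `> 0`.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30, q = 0.5)
#' taylor_ratio_r(143, p)
#' @export
taylor_ratio_r <- function(I, p) {
  stopifnot(inherits(p, "transform_params"))
  if (!is.numeric(I) || !all(is.finite(I))) stop("intensities must be finite")
  if (p$q >= 1) stop("taylor_ratio_r requires q < 1")
  if (any(I < p$beta)) stop("taylor_ratio_r requires I >= beta")
  denom <- 1 - (p$lam / (2 * p$alpha)) * (I - p$beta)
  if (any(denom <= 0)) stop("Taylor denominator must be positive")
  q_sigmoid_low(I, p) / denom
}

#' Forward difference quotient of the high-q family
#'
#' `(F(I + dI) - F(I)) / dI` for the `qsig_high` family, the numerical
#' stand-in for its derivative at the peak where no closed form exists.
#' Shrinking `dI` toward 0 at `I = beta` probes the one-sided slope; for
#' moderate `q` the quotient's magnitude decays to 0.
#'
#' @param I Numeric vector of intensities.
#' @param dI Positive step size.
#' @param p A [transform_params()] resolving to `qsig_high` (or its
#'   `q = 1` limit).
#' @return Numeric vector of forward difference quotients.
#' @examples
#' p <- transform_params(beta = 128, alpha = 30, q = 1.5)
#' difference_quotient_d(128, 0.01, p)
#' @export
difference_quotient_d <- function(I, dI, p) {
  stopifnot(inherits(p, "transform_params"))
  if (!is.numeric(dI) || length(dI) != 1L || !is.finite(dI) || dI <= 0)
    stop("`dI` must be a single positive number")
  (q_sigmoid_high(I + dI, p) - q_sigmoid_high(I, p)) / dI
}
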