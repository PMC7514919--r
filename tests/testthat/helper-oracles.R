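# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain arithmetic, naive loops, shift-based
# morphology.

# central finite difference of a scalar function
central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)

# binary 3x3 dilation by explicit shifts (outside treated as FALSE)
shift_dilate <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    shifted <- matrix(FALSE, nr, nc)
    rr <- seq_len(nr) - dr; cc <- seq_len(nc) - dc
    vr <- rr >= 1 & rr <= nr; vc <- cc >= 1 & cc <= nc
    shifted[vr, vc] <- m[rr[vr], cc[vc]]
    out <- out | shifted
  }
  out
}

# exhaustive Otsu: for every candidate split of the binned histogram,
# compute the two class weights/means directly and maximize the
# between-class variance; first (lowest) maximizer wins.
brute_otsu_bin <- function(values, L, nbins = 256) {
  b <- pmin(floor(values / L * (nbins - 1)), nbins - 1)
  best <- -Inf; kbest <- NA_integer_
  for (k in 1:(nbins - 1)) {
    lo <- b[b < k]; hi <- b[b >= k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(b); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best + 1e-12) { best <- v; kbest <- k }
  }
  kbest
}

# shoelace polygon area from an explicit vertex list
shoelace <- function(x, y) {
  n <- length(x); j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

default_p <- function(q = 1, beta = 128, alpha = 30, lam = 1, ...) {
  transform_params(beta = beta, alpha = alpha, lam = lam, q = q, ...)
}
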