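test_that("q-exponential matches its closed forms, cutoff and classical limit", {
  expect_equal(q_exp(0, 0.5), 1)
  expect_equal(q_exp(1, 0.5), 2.25)           # (1 + 0.5)^2
  expect_equal(q_exp(-3, 0.5), 0)             # base 1 - 1.5 < 0: cutoff
  expect_equal(q_exp(1, 1), exp(1))
  expect_equal(q_exp(1, 1 + 1e-12), exp(1))   # near-1 indices use exp()
  # vectorized, mixed branches
  expect_equal(q_exp(c(-3, 0, 1), 0.5), c(0, 1, 2.25))
  expect_error(q_exp(Inf, 0.5), "finite")
  expect_error(q_exp(1, -0.1), ">= 0")
})

test_that("each family takes its frozen reference values", {
  expect_equal(sigmoid_i1(143, default_p()), 2 / (1 + exp(0.5)))
  expect_equal(sigmoid_i1(128, default_p()), 1)
  expect_lt(sigmoid_i1(128 + 1e6 * 30, default_p()), 1e-12)

  expect_equal(modified_sigmoid_i2(128, default_p()), 1)
  expect_equal(modified_sigmoid_i2(158, default_p()), 1 / (1 + exp(-1)))
  expect_equal(modified_sigmoid_i2(128 + 1e6 * 30, default_p()), 0.5,
               tolerance = 1e-5)

  expect_equal(q_sigmoid_low(143, default_p(q = 0.5)), 2 / (1 + 1.25^2))
  expect_equal(q_sigmoid_low(128, default_p(q = 0.5)), 1)

  expect_equal(q_sigmoid_high(158, default_p(q = 1.5)), 1 / (1 + 1.5^-2))
  expect_equal(q_sigmoid_high(128, default_p(q = 1.5)), 1)
  # the 1/2 background asymptote
  expect_equal(q_sigmoid_high(128 + 1e5 * 30, default_p(q = 1.5)), 0.5,
               tolerance = 1e-3)
})

test_that("every family peaks at exactly 1 at beta, stays in [0,1], and is symmetric", {
  set.seed(42)
  grid_d <- c(0.01, 0.5, 2, 7.3, 30, 95, 400)
  for (i in 1:20) {
    beta <- runif(1, 0, 255); alpha <- runif(1, 0.5, 60)
    lam <- runif(1, 0.1, 3)
    q <- sample(c(runif(1, 0.05, 0.95), 1, runif(1, 1.05, 3)), 1)
    fam <- if (abs(q - 1) < 1e-9) sample(c("sigmoid", "modified_sigmoid"), 1)
           else if (q < 1) "qsig_low" else "qsig_high"
    p <- transform_params(beta, alpha, lam, q, family = fam)
    f <- function(I) eval_transform(I, p)
    expect_identical(f(beta), 1)
    vals <- f(beta + grid_d)
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(f(beta + grid_d), f(beta - grid_d), tolerance = 1e-12)
    # decreasing in |I - beta|; ties are possible where the values saturate
    # at double precision (flat peak, far-tail asymptote)
    expect_true(all(diff(vals) <= 0))
    expect_lt(vals[length(vals)], vals[1])
  }
})

test_that("q-sigmoids converge to the classical sigmoids as q -> 1", {
  I <- seq(0, 255, length.out = 256)
  lo <- q_sigmoid_low(I, default_p(q = 0.999))
  hi <- q_sigmoid_high(I, default_p(q = 1.001))
  expect_lt(max(abs(lo - sigmoid_i1(I, default_p()))), 5e-3)
  expect_lt(max(abs(hi - modified_sigmoid_i2(I, default_p()))), 5e-3)
  # at q = 1 exactly, both dispatch to the classical closed forms
  expect_identical(q_sigmoid_low(I, default_p(q = 1, family = "qsig_low")),
                   sigmoid_i1(I, default_p()))
  expect_identical(q_sigmoid_high(I, default_p(q = 1, family = "qsig_high")),
                   modified_sigmoid_i2(I, default_p()))
})

test_that("the low-q family is ordered in q and dominates the sigmoid", {
  I <- c(100, 120, 135, 150, 200, 255)
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9, 1)
  vals <- sapply(qs, function(q) q_sigmoid_low(I, default_p(q = q)))
  # non-increasing in q at every intensity, and >= the classical sigmoid
  expect_true(all(apply(vals, 1, diff) <= 1e-14))
  expect_true(all(vals >= matrix(sigmoid_i1(I, default_p()),
                                 length(I), length(qs)) - 1e-14))
})

test_that("out-of-intent q ranges are rejected unless extended", {
  expect_error(q_sigmoid_low(100, default_p(q = 1.5, family = "qsig_low")),
               "extend")
  expect_error(transform_params(128, 30, 1, 0.5, family = "qsig_high"),
               "extend")
  # extension semantics: qsig_low cutoff region -> 0
  p <- transform_params(128, 30, 1, 2, family = "qsig_low", extend = TRUE)
  far <- 128 + 10 * 30   # base 1 - u = -9 <= 0
  expect_identical(q_sigmoid_low(far, p), 0)
  expect_equal(q_sigmoid_low(128, p), 1)
  # qsig_high with q < 1: literal cutoff near beta gives value 1
  p2 <- transform_params(128, 30, 1, 0.5, family = "qsig_high", extend = TRUE)
  near <- 128 + 30 * 0.4          # base 1 - 0.5/0.4 < 0
  expect_identical(q_sigmoid_high(near, p2), 1)
  far2 <- 128 + 30 * 10           # base 1 - 0.5/10 > 0
  expect_lt(q_sigmoid_high(far2, p2), 1)
})

test_that("auto dispatch resolves by q and validates parameters", {
  expect_identical(resolve_family(transform_params(1, 0.03, q = 0.7)), "qsig_low")
  expect_identical(resolve_family(transform_params(1, 0.03, q = 1.2)), "qsig_high")
  expect_identical(resolve_family(transform_params(1, 0.03, q = 1)), "sigmoid")
  expect_error(transform_params(1, -0.1), "alpha")
  expect_error(transform_params(1, 0.1, lam = 0), "lam")
  expect_error(transform_params(1, 0.1, q = -1), "q")
  expect_error(sigmoid_i1(NaN, default_p()), "finite")
})

test_that("apply_transform maps whole images and preserves shape", {
  p <- transform_params(0.5, 0.1, q = 0.7)
  const <- gray_image(matrix(0.5, 3, 4))
  expect_equal(as.matrix(apply_transform(const, p)),
               matrix(1, 3, 4))
  one <- apply_transform(gray_image(matrix(0.2, 1, 1)), p)
  expect_identical(dim(one), c(1L, 1L))
  # phantom: all outputs in [0,1], maximum at the phantom center
  img <- gaussian_scene()
  out <- apply_transform(img, transform_params(1.0, 0.03, q = 0.5))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(which.max(as.matrix(out)),
                   which.max(as.matrix(img)))
  expect_identical(attr(out, "family"), "qsig_low")
  # rescale flag restores the input ceiling
  img8 <- gray_image(matrix(c(0, 64, 128, 255), 2, 2), ceiling = 255)
  out8 <- apply_transform(img8, transform_params(128, 30), rescale = TRUE)
  expect_equal(img_ceiling(out8), 255)
  expect_equal(max(out8), 255)   # the beta = 128 pixel maps to the ceiling
})

test_that("fractional logistic has its minimum, tails and classical limit", {
  expect_equal(fractional_logistic(128, 1, 1, 0.05, 2, 128), 0.5)  # Dmax/(1+C)
  expect_equal(fractional_logistic(128 + 1e6, 1, 1, 0.05, 2, 128), 1,
               tolerance = 1e-9)
  expect_equal(fractional_logistic(128 - 1e6, 2.5, 1, 0.05, 2, 128), 2.5,
               tolerance = 1e-8)
  I <- seq(0, 255, by = 5)
  expect_equal(fractional_logistic(I, 1, 2, 0.05, 2, 128, q = 1),
               1 / (1 + 2 * exp(-0.05 * (I - 128)^2)), tolerance = 1e-12)
  # q-deformed variant agrees with the q-exponential substitution
  expect_equal(fractional_logistic(150, 1, 2, 0.05, 2, 128, q = 0.7),
               1 / (1 + 2 * q_exp(-0.05 * 22^2, 0.7)), tolerance = 1e-12)
  expect_error(fractional_logistic(1, 1, 1, 0.05, b = 3.5, I0 = 0), "b")
  expect_error(fractional_logistic(1, -1, 1, 0.05, 2, 0), "Dmax")
})
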