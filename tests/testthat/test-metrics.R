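test_that("region extraction thresholds by family default and finds components", {
  ones <- gray_image(matrix(1, 4, 4))
  zeros <- gray_image(matrix(0, 4, 4))
  expect_true(all(extract_region(ones, 0.5)))
  expect_false(any(extract_region(zeros, 0.5)))
  # family-recorded defaults: 0.5 for 0-background, 0.75 for 1/2-background
  img <- gaussian_scene()
  lo <- apply_transform(img, transform_params(1, 0.03, q = 0.5))
  hi <- apply_transform(img, transform_params(1, 0.03, q = 1.5))
  expect_identical(default_threshold(attr(lo, "family")), 0.5)
  expect_identical(default_threshold(attr(hi, "family")), 0.75)
  expect_identical(as.logical(extract_region(lo)),
                   as.logical(as.matrix(lo) >= 0.5))
  # the transformed phantom yields one connected blob containing the center
  m <- extract_region(lo)
  mc <- extract_region(lo, largest_component = TRUE)
  expect_identical(as.logical(m), as.logical(mc))  # already one component
  expect_true(mc[175, 175])
  # largest_component keeps only the bigger of two blobs
  v <- matrix(0, 10, 10); v[1:2, 1:2] <- 1; v[6:9, 6:9] <- 1
  keep <- extract_region(gray_image(v), 0.5, largest_component = TRUE)
  expect_identical(sum(keep), 16L)
  expect_true(keep[7, 7]); expect_false(keep[1, 1])
})

test_that("convex hull area follows the shoelace oracle and is monotone", {
  expect_identical(convex_hull_area(matrix(FALSE, 5, 5)), 0)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_identical(convex_hull_area(single), 0)
  coll <- matrix(FALSE, 9, 9); coll[5, 2:8] <- TRUE     # collinear
  expect_identical(convex_hull_area(coll), 0)
  tri <- matrix(FALSE, 12, 12)
  tri[1, 1] <- tri[1, 11] <- tri[11, 1] <- TRUE
  expect_equal(convex_hull_area(tri), 50)               # right triangle
  sq <- matrix(FALSE, 12, 12); sq[1:11, 1:11] <- TRUE
  expect_equal(convex_hull_area(sq), 100)               # hull of centers 10x10
  # random masks: never below the area of any subset; matches shoelace
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.2, 20, 20)
    sub <- m & (matrix(runif(400), 20, 20) < 0.5)
    expect_gte(convex_hull_area(m), convex_hull_area(sub))
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx) >= 3) {
      h <- grDevices::chull(idx[, 2], idx[, 1])
      expect_equal(convex_hull_area(m), shoelace(idx[h, 2], idx[h, 1]))
    }
  }
})

test_that("Err obeys its identities and stays unclamped", {
  g <- ground_truth_mask(gaussian_scene_spec(), k = 1)
  expect_identical(err_measure(g, g), 0)
  empty <- region_mask(matrix(FALSE, 256, 256))
  expect_identical(err_measure(empty, g), 1)
  # half-truth hull: three points spanning half the square's area
  truth <- matrix(FALSE, 21, 21)
  truth[1, 1] <- truth[1, 21] <- truth[21, 1] <- truth[21, 21] <- TRUE
  ach <- matrix(FALSE, 21, 21)
  ach[1, 1] <- ach[1, 21] <- ach[21, 1] <- TRUE
  expect_equal(err_measure(ach, truth), 0.5)
  # bigger achieved hull -> negative error (not clamped)
  expect_lt(err_measure(truth, region_mask(ach)), 0)
  expect_error(err_measure(g, empty), "zero")
  # pixel-count variant for sensitivity checks
  expect_equal(err_measure(ach, truth, method = "count"), 0.25)
})

test_that("AMBE is the absolute mean difference, symmetric, zero on identity", {
  img <- gaussian_scene()
  expect_identical(ambe(img, img), 0)
  shifted <- gray_image(pmin(as.matrix(img) / 2 + 0.25, 1))
  expect_equal(ambe(img, shifted), ambe(shifted, img))
  # unclipped constant shift
  a <- matrix(runif(100, 0.2, 0.5), 10, 10)
  expect_equal(ambe(a, a + 0.3), 0.3, tolerance = 1e-12)
  expect_error(ambe(a, matrix(0, 5, 5)), "dimensions")
})

test_that("3x3 dilation matches the shift oracle and is extensive", {
  empty <- matrix(FALSE, 6, 6)
  expect_false(any(dilate_mask(empty)))
  one <- matrix(FALSE, 7, 7); one[4, 4] <- TRUE
  d1 <- dilate_mask(one)
  expect_identical(sum(d1), 9L)
  expect_true(all(d1[3:5, 3:5]))
  set.seed(21)
  for (i in 1:8) {
    m <- matrix(runif(15 * 13) < 0.25, 15, 13)
    d <- dilate_mask(m)
    expect_identical(as.logical(d), as.logical(shift_dilate(m)))
    expect_true(all(d[m]))  # mask contained in its dilation
  }
  # border pixels dilate without wrapping
  corner <- matrix(FALSE, 5, 5); corner[1, 1] <- TRUE
  expect_identical(sum(dilate_mask(corner)), 4L)
})

test_that("similarity S hits its identities and penalizes ring overlap", {
  G <- matrix(FALSE, 30, 30); G[10:20, 10:20] <- TRUE
  G <- region_mask(G)
  expect_identical(similarity_s(G, G), 1)
  expect_identical(similarity_s(matrix(FALSE, 30, 30), G), 0.5)
  # full-raster segmentation: Jaccard #G/#raster, ring term 0
  full <- matrix(TRUE, 30, 30)
  expect_equal(similarity_s(full, G), 0.5 * sum(G) / 900)
  # adding ring pixels to a perfect segmentation lowers S
  ring <- dilate_mask(G) & !G
  withring <- G | ring
  expect_lt(similarity_s(withring, G), 1)
  expect_error(similarity_s(G, matrix(FALSE, 30, 30)), "empty")
  expect_error(similarity_s(G, matrix(TRUE, 30, 30)), "ring")
  expect_error(similarity_s(G, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("metric records serialize their provenance", {
  r <- metric_record("Err", 0.25, params = list(alpha = 0.03, q = 0.7),
                     source = "phantom")
  expect_identical(r$name, "Err")
  expect_identical(r$params, "alpha=0.03;q=0.7")
  expect_identical(nrow(r), 1L)
})
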