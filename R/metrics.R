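#' Extract the achieved region from a transformed image
#'
#' Thresholds a (typically transformed) image at `threshold` and
#' optionally keeps only the largest 8-connected component. When
#' `threshold` is `NULL` it defaults by the transform family recorded on
#' the image: 0.5 for families whose background tends to 0 (`sigmoid`,
#' `qsig_low`) and 0.75 for families whose background tends to 1/2
#' (`modified_sigmoid`, `qsig_high`); images with no recorded family
#' default to 0.5. An empty mask is a valid result.
#'
#' @param img A [gray_image()] or numeric matrix, on the transform
#'   codomain `[0, 1]`.
#' @param threshold Threshold in `(0, 1)`, or `NULL` for the family
#'   default.
#' @param largest_component Keep only the largest 8-connected component
#'   (default `FALSE`).
#' @return A [region_mask()].
#' @examples
#' out <- apply_transform(gaussian_scene(), transform_params(1, 0.03))
#' m <- extract_region(out)
#' @export
extract_region <- function(img, threshold = NULL, largest_component = FALSE) {
  if (is.null(threshold)) threshold <- default_threshold(attr(img, "family"))
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  m <- if (inherits(img, "gray_image")) as.matrix(img) else img
  mask <- m >= threshold
  if (isTRUE(largest_component) && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  region_mask(matrix(mask, nrow(m), ncol(m)))
}

#' Default extraction threshold for a transform family
#'
#' @param family Family name as recorded by [apply_transform()], or
#'   `NULL`.
#' @return 0.75 for the 1/2-background families, otherwise 0.5.
#' @export
default_threshold <- function(family = NULL) {
  if (!is.null(family) && family %in% c("modified_sigmoid", "qsig_high"))
    0.75
  else 0.5
}

#' Convex-hull area of a mask
#'
#' Area (in squared pixels) of the convex hull of the centers of all set
#' pixels, computed from the hull polygon by the shoelace formula. Empty
#' masks, single pixels and collinear pixel sets have area 0. The area
#' is monotone under mask inclusion.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @return Hull area `>= 0`.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[1:11, 1:11] <- TRUE
#' convex_hull_area(m)  # hull of centers spans 10 x 10
#' @export
convex_hull_area <- function(mask) {
  mask <- as_mask_matrix(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) return(0)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  x <- idx[h, 2]; y <- idx[h, 1]
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex-hull region error
#'
#' `Err = 1 - A1 / A0`, where `A1` and `A0` are the convex-hull areas of
#' the achieved and ground-truth regions. 0 is optimal; the value is not
#' clamped, so an achieved hull larger than the truth hull gives a
#' negative error, and an empty achieved region gives 1.
#'
#' @param achieved,truth [region_mask()] objects of the same shape.
#' @param method `"hull"` (polygon area, default) or `"count"` (pixel
#'   count, for sensitivity checks).
#' @return The error value (`<= 1`, possibly negative).
#' @examples
#' g <- ground_truth_mask(gaussian_scene_spec(), k = 1)
#' err_measure(g, g)  # 0
#' @export
err_measure <- function(achieved, truth, method = c("hull", "count")) {
  method <- match.arg(method)
  achieved <- as_mask_matrix(achieved); truth <- as_mask_matrix(truth)
  check_same_shape(achieved, truth)
  area <- if (method == "hull") convex_hull_area else function(m) sum(m)
  A0 <- area(truth)
  if (A0 <= 0) stop("ground-truth area is zero; Err undefined")
  1 - area(achieved) / A0
}

#' Absolute mean brightness error
#'
#' `AMBE = |mean(X) - mean(Y)|` between two images on the same intensity
#' scale; symmetric in its arguments. Lower values mean the enhancement
#' preserved the global brightness better.
#'
#' @param X,Y [gray_image()] objects or numeric matrices of identical
#'   shape.
#' @return A non-negative scalar.
#' @examples
#' img <- gaussian_scene()
#' ambe(img, img)  # 0
#' @export
ambe <- function(X, Y) {
  Xm <- if (inherits(X, "gray_image")) as.matrix(X) else X
  Ym <- if (inherits(Y, "gray_image")) as.matrix(Y) else Y
  check_same_shape(Xm, Ym)
  abs(mean(Xm) - mean(Ym))
}

#' Binary dilation by the 3x3 square structuring element
#'
#' Morphological dilation of a mask by the canonical full 3x3 brush;
#' pixels outside the raster are treated as background. The result
#' always contains the input mask.
#'
#' @param mask A [region_mask()] or logical matrix.
#' @return The dilated [region_mask()].
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(dilate_mask(m))  # the 3x3 neighborhood
#' @export
dilate_mask <- function(mask) {
  mask <- as_mask_matrix(mask)
  if (!any(mask)) return(region_mask(mask))
  # pad so EBImage's border handling cannot wrap mass into the frame
  pad <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  d <- EBImage::dilate(pad, EBImage::makeBrush(3, shape = "box"))
  region_mask(matrix(d[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] > 0,
                     nrow(mask), ncol(mask)))
}

#' Dilation-ring segmentation similarity
#'
#' `S(A, G) = 1/2 [ #(A & G) / #(A | G) + #(ring & !A) / #ring ]`, the
#' mean of the Jaccard index between a segmentation `A` and ground truth
#' `G` and the fraction of the one-pixel outer ring of `G` (its 3x3
#' dilation minus itself) left uncovered by `A`. The ring term is 1 when
#' the segmentation isolates the region of interest from its
#' surroundings and penalizes segmentations that bridge across the
#' region's border.
#'
#' @param A Segmentation [region_mask()].
#' @param G Non-empty ground-truth [region_mask()] whose dilation ring is
#'   non-empty (i.e. `G` does not fill the raster).
#' @return Similarity in `[0, 1]`; 1 iff `A` equals `G`.
#' @examples
#' g <- ground_truth_mask(gaussian_scene_spec(), k = 1)
#' similarity_s(g, g)  # 1
#' @export
similarity_s <- function(A, G) {
  A <- as_mask_matrix(A); G <- as_mask_matrix(G)
  check_same_shape(A, G)
  if (!any(G)) stop("ground truth is empty; similarity undefined")
  ring <- as_mask_matrix(dilate_mask(G)) & !G
  if (!any(ring))
    stop("ground truth fills the raster (empty dilation ring); similarity undefined")
  jac <- if (any(A | G)) sum(A & G) / sum(A | G) else 0
  (jac + sum(ring & !A) / sum(ring)) / 2
}

#' Named metric record
#'
#' A row-wise record of a computed statistic with the parameters and
#' provenance that produced it, the unit all experiment runners emit.
#'
#' @param name Statistic name (`"Err"`, `"AMBE"`, `"S"`, ...).
#' @param value Numeric value.
#' @param params Named list (or string) of the producing configuration.
#' @param source Fixture or file identifier.
#' @return A one-row `data.frame` with columns `name`, `value`,
#'   `params`, `source`.
#' @export
metric_record <- function(name, value, params = list(), source = "") {
  if (is.list(params))
    params <- paste(names(params), unlist(params), sep = "=", collapse = ";")
  data.frame(name = name, value = as.numeric(value),
             params = as.character(params), source = as.character(source),
             stringsAsFactors = FALSE)
}
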