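#' Err grid over transform scale and entropic index
#'
#' The phantom enhancement study: for every `(alpha, q)` cell, build the
#' Gaussian phantom, apply the dispatched transform family
#' (`beta`/`lam` fixed), threshold the output into an achieved region,
#' and score it against the phantom's ground-truth disc with
#' [err_measure()]. Cells are evaluated in the order given; a failing
#' cell records `NA` and an error message instead of aborting the grid.
#'
#' With the default `family = "auto"` dispatch, `q < 1` uses the
#' heavy-tailed family and `q > 1` the 1/2-background family, matching
#' how the study conditions pair the two deformations with their index
#' ranges.
#'
#' @param alphas Numeric vector of scale values.
#' @param qs Numeric vector of entropic indices.
#' @param beta,lam Fixed target intensity and gain (defaults 1.0, 1.0).
#' @param family Family passed to [transform_params()] (default
#'   `"auto"`).
#' @param spec Phantom geometry, a [gaussian_scene_spec()].
#' @param k Ground-truth disc radius in spread units (default 3).
#' @param threshold Extraction threshold, or `NULL` for the per-family
#'   default of [default_threshold()].
#' @param largest_component Restrict the achieved region to its largest
#'   connected component (default `FALSE`).
#' @return A `data.frame` with one row per cell: `alpha`, `q`, `family`
#'   (resolved), `threshold`, `err`, `error_message`.
#' @examples
#' g <- run_err_grid(alphas = 0.03, qs = c(0.7, 1))
#' g$err
#' @export
run_err_grid <- function(alphas, qs, beta = 1.0, lam = 1.0, family = "auto",
                         spec = gaussian_scene_spec(), k = 3,
                         threshold = NULL, largest_component = FALSE) {
  stopifnot(length(alphas) >= 1, length(qs) >= 1)
  img <- gaussian_scene(spec)
  truth <- ground_truth_mask(spec, k = k)
  cells <- expand.grid(q = qs, alpha = alphas,
                       KEEP.OUT.ATTRS = FALSE)[, c("alpha", "q")]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    a <- cells$alpha[i]; q <- cells$q[i]
    out <- tryCatch({
      p <- transform_params(beta = beta, alpha = a, lam = lam, q = q,
                            family = family)
      tr <- apply_transform(img, p)
      t_used <- if (is.null(threshold))
        default_threshold(attr(tr, "family")) else threshold
      mask <- extract_region(tr, threshold = t_used,
                             largest_component = largest_component)
      list(fam = attr(tr, "family"), thr = t_used,
           err = err_measure(mask, truth), msg = "")
    }, error = function(e)
      list(fam = NA_character_, thr = NA_real_, err = NA_real_,
           msg = conditionMessage(e)))
    data.frame(alpha = a, q = q, family = out$fam, threshold = out$thr,
               err = out$err, error_message = out$msg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# evaluate one method config on one image
apply_method <- function(img, method) {
  stopifnot(is.list(method), !is.null(method$type))
  switch(method$type,
         identity = img,
         hist_eq = histogram_equalize(img),
         slicing = do.call(slicing, c(list(img), method$args %||% list())),
         transform = apply_transform(img, method$params,
                                     rescale = !is.null(method$rescale) &&
                                       method$rescale),
         stop("unknown method type: ", method$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch brightness-preservation comparison
#'
#' Applies each enhancement method to each image and records the
#' absolute mean brightness error against the input — the batch summary
#' behind box-plot comparisons of enhancers. Per-image failures are
#' recorded as `NA` rows and skipped in the summaries.
#'
#' Method configs are named lists:
#' `list(type = "identity")`, `list(type = "hist_eq")`,
#' `list(type = "slicing", args = list(...))`, or
#' `list(type = "transform", params = transform_params(...))`. AMBE for
#' transform methods compares on the transform codomain against the
#' input normalized to `[0, 1]`.
#'
#' @param images List of [gray_image()] objects.
#' @param methods Named list of method configs.
#' @return A list with `records` (a `data.frame`: `image`, `method`,
#'   `ambe`) and `summary` (per-method `mean` and `sd`).
#' @examples
#' imgs <- lapply(1:2, function(i) speckled_lesion_scene(seed = i)$image)
#' run_ambe_batch(imgs, list(id = list(type = "identity")))$summary
#' @export
run_ambe_batch <- function(images, methods) {
  stopifnot(length(images) >= 1, length(methods) >= 1)
  if (is.null(names(methods)) || any(names(methods) == ""))
    names(methods) <- paste0("method", seq_along(methods))
  rows <- list()
  for (i in seq_along(images)) {
    img <- as_gray_image(images[[i]])
    for (mn in names(methods)) {
      val <- tryCatch({
        out <- apply_method(img, methods[[mn]])
        ref <- img
        if (img_ceiling(out) != img_ceiling(ref)) {
          # compare on a common [0, 1] scale
          ref <- gray_image(as.matrix(ref) / img_ceiling(ref), 1)
          out <- gray_image(as.matrix(out) / img_ceiling(out), 1)
        }
        ambe(ref, out)
      }, error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, method = mn, ambe = val, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  ok <- !is.na(records$ambe)
  summ <- do.call(rbind, lapply(names(methods), function(mn) {
    v <- records$ambe[ok & records$method == mn]
    data.frame(method = mn, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(records = records, summary = summ)
}

#' Paired segmentation-similarity study on a noisy series
#'
#' For each `(image, truth)` pair, segments the raw image and the
#' q-sigmoid-preprocessed image with a pluggable segmenter (default:
#' Otsu foreground mask) and scores both against the ground truth with
#' [similarity_s()] — the paired comparison of segmentation quality with
#' and without transform preprocessing. Degenerate-mask errors are
#' recorded per item as `NA`.
#'
#' @param series A list with elements `image` (list of images) and
#'   either a shared `truth` mask or a list `truth` of per-image masks —
#'   the shape returned by [noisy_phantom_series()].
#' @param p [transform_params()] used for preprocessing.
#' @param segmenter Function mapping an image to a mask; the default
#'   thresholds with [otsu_threshold()].
#' @return A `data.frame` with one row per image: `image`, `snr` (if
#'   present in `series`), `s_raw`, `s_filtered`.
#' @examples
#' s <- noisy_phantom_series(n = 2, snr_min = 5, snr_max = 50, seed = 1)
#' run_noise_similarity(s, transform_params(1, 0.8, q = 0.1))
#' @export
run_noise_similarity <- function(series, p,
                                 segmenter = function(img)
                                   otsu_threshold(img)$mask) {
  stopifnot(is.list(series), !is.null(series$image), !is.null(series$truth))
  n <- length(series$image)
  shared_truth <- !is.list(series$truth) || inherits(series$truth, "region_mask")
  rows <- lapply(seq_len(n), function(i) {
    img <- as_gray_image(series$image[[i]])
    truth <- if (shared_truth) series$truth else series$truth[[i]]
    s_of <- function(x) tryCatch(similarity_s(segmenter(x), truth),
                                 error = function(e) NA_real_)
    data.frame(image = i,
               snr = if (!is.null(series$snr)) series$snr[i] else NA_real_,
               s_raw = s_of(img),
               s_filtered = s_of(apply_transform(img, p)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
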