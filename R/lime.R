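#' Partition an image into contiguous superpixels
#'
#' Produces the on/off units of the perturbation explainer: a regular block
#' partition whose blocks are spatially contiguous and cover every pixel.
#' The number of blocks is chosen close to `n_target` with an aspect ratio
#' matching the image, and always lies within `[n_target / 2, 2 * n_target]`.
#'
#' @param image an `H x W` matrix or `H x W x C` array.
#' @param n_target desired number of segments, >= 2.
#' @param seed accepted for interface stability; the block partition is
#'   fully deterministic.
#' @return A list of class `"superpixel_map"` with `labels` (`H x W`
#'   integer matrix of segment ids `0..n_segments-1`) and `n_segments`.
#' @export
segment_superpixels <- function(image, n_target, seed = 1L) {
  if (n_target < 2) stop("'n_target' must be >= 2", call. = FALSE)
  d <- dim(image)
  h <- d[1]; w <- d[2]
  if (is.null(h) || h < 1 || w < 1) stop("empty image", call. = FALSE)
  nr <- max(1L, as.integer(round(sqrt(n_target * h / w))))
  nc <- max(1L, as.integer(round(n_target / nr)))
  nr <- min(nr, as.integer(h)); nc <- min(nc, as.integer(w))
  while (nr * nc < ceiling(n_target / 2) && (nr < h || nc < w)) {
    if (nc < w) nc <- nc + 1L else nr <- nr + 1L
  }
  row_block <- resize_index(nr, h)   # contiguous block row of each pixel row
  col_block <- resize_index(nc, w)
  labels <- outer(row_block, col_block,
                  function(r, c) (r - 1L) * nc + (c - 1L))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, n_segments = as.integer(nr * nc)),
            class = "superpixel_map")
}

#' Explain one prediction with a local linear surrogate
#'
#' LIME-style perturbation analysis: segments of the image are switched off
#' at random (replaced by the per-channel image mean), the black-box
#' predictor is queried on each perturbed image, and a ridge regression of
#' the predictions on the binary on/off vectors — weighted by similarity to
#' the unperturbed image, `exp(-d^2 / kernel_width^2)` with `d` the cosine
#' distance to the all-on vector — yields one signed coefficient per
#' segment. Positive coefficients mark segments whose presence pushes the
#' prediction towards the positive (sick) class.
#'
#' @param image `H x W` matrix or `H x W x C` array in `[0, 1]`.
#' @param predictor function taking a list of images (same shape) and
#'   returning a numeric vector of probabilities in `[0, 1]`.
#' @param map a [segment_superpixels()] result for `image`.
#' @param n_samples number of perturbations, `>= n_segments + 1`.
#' @param kernel_width width of the exponential similarity kernel.
#' @param ridge L2 penalty of the surrogate (intercept unpenalized).
#' @param seed integer seed for the perturbation draw.
#' @param fill replacement for switched-off segments: `"mean"` for the
#'   per-channel image mean, or a number. For thermogram inputs a fill of
#'   0 means "tissue removed" (the background value after segmentation and
#'   scaling), which avoids introducing spurious gray blocks into the
#'   background.
#' @return An object of class `"lime_explanation"`: `segment_weights`
#'   (named by segment id), `intercept`, `r2` (weighted R-squared of the
#'   surrogate on its own perturbation sample), and the superpixel `map`.
#' @export
explain_instance <- function(image, predictor, map, n_samples = 150L,
                             kernel_width = 0.25, ridge = 1.0, seed = 1L,
                             fill = "mean") {
  stopifnot(inherits(map, "superpixel_map"))
  ns <- map$n_segments
  if (n_samples < ns + 1L)
    stop("'n_samples' must be at least n_segments + 1", call. = FALSE)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rbinom(n_samples * ns, 1L, 0.5), n_samples, ns)
  fill_img <- image
  if (identical(fill, "mean")) {
    if (length(dim(image)) == 3L) {
      for (c0 in seq_len(dim(image)[3]))
        fill_img[, , c0] <- mean(image[, , c0])
    } else {
      fill_img[] <- mean(image)
    }
  } else {
    stopifnot(is.numeric(fill), length(fill) == 1L)
    fill_img[] <- fill
  }
  fill <- fill_img
  seg_of_pixel <- as.vector(map$labels) + 1L
  make_perturbed <- function(z) {
    off_pixels <- !(z[seg_of_pixel] > 0)
    img <- image
    if (length(dim(image)) == 3L) {
      for (c0 in seq_len(dim(image)[3])) {
        plane <- img[, , c0]
        plane[off_pixels] <- fill[, , c0][off_pixels]
        img[, , c0] <- plane
      }
    } else {
      img[off_pixels] <- fill[off_pixels]
    }
    img
  }
  imgs <- lapply(seq_len(n_samples), function(i) make_perturbed(Z[i, ]))
  y <- predictor(imgs)
  if (!is.numeric(y) || length(y) != n_samples ||
      any(!is.finite(y)) || any(y < -1e-9) || any(y > 1 + 1e-9))
    stop("predictor must return one probability in [0, 1] per image",
         call. = FALSE)
  s <- rowSums(Z)
  cos_sim <- ifelse(s > 0, sqrt(s / ns), 0)
  d <- 1 - cos_sim
  wts <- exp(-d^2 / kernel_width^2)
  fit <- ridge_fit(Z, y, wts, ridge)
  sw <- fit$coef
  names(sw) <- as.character(seq_len(ns) - 1L)
  yhat <- fit$intercept + as.vector(Z %*% sw)
  ybar <- sum(wts * y) / sum(wts)
  ss_res <- sum(wts * (y - yhat)^2)
  ss_tot <- sum(wts * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(segment_weights = sw, intercept = fit$intercept, r2 = r2,
                 map = map, n_samples = n_samples,
                 kernel_width = kernel_width, ridge = ridge),
            class = "lime_explanation")
}

# weighted ridge regression with unpenalized intercept
ridge_fit <- function(X, y, w, lambda) {
  Xa <- cbind(1, X)
  P <- diag(c(0, rep(lambda, ncol(X))))
  A <- crossprod(Xa, Xa * w) + P
  b <- crossprod(Xa, w * y)
  beta <- solve(A, b)
  list(intercept = beta[1L], coef = beta[-1L])
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat(sprintf("<lime_explanation: %d segments, %d samples, surrogate R2 = %.4f>\n",
              x$map$n_segments, x$n_samples, x$r2))
  top <- top_segments(x, 3L)
  if (length(top))
    cat("  top segments:", paste(sprintf("%d (%+.4f)", top,
                                         x$segment_weights[as.character(top)]),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Segments most supporting the positive class
#'
#' @param explanation a [explain_instance()] result.
#' @param k number of segments requested.
#' @return Up to `min(k, number of positive-weight segments)` segment ids,
#'   ordered by descending weight; ties broken by lower id.
#' @export
top_segments <- function(explanation, k) {
  w <- explanation$segment_weights
  ids <- as.integer(names(w))
  pos <- w > 0
  ord <- order(-w[pos], ids[pos])
  utils::head(ids[pos][ord], k)
}

#' Binary mask of the top-k explanation segments
#'
#' @param explanation a [explain_instance()] result.
#' @param k number of segments, >= 1.
#' @return `H x W` logical matrix covering the union of the top-k
#'   positive-weight segments (empty if no segment has positive weight).
#' @export
explanation_mask <- function(explanation, k) {
  if (k < 1) stop("'k' must be >= 1", call. = FALSE)
  lab <- explanation$map$labels
  matrix(lab %in% top_segments(explanation, k), nrow(lab), ncol(lab))
}

#' Restrict a grid to the critical region of interest
#'
#' Intersects the grid's validity mask with the explanation's top-k segment
#' mask, carried from image coordinates back to grid coordinates by the
#' exact inverse of the nearest-neighbour resize used in
#' [preprocess_for_cnn()].
#'
#' @param grid the [thermogram] the explained image was derived from.
#' @param explanation a [explain_instance()] result.
#' @param k number of top segments to keep, >= 1.
#' @return The [thermogram] restricted to the critical ROI.
#' @export
critical_roi <- function(grid, explanation, k = 3L) {
  stopifnot(inherits(grid, "thermogram"))
  m_img <- explanation_mask(explanation, k)
  if (!any(m_img))
    stop_empty_segmentation("explanation has no positive-weight segments")
  gm <- resize_nearest(m_img, nrow(grid$values), ncol(grid$values))
  mask <- grid$mask & gm
  if (!any(mask))
    stop_empty_segmentation("critical ROI does not intersect the valid cells")
  thermogram(grid$values, mask = mask, meta = grid$meta)
}

#' Write an explanation overlay image
#'
#' Renders the image with segment boundaries in white and the top-k mask
#' tinted; weights can also be dumped as CSV.
#'
#' @param image the explained image (`H x W` or `H x W x C`, in `[0, 1]`).
#' @param explanation a [explain_instance()] result.
#' @param path output PNG path.
#' @param k number of top segments to highlight.
#' @return `path`, invisibly.
#' @export
write_explanation_overlay <- function(image, explanation, path, k = 3L) {
  lab <- explanation$map$labels
  h <- nrow(lab); w <- ncol(lab)
  img <- if (length(dim(image)) == 3L) image else {
    a <- array(0, c(h, w, 3L)); for (c0 in 1:3) a[, , c0] <- image; a
  }
  edge <- matrix(FALSE, h, w)
  edge[-1, ] <- edge[-1, ] | lab[-1, ] != lab[-h, ]
  edge[, -1] <- edge[, -1] | lab[, -1] != lab[, -w]
  m <- tryCatch(explanation_mask(explanation, k),
                error = function(e) matrix(FALSE, h, w))
  for (c0 in 1:3) {
    plane <- img[, , c0]
    if (c0 == 2) plane[m] <- pmin(plane[m] + 0.4, 1)
    plane[edge] <- 1
    img[, , c0] <- plane
  }
  write_image(img, path)
}

#' Write explanation weights as CSV
#' @param explanation a [explain_instance()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_explanation_weights <- function(explanation, path) {
  utils::write.csv(data.frame(segment_id = as.integer(names(explanation$segment_weights)),
                              weight = unname(explanation$segment_weights)),
                   path, row.names = FALSE)
  invisible(path)
}
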