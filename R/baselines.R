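#' Configuration of the classical baseline segmenters
#'
#' Four single-shot segmenters share the crop-to-mask contract of the
#' iterative annotator and serve as its comparison points: a fixed HSV band
#' threshold, Otsu's global binarization, an adaptive (local-mean)
#' threshold, and K-means clustering in HSV space. The raw binarizations
#' have no notion of vegetation, so for the last three the candidate class
#' whose mean hue is circularly closest to the centre of the fixed green
#' band is taken as foreground.
#'
#' @param method one of `"fixed_hsv"`, `"otsu"`, `"adaptive"`, `"kmeans"`.
#' @param fixed_band an [hsv_band()] (default H `[22, 85]`, S `[20, 255]`,
#'   V `[20, 240]`).
#' @param adaptive_block odd local-window side in pixels (default 31).
#' @param adaptive_offset constant subtracted from the local mean
#'   (default 5).
#' @param kmeans_k number of clusters (default 3).
#' @param seed RNG seed making K-means deterministic (default 1).
#' @return An object of class `baseline_config`.
#' @export
baseline_config <- function(method = c("fixed_hsv", "otsu", "adaptive", "kmeans"),
                            fixed_band = hsv_band(22, 85),
                            adaptive_block = 31, adaptive_offset = 5,
                            kmeans_k = 3, seed = 1) {
  method <- match.arg(method)
  if (adaptive_block < 3 || adaptive_block %% 2 == 0)
    stop("adaptive_block must be odd and >= 3")
  if (kmeans_k < 2) stop("kmeans_k must be >= 2")
  structure(list(method = method, fixed_band = fixed_band,
                 adaptive_block = as.integer(adaptive_block),
                 adaptive_offset = adaptive_offset,
                 kmeans_k = as.integer(kmeans_k), seed = as.integer(seed)),
            class = "baseline_config")
}

green_center_hue <- function(band) (band$h_low + band$h_high) / 2

# Circular distance between two hues on the 0-179 scale.
hue_circ_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Circular mean hue (0-179) of a pixel selection; NA when empty.
circular_mean_hue <- function(h, sel) {
  if (!any(sel)) return(NA_real_)
  ang <- h[sel] * 2 * pi / 180
  (atan2(mean(sin(ang)), mean(cos(ang))) * 180 / (2 * pi)) %% 180
}

# Choose between the two complementary pixel classes of a binarization:
# the class whose circular-mean hue is closest to green. A degenerate
# binarization (either class empty) yields an empty mask.
pick_green_class <- function(hsv, above, band) {
  if (!any(above) || all(above)) {
    message("degenerate binarization: returning an empty mask")
    return(matrix(FALSE, dim(hsv)[1], dim(hsv)[2]))
  }
  h <- hsv[, , 1]
  gc <- green_center_hue(band)
  d_above <- hue_circ_dist(circular_mean_hue(h, above), gc)
  d_below <- hue_circ_dist(circular_mean_hue(h, !above), gc)
  if (d_above <= d_below) above else !above
}

#' Fixed HSV band baseline
#'
#' A single-shot threshold at the full green band followed by morphological
#' refinement: identical to iteration 0 of the iterative annotator, without
#' the narrowing.
#'
#' @param crop RGB raster.
#' @param config a [baseline_config()].
#' @return logical mask matrix.
#' @export
segment_fixed_hsv <- function(crop, config = baseline_config("fixed_hsv")) {
  refine_mask(hue_band_mask(rgb_to_hsv(crop), config$fixed_band))
}

#' Otsu global threshold baseline
#'
#' Binarizes the crop's luminance at the threshold maximizing between-class
#' variance, then keeps the green-closest class. A constant-intensity crop
#' yields an empty mask.
#'
#' @inheritParams segment_fixed_hsv
#' @return logical mask matrix.
#' @export
segment_otsu <- function(crop, config = baseline_config("otsu")) {
  lum <- luminance(crop)
  if (diff(range(lum)) == 0) {
    message("constant-intensity crop: Otsu has no threshold, empty mask")
    return(matrix(FALSE, nrow(lum), ncol(lum)))
  }
  thr <- EBImage::otsu(EBImage::Image(lum / 255), range = c(0, 1),
                       levels = 256)
  pick_green_class(rgb_to_hsv(crop), lum / 255 > thr, config$fixed_band)
}

# Local mean with a block x block square window and replicate padding.
local_mean <- function(x, block) {
  r <- (block - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  xp <- x[pmin(pmax(seq_len(h + 2 * r) - r, 1), h),
          pmin(pmax(seq_len(w + 2 * r) - r, 1), w), drop = FALSE]
  cs <- rbind(0, apply(xp, 2, cumsum))
  colwin <- cs[(block + 1):(h + 2 * r + 1), , drop = FALSE] -
    cs[1:h, , drop = FALSE]
  cs2 <- cbind(0, t(apply(colwin, 1, cumsum)))
  rowwin <- cs2[, (block + 1):(w + 2 * r + 1), drop = FALSE] -
    cs2[, 1:w, drop = FALSE]
  rowwin / (block^2)
}

#' Adaptive (local mean) threshold baseline
#'
#' Each luminance pixel is compared with the mean over an
#' `adaptive_block`-sided window minus `adaptive_offset`; the green-closest
#' side of the binarization is the foreground. On a constant crop with a
#' positive offset every pixel exceeds its threshold, the binarization is
#' degenerate, and the mask is empty.
#'
#' @inheritParams segment_fixed_hsv
#' @return logical mask matrix.
#' @export
segment_adaptive <- function(crop, config = baseline_config("adaptive")) {
  lum <- luminance(crop)
  thr <- local_mean(lum, config$adaptive_block) - config$adaptive_offset
  pick_green_class(rgb_to_hsv(crop), lum > thr, config$fixed_band)
}

#' K-means clustering baseline
#'
#' Pixels are clustered in an HSV embedding (hue mapped to its angle's
#' cosine/sine to respect circularity, saturation and value scaled to
#' `[0, 1]`); the cluster whose centroid hue is closest to the green band
#' centre becomes the foreground. Deterministic for a given seed. When the
#' crop has fewer distinct colours than `kmeans_k`, k is reduced; a
#' single-colour crop forms one cluster covering the whole crop.
#'
#' @inheritParams segment_fixed_hsv
#' @return logical mask matrix.
#' @export
segment_kmeans <- function(crop, config = baseline_config("kmeans")) {
  hsv <- rgb_to_hsv(crop)
  ang <- hsv[, , 1] * 2 * pi / 180
  feats <- cbind(cos = as.vector(cos(ang)), sin = as.vector(sin(ang)),
                 s = as.vector(hsv[, , 2]) / 255,
                 v = as.vector(hsv[, , 3]) / 255)
  k <- min(config$kmeans_k, nrow(unique(feats)))
  if (k < 2) return(matrix(TRUE, nrow(hsv[, , 1]), ncol(hsv[, , 1])))
  km <- NULL
  while (is.null(km) && k >= 2) {
    km <- with_seed(config$seed, tryCatch(
      stats::kmeans(feats, centers = k, nstart = 3, iter.max = 50),
      error = function(e) NULL))
    if (is.null(km)) k <- k - 1L   # empty-cluster degeneracy: drop a cluster
  }
  if (is.null(km)) return(matrix(TRUE, dim(hsv)[1], dim(hsv)[2]))
  hue <- (atan2(km$centers[, "sin"], km$centers[, "cos"]) * 180 / (2 * pi)) %% 180
  best <- which.min(hue_circ_dist(hue, green_center_hue(config$fixed_band)))
  matrix(km$cluster == best, dim(hsv)[1], dim(hsv)[2])
}

#' Dispatch a baseline segmenter by configuration
#'
#' @inheritParams segment_fixed_hsv
#' @return logical mask matrix.
#' @export
segment_baseline <- function(crop, config) {
  switch(config$method,
         fixed_hsv = segment_fixed_hsv(crop, config),
         otsu = segment_otsu(crop, config),
         adaptive = segment_adaptive(crop, config),
         kmeans = segment_kmeans(crop, config),
         stop("unknown baseline method: ", config$method))
}
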