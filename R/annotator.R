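#' Parameters of the iterative hue-narrowing annotator
#'
#' The annotator thresholds a crop at a sequence of narrowing hue bands
#' `(h_start + i, h_top)`, `i = 0 .. n_bands - 1`, with fixed saturation and
#' value bounds, refines each mask morphologically, and scores the principal
#' contour of each band with the integral metric
#' `score = w_area * k_area + w_shape * k_shape`, where `k_area` is the
#' contour-area ratio between consecutive stored iterations and `k_shape`
#' the contour bounding-rectangle area over the crop area. The mask kept is
#' the last one before the first score drop exceeding `drop_fraction` of the
#' score range.
#'
#' @param h_start first lower hue bound (default 22).
#' @param h_top fixed upper hue bound (default 85).
#' @param n_bands number of narrowing steps (default 16, i.e. lower bounds
#'   22..37).
#' @param s_bounds,v_bounds closed saturation/value intervals
#'   (defaults `c(20, 255)` and `c(20, 240)`).
#' @param min_area minimum principal-contour area in pixels^2 (default 50);
#'   bands below it are skipped.
#' @param w_area,w_shape score weights, must sum to 1 (defaults 0.7 / 0.3).
#' @param drop_fraction significant-drop threshold as a fraction of the score
#'   range (default 0.2).
#' @param epsilon_factor Douglas-Peucker tolerance as a fraction of the
#'   contour perimeter (default 0.0015).
#' @return An object of class `annotator_params`.
#' @export
annotator_params <- function(h_start = 22, h_top = 85, n_bands = 16,
                             s_bounds = c(20, 255), v_bounds = c(20, 240),
                             min_area = 50, w_area = 0.7, w_shape = 0.3,
                             drop_fraction = 0.2, epsilon_factor = 0.0015) {
  if (abs(w_area + w_shape - 1) > 1e-9)
    stop("w_area + w_shape must equal 1")
  if (drop_fraction <= 0 || drop_fraction >= 1)
    stop("drop_fraction must lie in (0, 1)")
  if (n_bands < 1) stop("n_bands must be >= 1")
  if (h_start + n_bands - 1 > h_top)
    stop("narrowest band would be empty: h_start + n_bands - 1 must be <= h_top")
  structure(list(h_start = h_start, h_top = h_top, n_bands = as.integer(n_bands),
                 s_bounds = s_bounds, v_bounds = v_bounds,
                 min_area = min_area, w_area = w_area, w_shape = w_shape,
                 drop_fraction = drop_fraction,
                 epsilon_factor = epsilon_factor),
            class = "annotator_params")
}

#' Contour-area change coefficient
#'
#' Ratio of the principal contour area to the area at the previous stored
#' iteration; a sharp fall flags loss of object parts. The first stored
#' iteration has no predecessor and is defined as 1.
#'
#' @param area_now current contour area, pixels^2 (> 0).
#' @param area_prev previous stored contour area, or `NULL` at the first
#'   stored iteration.
#' @return `area_now / area_prev`, or 1 when `area_prev` is `NULL`.
#' @export
compute_k_area <- function(area_now, area_prev = NULL) {
  if (area_now <= 0) stop("area_now must be positive")
  if (is.null(area_prev)) return(1)
  if (area_prev <= 0) stop("area_prev must be positive")
  area_now / area_prev
}

#' Contour shape coefficient
#'
#' Area of the contour's tight bounding rectangle relative to the crop area.
#' Elongated structures (leaves) that vanish barely change the total contour
#' area but shrink this rectangle, which is what the coefficient detects.
#'
#' @param contour_rect `c(width, height)` of the contour's bounding
#'   rectangle, pixels.
#' @param crop_dims `c(width, height)` of the crop, pixels.
#' @return `(w_contour * h_contour) / (w * h)`.
#' @export
compute_k_shape <- function(contour_rect, crop_dims) {
  if (any(crop_dims <= 0)) stop("crop dimensions must be positive")
  if (any(contour_rect <= 0)) stop("contour rectangle must be positive")
  (contour_rect[1] * contour_rect[2]) / (crop_dims[1] * crop_dims[2])
}

#' Integral mask-quality score
#'
#' @param k_area,k_shape the two coefficients.
#' @param params an [annotator_params()] carrying the weights.
#' @return `w_area * k_area + w_shape * k_shape`.
#' @export
compute_score <- function(k_area, k_shape, params = annotator_params()) {
  params$w_area * k_area + params$w_shape * k_shape
}

#' Run the hue-narrowing iterations over a crop
#'
#' For each band `(h_start + i, h_top)` the crop is thresholded, refined
#' ([refine_mask()]) and its principal contour extracted. Bands with no
#' contour, or whose principal contour is smaller than `min_area`, are
#' skipped and do *not* update the predecessor area used by `k_area`.
#'
#' @param crop RGB raster.
#' @param params an [annotator_params()].
#' @return An object of class `segmentation_history`: an ordered list of
#'   records, each with `h_low`, `mask` (refined), `contour`, `area`,
#'   `k_area`, `k_shape` and `score`; empty when every band was skipped.
#' @export
build_history <- function(crop, params = annotator_params()) {
  assert_rgb(crop)
  hsv <- rgb_to_hsv(crop)
  crop_dims <- c(dim(crop)[2], dim(crop)[1])   # (width, height)
  records <- list()
  prev_area <- NULL
  for (i in seq_len(params$n_bands) - 1L) {
    band <- hsv_band(params$h_start + i, params$h_top,
                     params$s_bounds[1], params$s_bounds[2],
                     params$v_bounds[1], params$v_bounds[2])
    mask <- refine_mask(hue_band_mask(hsv, band))
    contour <- largest_contour(mask, min_area = params$min_area)
    if (is.null(contour)) next
    k_area <- compute_k_area(contour$area, prev_area)
    k_shape <- compute_k_shape(contour$rect[c("width", "height")], crop_dims)
    score <- compute_score(k_area, k_shape, params)
    prev_area <- contour$area
    records[[length(records) + 1L]] <- list(
      h_low = params$h_start + i, mask = mask, contour = contour,
      area = contour$area, k_area = k_area, k_shape = k_shape, score = score
    )
  }
  structure(list(records = records, params = params),
            class = "segmentation_history")
}

#' @export
length.segmentation_history <- function(x) length(x$records)

#' @export
as.data.frame.segmentation_history <- function(x, ...) {
  if (length(x$records) == 0)
    return(data.frame(h_low = integer(), area = numeric(),
                      k_area = numeric(), k_shape = numeric(),
                      score = numeric()))
  data.frame(
    h_low = vapply(x$records, `[[`, numeric(1), "h_low"),
    area = vapply(x$records, `[[`, numeric(1), "area"),
    k_area = vapply(x$records, `[[`, numeric(1), "k_area"),
    k_shape = vapply(x$records, `[[`, numeric(1), "k_shape"),
    score = vapply(x$records, `[[`, numeric(1), "score")
  )
}

#' @export
print.segmentation_history <- function(x, ...) {
  cat(sprintf("<segmentation_history: %d stored iterations>\n",
              length(x$records)))
  if (length(x$records)) print(as.data.frame(x))
  invisible(x)
}

#' @export
plot.segmentation_history <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0) stop("empty history: nothing to plot")
  graphics::plot(df$h_low, df$score, type = "b", pch = 19,
                 xlab = "lower hue bound", ylab = "integral score", ...)
  sel <- select_best_iteration(x)
  graphics::points(df$h_low[sel], df$score[sel], col = 2, cex = 2)
  invisible(x)
}

#' Select the mask before the first significant score drop
#'
#' Let `R` be the range (max - min) of the stored scores. Scanning
#' consecutive stored records, the first pair whose score decrease exceeds
#' `drop_fraction * R` marks segmentation degradation; the record *before*
#' that drop — the last stable iteration — is selected. When the scores are
#' constant (`R = 0`) or no such drop occurs, the last stored record (the
#' narrowest stable band) is selected.
#'
#' @param history a [build_history()] result.
#' @param drop_fraction fraction of the score range; defaults to the value
#'   carried in the history's parameters.
#' @return 1-based index into `history$records`.
#' @export
select_best_iteration <- function(history,
                                  drop_fraction = history$params$drop_fraction) {
  scores <- vapply(history$records, `[[`, numeric(1), "score")
  n <- length(scores)
  if (n == 0) stop("empty segmentation history: no annotation")
  r <- max(scores) - min(scores)
  if (r > 0) {
    for (j in seq_len(n)[-1]) {
      if (scores[j - 1] - scores[j] > drop_fraction * r) return(j - 1L)
    }
  }
  n
}

#' Annotate one bounding box with a contour
#'
#' The full per-box pipeline: crop, [build_history()],
#' [select_best_iteration()], then the principal contour of the selected
#' record's mask.
#'
#' @param image full RGB raster.
#' @param box a [labeled_box()].
#' @param params an [annotator_params()].
#' @return An object of class `gp_annotation` with fields `contour`
#'   (crop-local `gp_contour`), `index` (selected record), `history` and
#'   `box`; or `NULL` when no band produced a usable contour.
#' @export
annotate_box <- function(image, box, params = annotator_params()) {
  crop <- crop_region(image, box)
  history <- build_history(crop, params)
  if (length(history$records) == 0) return(NULL)
  idx <- select_best_iteration(history)
  contour <- largest_contour(history$records[[idx]]$mask,
                             min_area = params$min_area)
  structure(list(contour = contour, index = idx, history = history,
                 box = box),
            class = "gp_annotation")
}

#' @export
print.gp_annotation <- function(x, ...) {
  cat(sprintf("<annotation for '%s' box: iteration %d of %d (h_low %d), area %.0f px^2>\n",
              x$box$class_name, x$index, length(x$history$records),
              x$history$records[[x$index]]$h_low, x$contour$area))
  invisible(x)
}

#' Annotate every box of an image as simplified polygons
#'
#' Runs [annotate_box()] on each box, simplifies the contour with
#' [approximate_contour()] and maps vertices to full-image coordinates.
#' Boxes yielding no contour, or a polygon with fewer than 3 vertices after
#' simplification, are dropped.
#'
#' @param image full RGB raster.
#' @param ann an [annotated_image()] (its boxes are used).
#' @param params an [annotator_params()].
#' @param class_map named integer vector mapping class names to ids
#'   (default [read_class_map()]).
#' @return list of [polygon_annotation()] objects.
#' @export
annotate_image <- function(image, ann, params = annotator_params(),
                           class_map = read_class_map()) {
  dims <- c(dim(image)[2], dim(image)[1])
  out <- list()
  for (box in ann$boxes) {
    res <- annotate_box(image, box, params)
    if (is.null(res)) next
    verts <- approximate_contour(res$contour, params$epsilon_factor)
    if (is.null(verts)) next
    gl <- to_global_coords(verts, box, dims)
    cid <- class_map[[box$class_name]]
    if (is.null(cid)) cid <- -1L
    out[[length(out) + 1L]] <- polygon_annotation(cid, gl, dims)
  }
  out
}
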