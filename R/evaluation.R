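#' Intersection-over-union of two binary masks, in percent
#'
#' `100 * |A intersect M| / |A union M|`. Two empty masks are defined as
#' perfect agreement (100) with a warning; the situation never arises in
#' normal evaluation because reference masks are non-empty.
#'
#' @param auto,ref logical mask matrices of equal dimensions.
#' @return percent in `[0, 100]`.
#' @export
mask_iou <- function(auto, ref) {
  if (!identical(dim(auto), dim(ref)))
    stop("mask dimensions differ")
  inter <- sum(auto & ref)
  uni <- sum(auto | ref)
  if (uni == 0) {
    warning("both masks empty: agreement defined as 100")
    return(100)
  }
  100 * inter / uni
}

#' Dice similarity coefficient of two binary masks, in percent
#'
#' `100 * 2|A intersect M| / (|A| + |M|)`; per pair this equals
#' `2 IoU / (1 + IoU)` in fraction form.
#'
#' @inheritParams mask_iou
#' @return percent in `[0, 100]`.
#' @export
mask_dsc <- function(auto, ref) {
  if (!identical(dim(auto), dim(ref)))
    stop("mask dimensions differ")
  denom <- sum(auto) + sum(ref)
  if (denom == 0) {
    warning("both masks empty: agreement defined as 100")
    return(100)
  }
  100 * 2 * sum(auto & ref) / denom
}

#' Evaluate paired automatic and reference masks
#'
#' Per-pair IoU and DSC plus their arithmetic means across pairs.
#'
#' @param auto_masks,ref_masks equal-length lists of logical masks with
#'   pairwise equal dimensions.
#' @return An object of class `gp_eval`: `per_pair` (data frame with `iou`,
#'   `dsc` in percent), `mean_iou`, `mean_dsc`, `n`.
#' @export
evaluate_dataset <- function(auto_masks, ref_masks) {
  if (length(auto_masks) != length(ref_masks))
    stop("mask lists have different lengths")
  if (length(auto_masks) == 0) stop("nothing to evaluate")
  iou <- mapply(mask_iou, auto_masks, ref_masks)
  dsc <- mapply(mask_dsc, auto_masks, ref_masks)
  structure(list(per_pair = data.frame(iou = iou, dsc = dsc),
                 mean_iou = mean(iou), mean_dsc = mean(dsc),
                 n = length(iou)),
            class = "gp_eval")
}

#' @export
print.gp_eval <- function(x, ...) {
  cat(sprintf("<evaluation over %d mask pairs: mean IoU %.2f%%, mean DSC %.2f%%>\n",
              x$n, x$mean_iou, x$mean_dsc))
  invisible(x)
}

# Crop a full-image ground-truth mask to a box.
crop_mask <- function(mask, box) {
  mask[(box$y_min + 1L):box$y_max, (box$x_min + 1L):box$x_max, drop = FALSE]
}

# Automatic crop-local mask for one object: annotate, simplify, rasterize.
# An object with no usable contour or polygon yields an empty mask.
auto_object_mask <- function(image, box, params) {
  w <- box_width(box); h <- box_height(box)
  res <- annotate_box(image, box, params)
  if (is.null(res) || is.null(res$contour)) return(matrix(FALSE, h, w))
  verts <- approximate_contour(res$contour, params$epsilon_factor)
  if (is.null(verts)) return(matrix(FALSE, h, w))
  rasterize_polygon(verts, w, h)
}

#' Evaluate the iterative annotator over synthetic scenes
#'
#' For every object of every scene, runs the full pipeline (annotate,
#' simplify, rasterize) in crop coordinates and compares against the
#' scene's ground-truth mask cropped to the box.
#'
#' @param scenes list of scenes from [generate_scene()] (or [load_dataset()]).
#' @param params an [annotator_params()].
#' @return A `gp_eval`.
#' @export
evaluate_annotator <- function(scenes, params = annotator_params()) {
  auto <- list(); ref <- list()
  for (sc in scenes) {
    for (obj in sc$objects) {
      auto[[length(auto) + 1L]] <- auto_object_mask(sc$image, obj$box, params)
      ref[[length(ref) + 1L]] <- crop_mask(obj$mask, obj$box)
    }
  }
  evaluate_dataset(auto, ref)
}

#' Evaluate a baseline segmenter over synthetic scenes
#'
#' The baseline maps each object's crop directly to a mask (no
#' polygonization), compared against the ground truth cropped to the box.
#'
#' @param scenes list of scenes.
#' @param config a [baseline_config()].
#' @return A `gp_eval`.
#' @export
evaluate_baseline <- function(scenes, config) {
  auto <- list(); ref <- list()
  for (sc in scenes) {
    for (obj in sc$objects) {
      crop <- crop_region(sc$image, obj$box)
      auto[[length(auto) + 1L]] <- segment_baseline(crop, config)
      ref[[length(ref) + 1L]] <- crop_mask(obj$mask, obj$box)
    }
  }
  evaluate_dataset(auto, ref)
}

#' Default 11-pair weight grid
#'
#' `(w_area, w_shape)` from `(1.0, 0.0)` to `(0.0, 1.0)` in steps of 0.1.
#'
#' @return 11 x 2 matrix with columns `w_area`, `w_shape`.
#' @export
default_weight_grid <- function() {
  wa <- seq(1, 0, by = -0.1)
  cbind(w_area = wa, w_shape = 1 - wa)
}

#' Sweep the score weights over an evaluation set
#'
#' Re-runs the full annotator for every `(w_area, w_shape)` pair of the grid
#' and records the resulting mean IoU and DSC against the scenes' reference
#' masks — the experiment that justifies the default weights 0.7/0.3.
#'
#' @param scenes list of scenes with ground-truth masks.
#' @param weight_grid matrix/data frame with columns `w_area`, `w_shape`;
#'   each row must sum to 1 (default [default_weight_grid()]).
#' @param params base [annotator_params()]; only the weights vary.
#' @return data frame with columns `w_area`, `w_shape`, `mean_iou`,
#'   `mean_dsc`, one row per grid pair.
#' @export
weight_sweep <- function(scenes, weight_grid = default_weight_grid(),
                         params = annotator_params()) {
  weight_grid <- as.matrix(weight_grid)
  if (any(abs(rowSums(weight_grid) - 1) > 1e-9))
    stop("every weight pair must sum to 1")
  rows <- lapply(seq_len(nrow(weight_grid)), function(i) {
    p <- params
    p$w_area <- weight_grid[i, 1]
    p$w_shape <- weight_grid[i, 2]
    ev <- evaluate_annotator(scenes, p)
    data.frame(w_area = p$w_area, w_shape = p$w_shape,
               mean_iou = ev$mean_iou, mean_dsc = ev$mean_dsc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
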