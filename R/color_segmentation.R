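#' HSV channel band
#'
#' Closed per-channel intervals on the byte HSV scale (hue 0-179,
#' saturation/value 0-255). The default saturation/value bounds
#' `S [20, 255]`, `V [20, 240]` exclude near-achromatic pixels (soil glare,
#' deep shadow) while the hue bounds select the chromatic identity.
#'
#' @param h_low,h_high hue bounds, 0-179.
#' @param s_low,s_high saturation bounds, 0-255.
#' @param v_low,v_high value bounds, 0-255.
#' @return An object of class `hsv_band`.
#' @export
hsv_band <- function(h_low, h_high, s_low = 20, s_high = 255,
                     v_low = 20, v_high = 240) {
  chk <- function(lo, hi, top, what) {
    if (lo > hi || lo < 0 || hi > top)
      stop(sprintf("invalid %s bounds [%s, %s]", what, lo, hi))
  }
  chk(h_low, h_high, 179, "hue")
  chk(s_low, s_high, 255, "saturation")
  chk(v_low, v_high, 255, "value")
  structure(list(h_low = h_low, h_high = h_high, s_low = s_low,
                 s_high = s_high, v_low = v_low, v_high = v_high),
            class = "hsv_band")
}

#' Threshold an HSV raster against a band
#'
#' A pixel is foreground iff all three channels lie within their closed
#' bounds.
#'
#' @param hsv HSV raster from [rgb_to_hsv()].
#' @param band an [hsv_band()].
#' @return logical mask matrix of the raster's dimensions.
#' @export
hue_band_mask <- function(hsv, band) {
  h <- hsv[, , 1]; s <- hsv[, , 2]; v <- hsv[, , 3]
  h >= band$h_low & h <= band$h_high &
    s >= band$s_low & s <= band$s_high &
    v >= band$v_low & v <= band$v_high
}

morph_kernel <- function() EBImage::makeBrush(3, shape = "box")

#' Morphologically refine a binary mask
#'
#' Closing (3x3 square element, `close_iter` dilate/erode passes) restores
#' connectivity across small gaps and fills pinholes, then opening
#' (`open_iter` passes) removes speckle noise. Defaults: close twice, open
#' once.
#'
#' @param mask logical mask matrix.
#' @param close_iter,open_iter iteration counts.
#' @return logical mask of the same dimensions.
#' @export
refine_mask <- function(mask, close_iter = 2, open_iter = 1) {
  k <- morph_kernel()
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  for (i in seq_len(close_iter)) m <- EBImage::dilate(m, k)
  for (i in seq_len(close_iter)) m <- EBImage::erode(m, k)
  for (i in seq_len(open_iter)) m <- EBImage::erode(m, k)
  for (i in seq_len(open_iter)) m <- EBImage::dilate(m, k)
  m > 0.5
}

#' Build a contour object from an ordered point list
#'
#' Points are 0-based `(x, y)` crop-local coordinates of a closed boundary
#' (the closing edge from last to first point is implicit). `area` defaults
#' to the shoelace polygon area; [largest_contour()] overrides it with the
#' filled pixel count of the traced component.
#'
#' @param points n x 2 matrix of `(x, y)` coordinates.
#' @param area optional enclosed area override, in pixels^2.
#' @return An object of class `gp_contour` with fields `points`, `area`,
#'   `rect` (`c(x_min, y_min, width, height)`, pixel extents) and
#'   `perimeter`.
#' @export
as_contour <- function(points, area = NULL) {
  points <- matrix(as.numeric(points), ncol = 2,
                   dimnames = list(NULL, c("x", "y")))
  n <- nrow(points)
  if (n >= 2) {
    nxt <- c(2:n, 1)
    per <- sum(sqrt((points[nxt, 1] - points[, 1])^2 +
                    (points[nxt, 2] - points[, 2])^2))
    sho <- abs(sum(points[, 1] * points[nxt, 2] -
                   points[nxt, 1] * points[, 2])) / 2
  } else {
    per <- 0; sho <- 0
  }
  if (is.null(area)) area <- sho
  rect <- c(x_min = min(points[, 1]), y_min = min(points[, 2]),
            width = diff(range(points[, 1])) + 1,
            height = diff(range(points[, 2])) + 1)
  structure(list(points = points, area = area, rect = rect, perimeter = per),
            class = "gp_contour")
}

#' @export
print.gp_contour <- function(x, ...) {
  cat(sprintf("<contour: %d points, area %.0f px^2, rect %gx%g, perimeter %.1f>\n",
              nrow(x$points), x$area, x$rect["width"], x$rect["height"],
              x$perimeter))
  invisible(x)
}

#' Principal (largest) external contour of a mask
#'
#' Connected components are labelled, holes filled, and the component with
#' the largest filled area (the outer-silhouette area, counting hole pixels)
#' is traced. Ties are broken by label order, i.e. the component first
#' reached scanning columns left to right, top to bottom within a column.
#'
#' @param mask logical mask matrix.
#' @param min_area minimum filled area in pixels^2; smaller components yield
#'   `NULL` (absence is a value, not an error).
#' @return A `gp_contour` (points in 0-based crop-local `(x, y)`), or `NULL`
#'   when the mask has no component of sufficient area.
#' @export
largest_contour <- function(mask, min_area = 50) {
  if (min_area < 0) stop("min_area must be >= 0")
  if (!any(mask)) return(NULL)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  filled <- EBImage::fillHull(lab)
  areas <- tabulate(filled[filled > 0], nbins = max(lab))
  best <- which.max(areas)
  if (areas[best] < min_area) return(NULL)
  obj <- matrix(as.integer(filled == best), nrow(mask), ncol(mask))
  oc <- EBImage::ocontour(obj)[[1]]    # 0-based (row, col) boundary trace
  as_contour(cbind(x = oc[, 2], y = oc[, 1]), area = areas[best])
}

#' Fill the principal contour of a mask back into a mask
#'
#' Utility: the region (holes filled) of the component selected by
#' [largest_contour()], or an all-background mask when there is none.
#'
#' @inheritParams largest_contour
#' @return logical mask matrix.
#' @keywords internal
principal_region <- function(mask, min_area = 50) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!any(mask)) return(out)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  filled <- EBImage::fillHull(lab)
  areas <- tabulate(filled[filled > 0], nbins = max(lab))
  best <- which.max(areas)
  if (areas[best] < min_area) return(out)
  filled == best
}
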