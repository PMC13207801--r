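#' Polygon annotation in full-image coordinates
#'
#' A closed vertex list (the edge from the last vertex back to the first is
#' implicit) with an integer class id. Vertices are 0-based pixel
#' coordinates clamped to the image bounds.
#'
#' @param class_id integer class id.
#' @param vertices n x 2 matrix of `(x, y)` image coordinates, n >= 3.
#' @param image_dims `c(width, height)`.
#' @return An object of class `polygon_annotation`.
#' @export
polygon_annotation <- function(class_id, vertices, image_dims) {
  vertices <- matrix(as.numeric(vertices), ncol = 2,
                     dimnames = list(NULL, c("x", "y")))
  if (nrow(vertices) < 3) stop("a polygon needs at least 3 vertices")
  w <- image_dims[1]; h <- image_dims[2]
  if (any(vertices[, 1] < 0 | vertices[, 1] > w - 1 |
          vertices[, 2] < 0 | vertices[, 2] > h - 1))
    stop("polygon vertices outside image bounds")
  structure(list(class_id = as.integer(class_id), vertices = vertices,
                 image_dims = c(w, h)),
            class = "polygon_annotation")
}

#' @export
print.polygon_annotation <- function(x, ...) {
  cat(sprintf("<polygon_annotation class %d, %d vertices in %gx%g image>\n",
              x$class_id, nrow(x$vertices), x$image_dims[1], x$image_dims[2]))
  invisible(x)
}

# Squared distance from points (px, py) to the segment (x1,y1)-(x2,y2).
point_segment_dist <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / l2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Douglas-Peucker on an open chain (rows of pts); keeps both endpoints.
# Uses point-to-segment distance so every dropped point is within eps of the
# simplified polyline. Iterative (explicit stack) to avoid deep recursion.
dp_chain <- function(pts, eps) {
  n <- nrow(pts)
  keep <- rep(FALSE, n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    mid <- (i + 1):(j - 1)
    d <- point_segment_dist(pts[mid, 1], pts[mid, 2],
                            pts[i, 1], pts[i, 2], pts[j, 1], pts[j, 2])
    k <- mid[which.max(d)]
    if (max(d) > eps) {
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  pts[keep, , drop = FALSE]
}

#' Simplify a closed contour with Douglas-Peucker
#'
#' The tolerance is `epsilon = epsilon_factor * perimeter(contour)`. The
#' closed contour is split at its first point and the point farthest from
#' it, each half simplified independently, and the halves rejoined; every
#' original contour point then lies within `epsilon` of the returned closed
#' polygon. With `epsilon = 0` all points are retained.
#'
#' @param contour a `gp_contour` (or anything accepted by [as_contour()])
#'   with at least 3 points.
#' @param epsilon_factor tolerance as a fraction of the perimeter
#'   (default 0.0015).
#' @return n x 2 vertex matrix (closed implicitly), or `NULL` when fewer
#'   than 3 vertices survive — the caller should emit no annotation.
#' @export
approximate_contour <- function(contour, epsilon_factor = 0.0015) {
  if (!inherits(contour, "gp_contour")) contour <- as_contour(contour)
  pts <- contour$points
  n <- nrow(pts)
  if (n < 3) stop("contour must have at least 3 points")
  eps <- epsilon_factor * contour$perimeter
  if (eps <= 0) return(pts)
  d0 <- sqrt((pts[, 1] - pts[1, 1])^2 + (pts[, 2] - pts[1, 2])^2)
  split <- which.max(d0)
  if (d0[split] == 0) return(NULL)   # all points coincide
  half1 <- dp_chain(pts[1:split, , drop = FALSE], eps)
  half2 <- dp_chain(pts[c(split:n, 1), , drop = FALSE], eps)
  verts <- rbind(half1, half2[-1, , drop = FALSE])
  verts <- verts[-nrow(verts), , drop = FALSE]   # drop duplicated start
  if (nrow(verts) < 3) return(NULL)
  verts
}

#' Map crop-local vertices into full-image coordinates
#'
#' Each `(u, v)` becomes `(x_min + u, y_min + v)`, then coordinates are
#' clamped to `[0, width - 1] x [0, height - 1]` (boxes may abut image
#' edges in field imagery; clamping keeps such vertices rather than
#' rejecting the polygon).
#'
#' @param vertices n x 2 matrix of crop-local `(u, v)`.
#' @param box the [labeled_box()] the crop came from.
#' @param image_dims `c(width, height)` of the full image.
#' @return n x 2 matrix of image `(x, y)`.
#' @export
to_global_coords <- function(vertices, box, image_dims) {
  x <- pmin(pmax(vertices[, 1] + box$x_min, 0), image_dims[1] - 1)
  y <- pmin(pmax(vertices[, 2] + box$y_min, 0), image_dims[2] - 1)
  cbind(x = x, y = y)
}

#' Write YOLO segmentation label lines
#'
#' One line per annotation: the class id followed by the vertex sequence
#' normalized by image width/height, fixed 6-decimal precision. Annotations
#' with fewer than 3 vertices are skipped with a warning. An empty
#' annotation list yields an empty file.
#'
#' @param annotations list of [polygon_annotation()] objects.
#' @param image_dims `c(width, height)`; must be positive.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return character vector of label lines (invisibly when `path` is given).
#' @export
write_yolo_seg <- function(annotations, image_dims, path = NULL) {
  if (any(image_dims <= 0)) stop("image dimensions must be positive")
  w <- image_dims[1]; h <- image_dims[2]
  lines <- character(0)
  for (a in annotations) {
    if (nrow(a$vertices) < 3) {
      warning("skipping polygon with fewer than 3 vertices")
      next
    }
    coords <- as.vector(t(cbind(a$vertices[, 1] / w, a$vertices[, 2] / h)))
    lines <- c(lines, paste(a$class_id,
                            paste(sprintf("%.6f", coords), collapse = " ")))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse YOLO segmentation label lines
#'
#' Inverse of [write_yolo_seg()]: normalized coordinates are scaled back by
#' the image dimensions (round-trip is exact to the 6-decimal quantization,
#' i.e. well under one pixel).
#'
#' @param source path to a label file, or a character vector of lines.
#' @param image_dims `c(width, height)`.
#' @return list of [polygon_annotation()] objects.
#' @export
read_yolo_seg <- function(source, image_dims) {
  lines <- if (length(source) == 1 && file.exists(source)) readLines(source)
           else source
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    cid <- as.integer(f[1])
    xy <- matrix(f[-1], ncol = 2, byrow = TRUE)
    polygon_annotation(cid, cbind(xy[, 1] * image_dims[1],
                                  xy[, 2] * image_dims[2]), image_dims)
  })
}

# Pixels along the segment (x1,y1)-(x2,y2), rounded; used for outlines.
trace_segment <- function(x1, y1, x2, y2) {
  n <- max(abs(x2 - x1), abs(y2 - y1), 1)
  t <- seq(0, 1, length.out = ceiling(n) + 1)
  cbind(round(x1 + t * (x2 - x1)), round(y1 + t * (y2 - y1)))
}

#' Rasterize a closed polygon into a binary mask
#'
#' Even-odd scanline fill at integer scanlines plus the polygon outline, so
#' boundary pixels are foreground. Vertices are 0-based `(x, y)` pixel
#' coordinates (fractional allowed).
#'
#' @param vertices n x 2 vertex matrix (closed implicitly).
#' @param width,height mask dimensions in pixels.
#' @return logical mask matrix `[height, width]`.
#' @export
rasterize_polygon <- function(vertices, width, height) {
  mask <- matrix(FALSE, height, width)
  if (is.null(vertices) || nrow(vertices) < 3) return(mask)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  nxt <- c(2:n, 1)
  x1 <- vx; y1 <- vy; x2 <- vx[nxt]; y2 <- vy[nxt]
  for (row in 0:(height - 1)) {
    cross <- (y1 <= row & y2 > row) | (y2 <= row & y1 > row)
    if (!any(cross)) next
    xs <- sort(x1[cross] + (row - y1[cross]) *
                 (x2[cross] - x1[cross]) / (y2[cross] - y1[cross]))
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[k] - 1e-9); b <- floor(xs[k + 1] + 1e-9)
      a <- max(a, 0); b <- min(b, width - 1)
      if (a <= b) mask[row + 1, (a + 1):(b + 1)] <- TRUE
    }
  }
  for (i in seq_len(n)) {
    px <- trace_segment(x1[i], y1[i], x2[i], y2[i])
    px[, 1] <- pmin(pmax(px[, 1], 0), width - 1)
    px[, 2] <- pmin(pmax(px[, 2], 0), height - 1)
    mask[cbind(px[, 2] + 1, px[, 1] + 1)] <- TRUE
  }
  mask
}
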