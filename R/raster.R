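#' @title Image raster conventions
#'
#' @description greenpoly represents an RGB image as a numeric array
#' `[height, width, 3]` with byte values in `0..255`; pixel `(x, y)` in
#' 0-based image coordinates lives at `image[y + 1, x + 1, ]`. HSV rasters
#' share the layout with hue on the 0-179 half-degree scale and
#' saturation/value on 0-255 (the byte convention of mainstream computer
#' vision libraries, under which green vegetation occupies roughly H 35-85).
#' Binary masks are logical matrices `[height, width]`.
#'
#' @name raster-conventions
NULL

assert_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB raster: numeric array [height, width, 3]")
  invisible(image)
}

#' Convert an RGB raster to byte-scaled HSV
#'
#' Hue is reported on the 0-179 half-degree scale (so pure green maps to 60),
#' saturation and value on 0-255. Achromatic pixels have zero saturation and
#' hue 0.
#'
#' @param crop RGB raster, numeric array `[h, w, 3]` with values in 0..255.
#' @return Numeric array `[h, w, 3]` with channels H (0-179), S, V (0-255).
#' @export
rgb_to_hsv <- function(crop) {
  assert_rgb(crop)
  d <- dim(crop)
  px <- rbind(
    r = as.vector(crop[, , 1]),
    g = as.vector(crop[, , 2]),
    b = as.vector(crop[, , 3])
  )
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
  h <- round(hsv[1, ] * 180) %% 180
  s <- round(hsv[2, ] * 255)
  v <- round(hsv[3, ] * 255)
  array(c(h, s, v), dim = d)
}

#' Convert byte-scaled HSV triplets to RGB bytes
#'
#' Inverse companion of [rgb_to_hsv()] used by the synthetic-scene renderer.
#'
#' @param h,s,v numeric vectors: hue 0-179, saturation/value 0-255.
#' @return 3 x n integer matrix of R, G, B bytes.
#' @export
hsv_to_rgb <- function(h, s, v) {
  cols <- grDevices::hsv(
    h = (h * 2) / 360,
    s = pmin(pmax(s / 255, 0), 1),
    v = pmin(pmax(v / 255, 0), 1)
  )
  grDevices::col2rgb(cols)
}

#' Luminance of an RGB raster
#'
#' BT.601 weights (0.299, 0.587, 0.114), the greyscale convention of the
#' classical thresholding baselines.
#'
#' @param image RGB raster in 0..255.
#' @return Numeric matrix `[h, w]` in 0..255.
#' @export
luminance <- function(image) {
  assert_rgb(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Read / write PNG rasters
#'
#' Thin wrappers around the png package using greenpoly's byte-array layout.
#' Greyscale PNGs are read as matrices (used for reference masks).
#'
#' @param path file path.
#' @param image RGB raster (array `[h, w, 3]`) or matrix, values 0..255.
#' @return `read_image()`: array or matrix of bytes; `write_image()`: the
#'   path, invisibly.
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , seq_len(min(3L, dim(x)[3])), drop = FALSE]
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) x <- x[, , 1]
  round(x * 255)
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), target = path)
  invisible(path)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}
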