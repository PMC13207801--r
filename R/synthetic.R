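#' Configuration of the synthetic field-scene generator
#'
#' The generator emulates the interference conditions of field imagery of
#' row crops: rosette plants built from overlapping elongated elliptical
#' leaf lobes (green hues), a textured brown/grey soil background with
#' sparse olive-hued residue patches (the low-hue confusers that a fixed
#' green band picks up and the iterative narrowing discards), optional
#' multiplicative shadow darkening over a sector of each plant, optional
#' bright desaturated stone blobs, and optional Gaussian pixel noise. Every
#' scene carries exact per-object ground-truth masks and tight bounding
#' boxes, making it the test oracle for the whole pipeline.
#'
#' @param width,height scene dimensions in pixels (defaults 320 x 240).
#' @param n_plants number of plants (default 3).
#' @param leaf_lobes `c(min, max)` lobes per plant (default 4..8).
#' @param plant_hue_range closed hue interval for leaves on the 0-179 scale
#'   (default `c(35, 75)`); draws use the open interior so 8-bit colour
#'   round-trips stay inside the interval.
#' @param soil_palette character vector of soil RGB tones.
#' @param shadow_strength fraction in `[0, 1]`: leaf value channel is scaled
#'   by `1 - shadow_strength` inside a random sector (default 0 = off).
#' @param stone_probability probability that each candidate stone site hosts
#'   a stone (default 0 = off).
#' @param noise_sigma standard deviation of additive Gaussian RGB noise in
#'   byte units (default 0 = off).
#' @param seed integer RNG seed; scenes are fully determined by it.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(width = 320, height = 240, n_plants = 3,
                         leaf_lobes = c(4, 8),
                         plant_hue_range = c(35, 75),
                         soil_palette = c("#7d5438", "#6e4a2c", "#8a6244",
                                          "#6f6a62", "#55524c"),
                         shadow_strength = 0, stone_probability = 0,
                         noise_sigma = 0, seed = 1) {
  if (plant_hue_range[1] < 0 || plant_hue_range[2] > 179 ||
      plant_hue_range[1] > plant_hue_range[2])
    stop("plant_hue_range must be an interval within [0, 179]")
  if (shadow_strength < 0 || shadow_strength > 1 ||
      stone_probability < 0 || stone_probability > 1)
    stop("shadow_strength and stone_probability must lie in [0, 1]")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_plants = as.integer(n_plants), leaf_lobes = leaf_lobes,
                 plant_hue_range = plant_hue_range,
                 soil_palette = soil_palette,
                 shadow_strength = shadow_strength,
                 stone_probability = stone_probability,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "scene_config")
}

# Logical [h, w] mask of an ellipse: centre (cx, cy) 0-based, semi-axes
# (a, b), rotation theta.
ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  x0 <- max(0, floor(cx - a - b)); x1 <- min(w - 1, ceiling(cx + a + b))
  y0 <- max(0, floor(cy - a - b)); y1 <- min(h - 1, ceiling(cy + a + b))
  out <- matrix(FALSE, h, w)
  if (x0 > x1 || y0 > y1) return(out)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  out[ys + 1, xs + 1] <- u^2 + v^2 <= 1
  out
}

clamp_byte <- function(x) pmin(pmax(round(x), 0), 255)

#' Generate one synthetic field scene
#'
#' Deterministic for a given config (including its seed): rendering draws
#' all randomness under a local RNG state that is restored afterwards.
#'
#' @param config a [scene_config()].
#' @return An object of class `gp_scene`: `image` (RGB raster) and
#'   `objects`, a list of `list(class_name, box, mask)` with the mask in
#'   full-image coordinates and the box its tight bounds.
#' @export
generate_scene <- function(config = scene_config()) {
  with_seed(config$seed, render_scene(config))
}

render_scene <- function(config) {
  w <- config$width; h <- config$height
  soil_hsv <- rgb_to_hsv(array(t(grDevices::col2rgb(config$soil_palette)),
                               dim = c(length(config$soil_palette), 1, 3)))

  # soil: blocky palette field plus per-pixel value jitter
  cell <- 8L
  gw <- ceiling(w / cell); gh <- ceiling(h / cell)
  pal_idx <- matrix(sample.int(length(config$soil_palette), gw * gh,
                               replace = TRUE), gh, gw)
  pidx <- pal_idx[cbind(rep(pmin((0:(h - 1)) %/% cell + 1, gh), w),
                        rep(pmin((0:(w - 1)) %/% cell + 1, gw), each = h))]
  H <- matrix(soil_hsv[pidx, 1, 1], h, w)
  S <- matrix(clamp_byte(soil_hsv[pidx, 1, 2] + rnorm(h * w, 0, 6)), h, w)
  V <- matrix(clamp_byte(soil_hsv[pidx, 1, 3] + rnorm(h * w, 0, 10)), h, w)

  # olive residue patches: hues just above the soil browns, inside the
  # wide green band but below typical leaf hues
  n_olive <- max(1L, round(w * h / 12000))
  for (i in seq_len(n_olive)) {
    em <- ellipse_mask(h, w, runif(1, 0, w - 1), runif(1, 0, h - 1),
                       runif(1, 2.5, 7), runif(1, 2, 5), runif(1, 0, pi))
    H[em] <- sample(22:33, 1)
    S[em] <- clamp_byte(runif(sum(em), 45, 100))
    V[em] <- clamp_byte(runif(sum(em), 70, 140))
  }

  # stones: bright, desaturated blobs on the soil
  if (config$stone_probability > 0) {
    n_sites <- max(1L, round(w * h / 8000))
    for (i in seq_len(n_sites)) {
      if (runif(1) > config$stone_probability) next
      em <- ellipse_mask(h, w, runif(1, 0, w - 1), runif(1, 0, h - 1),
                         runif(1, 3, 8), runif(1, 3, 7), runif(1, 0, pi))
      H[em] <- sample(15:35, 1)
      S[em] <- clamp_byte(runif(sum(em), 5, 18))
      V[em] <- clamp_byte(runif(sum(em), 238, 255))
    }
  }

  # plants: rosettes of elongated lobes; boxes kept disjoint
  hue_lo <- config$plant_hue_range[1] + 1
  hue_hi <- config$plant_hue_range[2] - 1
  objects <- list()
  occupied <- list()
  for (p in seq_len(config$n_plants)) {
    placed <- FALSE
    for (attempt in seq_len(200)) {
      base_r <- runif(1, 0.055, 0.09) * min(w, h)
      cx <- runif(1, 2.5 * base_r, w - 1 - 2.5 * base_r)
      cy <- runif(1, 2.5 * base_r, h - 1 - 2.5 * base_r)
      n_lobes <- sample(config$leaf_lobes[1]:config$leaf_lobes[2], 1)
      angles <- runif(1, 0, 2 * pi) + (0:(n_lobes - 1)) * 2 * pi / n_lobes +
        rnorm(n_lobes, 0, 0.15)
      lobes <- list(list(m = ellipse_mask(h, w, cx, cy, 0.55 * base_r,
                                          0.55 * base_r, 0)))
      for (li in seq_len(n_lobes)) {
        len <- runif(1, 1.1, 1.8) * base_r
        wid <- len * runif(1, 0.35, 0.55)
        lobes[[li + 1]] <- list(
          m = ellipse_mask(h, w, cx + 0.55 * len * cos(angles[li]),
                           cy + 0.55 * len * sin(angles[li]),
                           len, wid, angles[li]))
      }
      pm <- Reduce(`|`, lapply(lobes, `[[`, "m"))
      if (!any(pm)) next
      rows <- range(which(rowSums(pm) > 0)); cols <- range(which(colSums(pm) > 0))
      box <- labeled_box(sample(c("crop", "weed"), 1),
                         cols[1] - 1L, rows[1] - 1L, cols[2], rows[2])
      clash <- any(vapply(occupied, function(o) box_iou(o, box) > 0, logical(1)))
      if (clash || box$x_min < 1 || box$y_min < 1 ||
          box$x_max > w - 1 || box$y_max > h - 1) next

      for (lb in lobes) {
        m <- lb$m
        H[m] <- sample(hue_lo:hue_hi, 1)
        S[m] <- clamp_byte(runif(1, 130, 210) + rnorm(sum(m), 0, 5))
        V[m] <- clamp_byte(runif(1, 115, 190) + rnorm(sum(m), 0, 6))
      }
      if (config$shadow_strength > 0) {
        ang0 <- runif(1, 0, 2 * pi)
        halfw <- runif(1, pi / 4, pi / 2.2)
        idx <- which(pm, arr.ind = TRUE)
        pa <- atan2(idx[, 1] - 1 - cy, idx[, 2] - 1 - cx)
        d <- abs(((pa - ang0 + pi) %% (2 * pi)) - pi)
        sh <- idx[d <= halfw, , drop = FALSE]
        V[sh] <- clamp_byte(V[sh] * (1 - config$shadow_strength))
      }
      occupied[[length(occupied) + 1L]] <- box
      objects[[length(objects) + 1L]] <-
        list(class_name = box$class_name, box = box, mask = pm)
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place plant %d after 200 attempts; reduce n_plants or enlarge the scene", p))
  }

  rgb <- hsv_to_rgb(as.vector(H), as.vector(S), as.vector(V))
  image <- array(0, dim = c(h, w, 3))
  image[, , 1] <- rgb[1, ]; image[, , 2] <- rgb[2, ]; image[, , 3] <- rgb[3, ]
  if (config$noise_sigma > 0)
    image <- array(clamp_byte(image + rnorm(length(image), 0,
                                            config$noise_sigma)),
                   dim = dim(image))
  structure(list(image = image, objects = objects, config = config),
            class = "gp_scene")
}

#' @export
print.gp_scene <- function(x, ...) {
  cat(sprintf("<gp_scene %dx%d, %d objects (%s)>\n",
              x$config$width, x$config$height, length(x$objects),
              paste(vapply(x$objects, `[[`, character(1), "class_name"),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.gp_scene <- function(x, ...) {
  graphics::plot.new()
  graphics::plot.window(c(0, x$config$width), c(x$config$height, 0),
                        asp = 1)
  graphics::rasterImage(x$image / 255, 0, x$config$height, x$config$width, 0)
  for (obj in x$objects)
    graphics::rect(obj$box$x_min, obj$box$y_max, obj$box$x_max,
                   obj$box$y_min, border = "yellow")
  invisible(x)
}

# Sub-seed for scene i of a dataset, kept inside 32-bit integer range.
scene_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * i) %% 2147483647)
}

#' Generate a synthetic dataset on disk
#'
#' Writes, per scene, a PNG image, a Pascal VOC XML annotation and one
#' 0/255 PNG reference mask per object (`<id>_obj<k>.png`). Per-scene seeds
#' are derived deterministically from the config's master seed, so
#' regeneration reproduces identical files.
#'
#' @param n_scenes number of scenes (>= 1).
#' @param config a [scene_config()]; its `seed` acts as the master seed.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated `gp_scene` objects.
#' @export
generate_dataset <- function(n_scenes, config = scene_config(), dir) {
  if (n_scenes < 1) stop("n_scenes must be >= 1")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scenes <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    cfg <- config
    cfg$seed <- scene_seed(config$seed, i)
    sc <- generate_scene(cfg)
    id <- sprintf("scene_%03d", i)
    write_image(sc$image, file.path(dir, paste0(id, ".png")))
    ann <- annotated_image(id, cfg$width, cfg$height,
                           lapply(sc$objects, `[[`, "box"))
    write_voc_annotation(ann, file.path(dir, paste0(id, ".xml")))
    for (k in seq_along(sc$objects))
      write_image(sc$objects[[k]]$mask * 255,
                  file.path(dir, sprintf("%s_obj%02d.png", id, k)))
    scenes[[i]] <- sc
  }
  invisible(scenes)
}

#' Load a dataset directory back into scene objects
#'
#' Reads the images, VOC annotations and reference masks written by
#' [generate_dataset()] (object order follows the XML's box order).
#'
#' @param dir dataset directory.
#' @return list of `gp_scene`-shaped lists (`image`, `objects`).
#' @export
load_dataset <- function(dir) {
  xmls <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (length(xmls) == 0) stop("no annotations found in ", dir)
  lapply(xmls, function(xf) {
    ann <- read_voc_annotation(xf)
    id <- sub("\\.xml$", "", basename(xf))
    image <- read_image(file.path(dir, paste0(id, ".png")))
    objects <- lapply(seq_along(ann$boxes), function(k) {
      mf <- file.path(dir, sprintf("%s_obj%02d.png", id, k))
      mask <- if (file.exists(mf)) read_image(mf) > 127 else NULL
      list(class_name = ann$boxes[[k]]$class_name, box = ann$boxes[[k]],
           mask = mask)
    })
    structure(list(image = image, objects = objects,
                   config = list(width = ann$width, height = ann$height)),
              class = "gp_scene")
  })
}
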