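# Shared fixtures: everything is generated in code, nothing on disk.

# Uniform crop with one HSV colour (byte scales: H 0-179, S/V 0-255).
uniform_crop <- function(h, w, hue, sat, val) {
  rgb <- hsv_to_rgb(rep(hue, h * w), rep(sat, h * w), rep(val, h * w))
  crop <- array(0, c(h, w, 3))
  crop[, , 1] <- rgb[1, ]; crop[, , 2] <- rgb[2, ]; crop[, , 3] <- rgb[3, ]
  crop
}

# Minimal VOC XML document as a string.
voc_xml <- function(objects, width = 1137, height = 640,
                    filename = "img.png") {
  objs <- vapply(objects, function(o) sprintf(
    "<object><name>%s</name><bndbox><xmin>%s</xmin><ymin>%s</ymin><xmax>%s</xmax><ymax>%s</ymax></bndbox></object>",
    o[[1]], o[[2]], o[[3]], o[[4]], o[[5]]), character(1))
  sprintf("<annotation><filename>%s</filename><size><width>%d</width><height>%d</height><depth>3</depth></size>%s</annotation>",
          filename, width, height, paste(objs, collapse = ""))
}

# Random blob mask from a few overlapping ellipses; returns its principal
# contour (guaranteed non-NULL for these sizes).
random_blob_contour <- function(seed, h = 60, w = 60) {
  set.seed(seed)
  m <- matrix(FALSE, h, w)
  for (i in 1:sample(2:4, 1)) {
    cx <- runif(1, 15, w - 15); cy <- runif(1, 15, h - 15)
    a <- runif(1, 6, 14); b <- runif(1, 4, 10); th <- runif(1, 0, pi)
    xs <- outer(rep(1, h), 0:(w - 1)) - cx
    ys <- outer(0:(h - 1), rep(1, w)) - cy
    u <- (xs * cos(th) + ys * sin(th)) / a
    v <- (-xs * sin(th) + ys * cos(th)) / b
    m <- m | (u^2 + v^2 <= 1)
  }
  largest_contour(m, min_area = 10)
}

# Distance from a point to a closed polygon's boundary (independent oracle
# for the simplification bound; does not reuse package internals).
point_polygon_dist <- function(px, py, verts) {
  n <- nrow(verts)
  nxt <- c(2:n, 1)
  d <- Inf
  for (i in seq_len(n)) {
    x1 <- verts[i, 1]; y1 <- verts[i, 2]
    x2 <- verts[nxt[i], 1]; y2 <- verts[nxt[i], 2]
    l2 <- (x2 - x1)^2 + (y2 - y1)^2
    t <- if (l2 == 0) 0 else
      min(max(((px - x1) * (x2 - x1) + (py - y1) * (y2 - y1)) / l2, 0), 1)
    d <- min(d, sqrt((px - (x1 + t * (x2 - x1)))^2 +
                     (py - (y1 + t * (y2 - y1)))^2))
  }
  d
}

# Random logical mask pair with controlled overlap.
random_mask_pair <- function(seed, h = 20, w = 20) {
  set.seed(seed)
  list(a = matrix(runif(h * w) < runif(1, 0.2, 0.7), h, w),
       b = matrix(runif(h * w) < runif(1, 0.2, 0.7), h, w))
}

# Exhaustive-scan oracle for the first-significant-drop rule.
drop_oracle <- function(scores, frac) {
  r <- max(scores) - min(scores)
  n <- length(scores)
  if (r > 0 && n > 1) {
    for (j in 2:n) if (scores[j - 1] - scores[j] > frac * r) return(j - 1L)
  }
  n
}

# Hand-built history carrying given k_area / k_shape trajectories.
fake_history <- function(k_area, k_shape, params) {
  records <- lapply(seq_along(k_area), function(i) {
    list(h_low = 21 + i, mask = NULL, contour = NULL, area = NA,
         k_area = k_area[i], k_shape = k_shape[i],
         score = params$w_area * k_area[i] + params$w_shape * k_shape[i])
  })
  structure(list(records = records, params = params),
            class = "segmentation_history")
}

clean_cfg <- function(seed) scene_config(seed = seed)
hard_cfg <- function(seed) scene_config(shadow_strength = 0.5,
                                        stone_probability = 0.5,
                                        noise_sigma = 4, seed = seed)
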