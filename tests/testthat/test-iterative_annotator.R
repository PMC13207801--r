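test_that("annotator parameters are validated", {
  expect_error(annotator_params(w_area = 0.7, w_shape = 0.4), "equal 1")
  expect_error(annotator_params(drop_fraction = 0), "drop_fraction")
  expect_error(annotator_params(drop_fraction = 1), "drop_fraction")
  expect_error(annotator_params(n_bands = 0), "n_bands")
  expect_error(annotator_params(h_start = 80, n_bands = 16), "h_top")
  p <- annotator_params()
  expect_equal(c(p$h_start, p$h_top, p$n_bands), c(22, 85, 16))
  expect_equal(c(p$w_area, p$w_shape), c(0.7, 0.3))
})

test_that("area-change coefficient is the successive ratio, 1 at the first stored iteration", {
  expect_equal(compute_k_area(500, 1000), 0.5)
  expect_equal(compute_k_area(700, NULL), 1)
  expect_equal(compute_k_area(850, 850), 1)
  expect_error(compute_k_area(0, 100), "positive")
  expect_error(compute_k_area(100, 0), "positive")
})

test_that("shape coefficient is the rect-to-crop area ratio", {
  expect_equal(compute_k_shape(c(50, 20), c(100, 40)), 0.25)
  expect_equal(compute_k_shape(c(100, 40), c(100, 40)), 1)
  expect_equal(compute_k_shape(c(1, 1), c(100, 100)), 1e-4)
  expect_error(compute_k_shape(c(10, 10), c(0, 40)), "positive")
})

test_that("integral score is the stated weighted sum", {
  p <- annotator_params()
  expect_equal(compute_score(1, 1, p), 1)
  expect_equal(compute_score(0.5, 0.25, p), 0.425)
  p2 <- annotator_params(w_area = 0.4, w_shape = 0.6)
  expect_equal(compute_score(0.5, 0.25, p2), 0.35)
})

test_that("a uniform green crop yields a full-score record per band", {
  crop <- uniform_crop(40, 50, hue = 60, sat = 200, val = 150)
  h <- build_history(crop)
  expect_length(h, 16)
  df <- as.data.frame(h)
  expect_equal(df$score, rep(1, 16))
  expect_equal(df$k_area, rep(1, 16))
  expect_equal(df$k_shape, rep(1, 16))
  expect_equal(df$area, rep(40 * 50, 16))
  expect_equal(df$h_low, 22:37)
})

test_that("bands not containing the crop hue are skipped", {
  # hue 30 falls in bands with h_low <= 30 only: 9 stored records
  crop <- uniform_crop(30, 30, hue = 30, sat = 150, val = 120)
  h <- build_history(crop)
  expect_equal(as.data.frame(h)$h_low, 22:30)
  # no pixel in any band: empty history
  soil <- uniform_crop(30, 30, hue = 10, sat = 120, val = 100)
  expect_length(build_history(soil), 0)
})

test_that("history is deterministic and scores recompose from their parts", {
  sc <- generate_scene(scene_config(seed = 5, n_plants = 1,
                                    width = 140, height = 110))
  crop <- crop_region(sc$image, sc$objects[[1]]$box)
  h1 <- build_history(crop)
  h2 <- build_history(crop)
  expect_identical(h1, h2)
  p <- h1$params
  for (r in h1$records) {
    expect_equal(r$score, p$w_area * r$k_area + p$w_shape * r$k_shape,
                 tolerance = 1e-12)
    expect_gte(r$area, p$min_area)
    expect_gt(r$k_shape, 0); expect_lte(r$k_shape, 1)
  }
  expect_true(all(diff(as.data.frame(h1)$h_low) > 0))
})

test_that("selection returns the last stable record before a significant drop", {
  p <- annotator_params()
  h <- fake_history(c(1.00, 0.97, 0.95, 0.94, 0.50, 0.45), rep(0, 6),
                    annotator_params(w_area = 1, w_shape = 0))
  # scores 1.00 .. 0.45: range 0.55, threshold 0.11, first drop 0.94 -> 0.50
  expect_equal(select_best_iteration(h, 0.2), 4L)  # record before the drop

  const <- fake_history(rep(0.8, 3), rep(0, 3),
                        annotator_params(w_area = 1, w_shape = 0))
  expect_equal(select_best_iteration(const, 0.2), 3L)   # no drop: last

  single <- fake_history(1, 0, annotator_params(w_area = 1, w_shape = 0))
  expect_equal(select_best_iteration(single, 0.2), 1L)

  empty <- structure(list(records = list(), params = p),
                     class = "segmentation_history")
  expect_error(select_best_iteration(empty, 0.2), "no annotation")
})

test_that("selection agrees with the exhaustive consecutive-pair oracle", {
  p1 <- annotator_params(w_area = 1, w_shape = 0)
  set.seed(42)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    scores <- switch(sample(3, 1),
                     round(runif(n), 3),
                     rep(round(runif(1), 3), n),          # constant
                     sort(round(runif(n), 3), TRUE))       # monotone decay
    h <- fake_history(scores, rep(0, n), p1)
    frac <- sample(c(0.1, 0.2, 0.5), 1)
    expect_equal(select_best_iteration(h, frac), drop_oracle(scores, frac))
  }
})

test_that("extreme weights decouple area and shape dynamics", {
  # area collapses at step 4; rect collapses at step 2
  k_area <- c(1, 1.00, 0.98, 0.30, 1.00)
  k_shape <- c(0.9, 0.30, 0.28, 0.28, 0.28)
  area_only <- fake_history(k_area, k_shape,
                            annotator_params(w_area = 1, w_shape = 0))
  shape_only <- fake_history(k_area, k_shape,
                             annotator_params(w_area = 0, w_shape = 1))
  i_area <- select_best_iteration(area_only, 0.2)
  i_shape <- select_best_iteration(shape_only, 0.2)
  expect_equal(i_area, 3L)
  expect_equal(i_shape, 1L)
  expect_true(i_area != i_shape)
})

test_that("annotate_box recovers a clean synthetic plant and degrades to NULL on soil", {
  ious <- vapply(1:5, function(seed) {
    sc <- generate_scene(scene_config(seed = seed, n_plants = 1,
                                      width = 160, height = 130))
    obj <- sc$objects[[1]]
    res <- annotate_box(sc$image, obj$box)
    mask <- rasterize_polygon(res$contour$points,
                              obj$box$x_max - obj$box$x_min,
                              obj$box$y_max - obj$box$y_min)
    gt <- obj$mask[(obj$box$y_min + 1):obj$box$y_max,
                   (obj$box$x_min + 1):obj$box$x_max]
    mask_iou(mask, gt)
  }, numeric(1))
  expect_gte(mean(ious), 90)

  soil <- uniform_crop(40, 40, hue = 10, sat = 120, val = 100)
  expect_null(annotate_box(soil, labeled_box("weed", 0, 0, 40, 40)))

  green <- uniform_crop(30, 30, hue = 60, sat = 200, val = 150)
  res <- annotate_box(green, labeled_box("crop", 0, 0, 30, 30))
  expect_equal(res$contour$area, 900)   # full-crop silhouette
})
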