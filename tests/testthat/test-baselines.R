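test_that("all four baselines honour the crop-to-mask contract", {
  sc <- generate_scene(scene_config(seed = 3, n_plants = 1,
                                    width = 120, height = 100))
  crop <- crop_region(sc$image, sc$objects[[1]]$box)
  for (m in c("fixed_hsv", "otsu", "adaptive", "kmeans")) {
    mask <- suppressMessages(segment_baseline(crop, baseline_config(m)))
    expect_true(is.logical(mask))
    expect_equal(dim(mask), dim(crop)[1:2])
  }
})

test_that("fixed HSV baseline equals the annotator's first stored mask", {
  sc <- generate_scene(scene_config(seed = 9, n_plants = 1,
                                    width = 120, height = 100))
  crop <- crop_region(sc$image, sc$objects[[1]]$box)
  h <- build_history(crop)
  expect_equal(h$records[[1]]$h_low, 22)
  expect_identical(segment_fixed_hsv(crop), h$records[[1]]$mask)

  soil <- uniform_crop(20, 20, hue = 10, sat = 120, val = 100)
  expect_false(any(segment_fixed_hsv(soil)))
  green <- uniform_crop(20, 20, hue = 60, sat = 200, val = 150)
  expect_true(all(segment_fixed_hsv(green)))
})

test_that("Otsu matches a brute-force between-class-variance oracle", {
  # two-level luminance image, equal counts at 50 and 200
  lum <- matrix(rep(c(50, 200), each = 50), 10, 10)
  crop <- array(rep(lum, 3), c(10, 10, 3))
  # oracle: scan all 256 thresholds, maximize between-class variance
  counts <- tabulate(as.vector(lum) + 1, 256)
  best_t <- which.max(vapply(1:255, function(t) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts[(t + 1):256])
    if (w0 == 0 || w1 == 0) return(-1)
    m0 <- sum((0:(t - 1)) * counts[1:t]) / w0
    m1 <- sum((t:255) * counts[(t + 1):256]) / w1
    w0 * w1 * (m0 - m1)^2
  }, numeric(1)))
  expect_gt(best_t, 50); expect_lte(best_t, 200)
  thr <- EBImage::otsu(EBImage::Image(lum / 255), range = c(0, 1),
                       levels = 256) * 255
  expect_gt(thr, 50); expect_lt(thr, 200)
  # classes separate exactly; achromatic image -> green rule picks either
  mask <- suppressMessages(segment_otsu(crop))
  expect_true(all(mask == (lum > thr)) || all(mask == (lum <= thr)))

  expect_message(out <- segment_otsu(uniform_crop(8, 8, 0, 0, 100)),
                 "constant")
  expect_false(any(out))
})

test_that("Otsu keeps the green-luminance class of a half-green crop", {
  crop <- array(0, c(10, 10, 3))
  crop[, 1:5, 2] <- 200                          # bright green half
  crop[, 6:10, 1] <- 60; crop[, 6:10, 2] <- 45   # dark brown soil half
  crop[, 6:10, 3] <- 30
  mask <- segment_otsu(crop)
  expect_true(all(mask[, 1:5]))
  expect_false(any(mask[, 6:10]))
})

test_that("adaptive threshold recovers a bright blob and degrades to empty", {
  crop <- array(20, c(30, 30, 3))
  crop[10:18, 10:18, 2] <- 220   # greenish bright blob
  cfg <- baseline_config("adaptive", adaptive_block = 21, adaptive_offset = 5)
  mask <- segment_adaptive(crop, cfg)
  expect_true(all(mask[11:17, 11:17]))
  # just outside the blob the window mean is pulled above pixel + offset
  expect_false(any(mask[8:9, 10:18]))

  flat <- uniform_crop(10, 10, 0, 0, 100)
  expect_message(m1 <- segment_adaptive(flat, cfg), "degenerate")
  expect_false(any(m1))
  # pinned tie rule: offset 0 on a constant image is still degenerate
  cfg0 <- baseline_config("adaptive", adaptive_offset = 0)
  expect_message(m2 <- segment_adaptive(flat, cfg0), "degenerate")
  expect_false(any(m2))
})

test_that("K-means separates two colours, is seed-deterministic, accepts one colour", {
  crop <- array(0, c(10, 10, 3))
  crop[, 1:5, 2] <- 200                      # green half
  crop[, 6:10, 1] <- 150; crop[, 6:10, 3] <- 30  # reddish half
  cfg <- baseline_config("kmeans", kmeans_k = 2, seed = 4)
  m1 <- segment_kmeans(crop, cfg)
  expect_true(all(m1[, 1:5]))
  expect_false(any(m1[, 6:10]))
  expect_identical(segment_kmeans(crop, cfg), m1)

  one <- uniform_crop(8, 8, 60, 200, 150)
  expect_true(all(segment_kmeans(one, baseline_config("kmeans", kmeans_k = 2))))
})

test_that("baseline configuration is validated", {
  expect_error(baseline_config("adaptive", adaptive_block = 10), "odd")
  expect_error(baseline_config("kmeans", kmeans_k = 1), ">= 2")
  expect_error(segment_baseline(uniform_crop(4, 4, 60, 200, 150),
                                structure(list(method = "snake"),
                                          class = "baseline_config")),
               "unknown")
})
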