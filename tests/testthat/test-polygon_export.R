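test_that("Douglas-Peucker strips collinear edge points from a square", {
  # square traced from a corner with a midpoint on each edge
  sq <- rbind(c(0, 0), c(5, 0), c(10, 0), c(10, 5), c(10, 10),
              c(5, 10), c(0, 10), c(0, 5))
  ct <- as_contour(sq)
  verts <- approximate_contour(ct, epsilon_factor = 0.0015)
  expect_equal(nrow(verts), 4)
  expect_setequal(paste(verts[, 1], verts[, 2]),
                  c("0 0", "10 0", "10 10", "0 10"))

  tri <- as_contour(rbind(c(0, 0), c(8, 0), c(4, 6)))
  expect_equal(nrow(approximate_contour(tri, 0.0015)), 3)

  # zero tolerance retains every point
  expect_equal(nrow(approximate_contour(ct, 0)), 8)
})

test_that("every original point stays within epsilon of the simplified polygon", {
  for (seed in 1:20) {
    ct <- random_blob_contour(seed)
    eps <- 0.0015 * ct$perimeter
    verts <- approximate_contour(ct, 0.0015)
    expect_lte(nrow(verts), nrow(ct$points))
    dmax <- max(vapply(seq_len(nrow(ct$points)), function(i)
      point_polygon_dist(ct$points[i, 1], ct$points[i, 2], verts),
      numeric(1)))
    expect_lte(dmax, eps + 1e-9)
  }
})

test_that("crop-local vertices translate by the box origin and clamp to bounds", {
  box <- labeled_box("crop", 100, 200, 160, 260)
  v <- rbind(c(0, 0), c(10, 0), c(10, 10))
  g <- to_global_coords(v, box, c(1137, 640))
  expect_equal(unname(g), rbind(c(100, 200), c(110, 200), c(110, 210)))

  at_origin <- labeled_box("crop", 0, 0, 60, 60)
  expect_equal(unname(to_global_coords(v, at_origin, c(1137, 640))),
               unname(v))

  # vertex landing on x = width clamps to width - 1
  edge_box <- labeled_box("crop", 1130, 630, 1137, 640)
  ge <- to_global_coords(rbind(c(7, 0), c(0, 10), c(3, 3)), edge_box,
                         c(1137, 640))
  expect_equal(as.numeric(ge[1, 1]), 1136)
  expect_equal(as.numeric(ge[2, 2]), 639)
})

test_that("polygon annotations validate vertex count and bounds", {
  expect_error(polygon_annotation(0, rbind(c(0, 0), c(1, 1)), c(10, 10)),
               "3 vertices")
  expect_error(polygon_annotation(0, rbind(c(0, 0), c(12, 0), c(5, 5)),
                                  c(10, 10)), "bounds")
})

test_that("YOLO-seg lines are normalized 6-decimal, one per polygon", {
  dims <- c(1137, 640)
  tri <- polygon_annotation(1, rbind(c(100, 200), c(110, 200), c(110, 210)),
                            dims)
  line <- write_yolo_seg(list(tri), dims)
  expect_equal(line,
               "1 0.087951 0.312500 0.096746 0.312500 0.096746 0.328125")
  expect_equal(write_yolo_seg(list(), dims), character(0))

  origin <- polygon_annotation(0, rbind(c(0, 0), c(5, 0), c(5, 5)), dims)
  expect_match(write_yolo_seg(list(origin), dims), "^0 0\\.000000 0\\.000000 ")

  # an empty list still produces a zero-length file
  path <- withr::local_tempfile(fileext = ".txt")
  write_yolo_seg(list(), dims, path)
  expect_equal(length(readLines(path)), 0)
})

test_that("emitted labels parse back within one-pixel quantization", {
  dims <- c(1137, 640)
  set.seed(3)
  polys <- lapply(1:10, function(i) {
    n <- sample(3:12, 1)
    polygon_annotation(sample(0:1, 1),
                       cbind(runif(n, 0, dims[1] - 1),
                             runif(n, 0, dims[2] - 1)), dims)
  })
  lines <- write_yolo_seg(polys, dims)
  expect_true(all(vapply(strsplit(lines, " "), function(f)
    all(as.numeric(f[-1]) >= 0 & as.numeric(f[-1]) <= 1), logical(1))))
  back <- read_yolo_seg(lines, dims)
  for (i in seq_along(polys)) {
    expect_equal(back[[i]]$class_id, polys[[i]]$class_id)
    expect_lt(max(abs(back[[i]]$vertices - polys[[i]]$vertices)), 1)
  }
})

test_that("rasterization fills the polygon interior and boundary", {
  sq <- rbind(c(2, 2), c(7, 2), c(7, 7), c(2, 7))
  m <- rasterize_polygon(sq, 10, 10)
  expect_true(all(m[3:8, 3:8]))
  expect_false(any(m[1, ]) || any(m[, 1]) || any(m[10, ]) || any(m[, 10]))
  expect_equal(sum(m), 36)
  # degenerate vertex lists rasterize to an empty mask
  expect_false(any(rasterize_polygon(NULL, 5, 5)))
  expect_false(any(rasterize_polygon(rbind(c(1, 1), c(3, 3)), 5, 5)))
})
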