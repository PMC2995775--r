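test_that("tracing an axis-aligned square yields its 4 corners", {
  mask <- matrix(FALSE, 32, 32)
  mask[11:20, 6:15] <- TRUE  # 10 x 10 square, pixels x 5..14, y 10..19
  poly <- trace_region_polygon(mask)
  expect_identical(nrow(poly), 4L)
  expect_equal(polygon_area(poly), 100)
  expect_identical(rasterize_polygon(poly, 32, 32), mask)
})

test_that("re-rasterizing a traced region reproduces the mask exactly", {
  set.seed(11)
  for (rep in 1:10) {
    img <- matrix(0, 40, 40)
    # random blobby region: union of a few rectangles around a centre
    for (k in 1:4) {
      r0 <- sample(5:28, 1); c0 <- sample(5:28, 1)
      img[r0:(r0 + sample(3:8, 1)), c0:(c0 + sample(3:8, 1))] <- 1
    }
    seeds <- which(img == 1, arr.ind = TRUE)
    seed <- seeds[1, ]
    region <- flood_fill(img, c(seed[2] - 1L, seed[1] - 1L))
    poly <- trace_region_polygon(region)
    expect_identical(rasterize_polygon(poly, 40, 40), fill_holes(region))
  }
})

test_that("tracing a disk recovers its area within 3%", {
  mask <- cmdx:::rasterize_ellipse(c(x = 5, y = 5, width = 40, height = 40),
                                   50, 50)
  poly <- trace_region_polygon(mask)
  expect_lt(abs(polygon_area(poly) - sum(mask)) / sum(mask), 0.03)
})

test_that("empty and multi-component masks are rejected", {
  expect_error(trace_region_polygon(matrix(FALSE, 4, 4)), "empty")
  two <- matrix(FALSE, 8, 8)
  two[1:2, 1:2] <- TRUE
  two[6:7, 6:7] <- TRUE
  expect_error(trace_region_polygon(two), "component")
})
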