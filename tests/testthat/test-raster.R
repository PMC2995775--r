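test_that("pixel-centre sampling gives exact counts for axis-aligned shapes", {
  # rectangle (2, 2, 10, 10) covers exactly 100 pixels
  m <- cmdx:::rasterize_rect(c(x = 2, y = 2, width = 10, height = 10),
                             64, 64)
  expect_identical(sum(m), 100L)
  # the same square as a polygon
  mp <- rasterize_polygon(square_pts(2, 2, 10), 64, 64)
  expect_identical(mp, m)
  # right triangle (0,0) (10,0) (0,10): pixel centres strictly under the
  # hypotenuse x + y = 10 -> 9 + 8 + ... + 1 = 45 pixels
  mt <- rasterize_polygon(rbind(c(0, 0), c(10, 0), c(0, 10)), 64, 64)
  expect_identical(sum(mt), 45L)
})

test_that("polygon rasterization matches a brute-force even-odd oracle", {
  set.seed(42)
  for (rep in 1:5) {
    k <- sample(3:9, 1)
    pts <- cbind(runif(k, 2, 30), runif(k, 2, 30))
    m <- rasterize_polygon(pts, 32, 32)
    oracle <- matrix(FALSE, 32, 32)
    for (y in 0:31) for (x in 0:31) {
      oracle[y + 1, x + 1] <- point_in_polygon(x + 0.5, y + 0.5, pts)
    }
    expect_identical(m, oracle)
  }
})

test_that("ellipse pixel count approximates the analytic area", {
  m <- cmdx:::rasterize_ellipse(c(x = 6, y = 46, width = 100, height = 60),
                                512, 512)
  expect_lt(abs(sum(m) - pi * 50 * 30) / (pi * 50 * 30), 0.01)
})

test_that("area fractions are stable across reference resolutions", {
  d <- rect_slice_doc(list(square_pts(20, 20, 35)), factor = 1)
  frac <- function(long_side) {
    v <- estimate_volume(d, long_side = long_side)
    v$per_slice$cancer_pixels / v$per_slice$slice_pixels
  }
  expect_lt(abs(frac(512) - frac(1024)), 0.005)
})

test_that("degenerate geometry is rejected", {
  expect_error(rasterize_polygon(rbind(c(0, 0), c(1, 1)), 8, 8),
               "degenerate")
  expect_error(rasterize_polygon(rbind(c(0, 0), c(5, 5), c(10, 10)), 16, 16),
               "degenerate")
  expect_error(cmdx:::rasterize_rect(c(x = 0, y = 0, width = 0, height = 5),
                                     8, 8), "degenerate")
})

test_that("hit_test returns the topmost surface in document order", {
  d <- rect_slice_doc()
  d$mask <- list(
    mask_surface("bottom", shape = "rectangle", rect = c(0, 0, 50, 50),
                 percentage = 0.5),
    mask_surface("top", shape = "rectangle", rect = c(25, 25, 50, 50),
                 percentage = 0.5))
  expect_identical(hit_test(d, c(30, 30)), "top")
  expect_identical(hit_test(d, c(10, 10)), "bottom")
  expect_identical(hit_test(d, c(90, 90)), NA_character_)
})
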