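test_that("flood fill on a uniform image selects everything", {
  img <- matrix(0.5, 16, 16)
  expect_true(all(flood_fill(img, c(0, 0))))
})

test_that("flood fill stays within the seed's connected component", {
  img <- matrix(1, 16, 16)
  img[, 8] <- 0  # vertical wall splits the image
  sel <- flood_fill(img, c(0, 0))
  expect_true(all(sel[, 1:6]))
  expect_false(any(sel[, 8:16]))
})

test_that("diagonally touching pixels are connected (8-connectivity)", {
  img <- matrix(0, 8, 8)
  img[cbind(1:8, 1:8)] <- 1  # diagonal line
  sel <- flood_fill(img, c(0, 0))
  expect_identical(sum(sel), 8L)
})

test_that("tolerance is a Chebyshev bound on the 0-255 scale", {
  img <- matrix(0, 4, 4)
  img[, 2] <- 10 / 255
  img[, 3] <- 30 / 255
  sel <- flood_fill(img, c(0, 0), tolerance = 10)
  expect_true(all(sel[, 1:2]))
  expect_false(any(sel[, 3:4]))
})

test_that("outside_contour_only fills interior holes", {
  img <- matrix(0, 16, 16)
  img[5:12, 5:12] <- 1
  img[8:9, 8:9] <- 0  # hole inside the square
  sel <- flood_fill(img, c(6, 6))           # seed inside the ring
  expect_false(any(sel[8:9, 8:9]))          # hole excluded by default
  sel2 <- flood_fill(img, c(6, 6), outside_contour_only = TRUE)
  expect_true(all(sel2[8:9, 8:9]))          # hole filled
  expect_identical(sel2[5:12, 5:12], matrix(TRUE, 8, 8))
})

test_that("flood fill matches an independent BFS oracle on random images", {
  set.seed(7)
  for (rep in 1:20) {
    img <- matrix(sample(c(0, 0.4, 1), 24 * 24, replace = TRUE,
                         prob = c(0.4, 0.3, 0.3)), 24, 24)
    seed <- c(sample(0:23, 1), sample(0:23, 1))
    tol <- sample(c(0, 120), 1)
    got <- flood_fill(img, seed, tolerance = tol)
    want <- bfs_flood_fill(img, seed, tolerance = tol)
    expect_identical(got, want)
    expect_identical(flood_fill(img, seed, tolerance = tol,
                                outside_contour_only = TRUE),
                     bfs_fill_holes(want))
  }
})

test_that("seed outside the image is rejected", {
  expect_error(flood_fill(matrix(0, 4, 4), c(4, 0)), "out of bounds")
  expect_error(flood_fill(matrix(0, 4, 4), c(-1, 0)), "out of bounds")
})
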