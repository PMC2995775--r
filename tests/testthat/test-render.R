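test_that("rendering is deterministic and returns an RGBA canvas", {
  d <- simulate_specimen(tpl, cohort_params(seed = 2), seed = 11)$doc
  a <- render_document(d)
  b <- render_document(d)
  expect_identical(a, b)
  expect_identical(dim(a), c(512L, 512L, 4L))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("layers compose: each extra layer changes the canvas", {
  d <- simulate_specimen(tpl, cohort_params(seed = 2), seed = 11)$doc
  bg <- render_document(d, layers = "background")
  bm <- render_document(d, layers = c("background", "mask"))
  all3 <- render_document(d, layers = c("background", "mask", "draw"))
  expect_false(identical(bg, bm))
  expect_false(identical(bm, all3))
})

test_that("set_clip confines a focus to its slice", {
  # a focus hanging far outside its slice: clipped pixels must not paint
  big <- square_pts(-30, -30, 80)  # covers the slice corner and beyond
  d <- rect_slice_doc(list(big))
  d$mask[[1]]$rect <- c(x = 0, y = 0, width = 40, height = 40)
  d$mask[[1]]$style$set_clip <- TRUE
  size <- c(width = 100L, height = 100L)
  img <- render_document(d, size = size)
  bg_only <- render_document(d, size = size, layers = "background")
  outside <- img[60:100, 60:100, ]  # region far outside the 40x40 slice
  expect_identical(outside, bg_only[60:100, 60:100, ])
})

test_that("render_to_png writes a decodable image", {
  d <- simulate_specimen(tpl, cohort_params(seed = 2), seed = 11)$doc
  f <- withr::local_tempfile(fileext = ".png")
  render_to_png(d, f)
  img <- png::readPNG(f)
  expect_identical(dim(img)[1:2], c(512L, 512L))
})
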