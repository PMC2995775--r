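test_that("the default template validates cleanly", {
  v <- validate_document(tpl)
  expect_s3_class(v, "data.frame")
  expect_identical(nrow(v), 0L)
  expect_length(tpl$mask, 10)  # 8 slices + 2 seminal vesicles
  factors <- vapply(tpl$mask, `[[`, numeric(1), "percentage")
  levels <- vapply(tpl$mask, `[[`, character(1), "level")
  expect_equal(sum(factors[levels != "vesicle"]), 1)
  expect_equal(factors[levels == "vesicle"], c(0, 0))
})

test_that("befund_record derives the Gleason score from its patterns", {
  b <- befund_record("F1", gleason1 = 3, gleason2 = 4)
  expect_identical(b$gleason_score, 7L)
  b2 <- befund_record("F1", gleason1 = 3, gleason2 = 4, gleason_score = 9)
  expect_identical(b2$gleason_score, 9L)  # explicit value wins (invalid,
                                          # caught by validation below)
})

test_that("validation flags each class of broken document", {
  break_doc <- function(mutate) {
    d <- rect_slice_doc(list(square_pts(10, 10, 20)),
                        factor = 1, prostat_volumen = 40)
    mutate(d)
  }
  expect_rule <- function(doc, rule) {
    v <- validate_document(doc)
    expect_true(rule %in% v$rule,
                info = paste("expected rule", rule, "got",
                             paste(v$rule, collapse = ", ")))
  }

  # colour channel out of range
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$style$brush_color[["red"]] <- 300
    d
  }), "channel_range")

  # polygon with fewer than 3 vertices
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$geometry$value <- rbind(c(0, 0), c(1, 1))
    d
  }), "focus_polygon")

  # slice factor outside [0, 1]
  expect_rule(break_doc(function(d) {
    d$mask[[1]]$percentage <- 1.5
    d
  }), "percentage_range")

  # Gleason score not the sum of its patterns
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$befund$gleason_score <- 9L
    d
  }), "gleason_score_sum")

  # map object referencing an unknown tool
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$tool_name <- "NoSuchTool"
    d
  }), "tool_resolves")

  # map object referencing an unknown surface
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$surface_id <- "S99"
    d
  }), "surface_resolves")

  # duplicate surface ids
  expect_rule(break_doc(function(d) {
    d$mask <- c(d$mask, d$mask)
    d
  }), "surface_id_unique")

  # befund attached to a non-focus object
  expect_rule(break_doc(function(d) {
    d$map_objects[[1]]$kind <- "hgpin"
    d
  }), "befund_only_on_focus")

  # more positive than examined lymph nodes
  expect_rule(break_doc(function(d) {
    d$form$lk_b <- 5L; d$form$lk_g <- 2L
    d
  }), "lymph_node_counts")

  # non-positive prostate volume
  expect_rule(break_doc(function(d) {
    d$form$prostat_volumen <- -1
    d
  }), "prostate_volume_positive")

  # complete template whose slice factors do not sum to 1
  expect_rule(break_doc(function(d) {
    d$mask[[1]]$percentage <- 0.5
    d
  }), "slice_factor_sum")
})

test_that("resolve_focus_records rejects duplicate focus ids", {
  d <- rect_slice_doc(list(square_pts(10, 10, 20),
                           square_pts(60, 60, 20)))
  d$map_objects[[2]]$id <- "F1"
  expect_error(resolve_focus_records(d), "F1")
})

test_that("geometry normalization distinguishes point, rect and polygon", {
  o1 <- map_object("a", "PCa", geometry = c(3, 4))
  expect_identical(o1$geometry$type, "position")
  o2 <- map_object("a", "PCa", geometry = c(1, 2, 10, 10))
  expect_identical(o2$geometry$type, "rect")
  o3 <- map_object("a", "PCa", geometry = square_pts(0, 0, 5))
  expect_identical(o3$geometry$type, "points")
  expect_error(map_object("a", "PCa", geometry = c(1, 2, 3)), "geometry")
})
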