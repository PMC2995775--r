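test_that("volume estimation follows the slice-factor formula", {
  # a focus covering exactly half of a slice with factor 0.2, prostate
  # volume 50 cm^3 -> tumour volume 0.5 * 0.2 * 50 = 5 cm^3
  half <- rbind(c(0, 0), c(50, 0), c(50, 100), c(0, 100))
  d <- rect_slice_doc(list(half), factor = 1, prostat_volumen = 50)
  d$mask[[1]]$percentage <- 0.2
  d$complete <- FALSE  # single slice, factors intentionally incomplete
  v <- estimate_volume(d)
  expect_equal(v$per_slice$cancer_pixels / v$per_slice$slice_pixels, 0.5,
               tolerance = 0.01)
  expect_equal(v$volume_cm3, 5, tolerance = 0.05)
})

test_that("complete coverage returns exactly the prostate volume", {
  full <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  d <- rect_slice_doc(list(full), factor = 1, prostat_volumen = 42.5)
  v <- estimate_volume(d)
  expect_identical(v$per_slice$cancer_pixels, v$per_slice$slice_pixels)
  expect_equal(v$relative_volume, 1)
  expect_equal(v$volume_cm3, 42.5)
})

test_that("overlapping foci are counted once", {
  a <- square_pts(10, 10, 30)
  b <- square_pts(25, 25, 30)  # overlaps a
  v_both <- estimate_volume(rect_slice_doc(list(a, b)))
  union_px <- sum(rasterize_polygon(a, 512, 512) |
                  rasterize_polygon(b, 512, 512))
  expect_identical(v_both$per_slice$cancer_pixels, union_px)
})

test_that("volume grows monotonically with the focus", {
  sizes <- c(10, 20, 35, 60)
  vols <- vapply(sizes, function(s) {
    estimate_volume(rect_slice_doc(list(square_pts(15, 15, s)),
                                   prostat_volumen = 40))$volume_cm3
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("seminal vesicles never contribute to the volume", {
  d <- simulate_specimen(tpl, cohort_params(seed = 4), seed = 21)$doc
  v <- estimate_volume(d)
  expect_false(any(c("V1", "V2") %in% v$per_slice$slice_id))
})

test_that("bbox clustering merges adjacent foci that polygon mode splits", {
  # two thin diagonal strips: disjoint polygons, overlapping boxes
  d1 <- rbind(c(10, 30), c(40, 60), c(38, 62), c(8, 32))
  d2 <- rbind(c(12, 24), c(44, 56), c(46, 54), c(14, 22))
  d <- rect_slice_doc(list(d1, d2))
  expect_identical(cluster_foci(d, mode = "bbox")$n_clusters, 1L)
  expect_identical(cluster_foci(d, mode = "bbox")$label, "unifocal")
  expect_identical(cluster_foci(d, mode = "polygon")$n_clusters, 2L)
  expect_identical(cluster_foci(d, mode = "polygon")$label, "multifocal")
})

test_that("clustering equals brute-force transitive closure", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:7, 1)
    fs <- lapply(seq_len(n), function(i) {
      square_pts(runif(1, 0, 70), runif(1, 0, 70), runif(1, 5, 25))
    })
    d <- rect_slice_doc(fs)
    got <- cluster_foci(d, mode = "bbox")
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      adj[i, j] <- cmdx:::bboxes_overlap(cmdx:::bbox_of(fs[[i]]),
                                         cmdx:::bbox_of(fs[[j]]))
    }
    labels <- closure_partition(adj)
    expect_identical(got$n_clusters, max(labels))
    got_parts <- lapply(got$cluster_members, function(ids)
      sort(as.integer(sub("^F", "", ids))))
    got_parts <- got_parts[order(vapply(got_parts, `[`, integer(1), 1))]
    expect_identical(got_parts, canon_partition(labels))
  }
})

test_that("Relation metadata links foci across slices", {
  d <- simulate_specimen(tpl, cohort_params(seed = 4), seed = 21)$doc
  # two fresh foci on different slices, linked by Relation
  f1 <- map_object("X1", "PCa", geometry = square_pts(80, 95, 12),
                   surface_id = "S1")
  f2 <- map_object("X2", "PCa", geometry = square_pts(80, 300, 12),
                   surface_id = "S5", relation = "X1")
  d$map_objects <- list(f1, f2)
  expect_identical(cluster_foci(d)$n_clusters, 1L)
  d$map_objects[[2]]$relation <- ""
  expect_identical(cluster_foci(d)$n_clusters, 2L)
})

test_that("focality concordance reproduces the published table", {
  pairs <- rbind(
    data.frame(tool = "multifocal", reference = "multifocal")[rep(1, 121), ],
    data.frame(tool = "unifocal", reference = "multifocal")[rep(1, 13), ],
    data.frame(tool = "unifocal", reference = "unifocal")[rep(1, 121), ])
  cc <- focality_concordance(pairs)
  expect_equal(cc$sensitivity_multifocal, 100 * 121 / 134)
  expect_equal(round(cc$sensitivity_multifocal, 1), 90.3)
  expect_equal(round(cc$reference_multifocal_rate, 1), 52.5)
  expect_equal(round(cc$tool_multifocal_rate, 1), 47.5)
  expect_equal(cc$specificity, 100)
})

test_that("zone summary reproduces the published per-level statistics", {
  s <- zone_percentage_summary(c(36, 80, 87, 89))
  expect_equal(s$mean, 73)
  expect_equal(s$median, 83.5)
  expect_equal(round(s$sd), 25)
})

test_that("zone localization computes pooled PZ percentages", {
  docs <- lapply(1:4, function(i)
    simulate_specimen(tpl, cohort_params(seed = 9), seed = 100 + i)$doc)
  z <- suppressWarnings(zone_localization(docs))
  expect_true(all(z$per_level$pz_percent >= 0 &
                  z$per_level$pz_percent <= 100))
  expect_true(all(z$per_level$level %in%
                  c("base", "middle1", "middle2", "apex")))
})

test_that("cumulative map counts per-pixel focus coverage", {
  a <- square_pts(10, 10, 30)
  b <- square_pts(25, 25, 30)
  d1 <- rect_slice_doc(list(a))
  d2 <- rect_slice_doc(list(b))
  cm <- cumulative_map(list(d1, d2))
  expect_identical(max(cm$grid), 2L)  # the overlap region
  expect_identical(cm$n_foci, 2L)
  ga <- rasterize_polygon(a, 512, 512)
  gb <- rasterize_polygon(b, 512, 512)
  expect_identical(cm$grid, ga + gb)
})

test_that("cohort analysis rejects documents with different templates", {
  d1 <- simulate_specimen(tpl, cohort_params(seed = 2), seed = 1)$doc
  d2 <- rect_slice_doc(list(square_pts(5, 5, 10)))
  expect_error(cumulative_map(list(one = d1, two = d2)), "template")
})

test_that("CSV export writes re-readable results", {
  res <- simulate_cohort(cohort_params(n_specimens = 4, seed = 6))
  # small cohorts can leave levels without cancer; the exclusion warning
  # is documented behaviour
  coh <- suppressWarnings(analyze_cohort(res$docs))
  out <- withr::local_tempdir()
  files <- export_csv(coh, out)
  expect_true(all(file.exists(file.path(out, c("specimens.csv",
                                               "slice_incidence.csv")))))
  spec <- read.csv(file.path(out, "specimens.csv"))
  expect_identical(nrow(spec), 4L)
  expect_equal(spec$relative_volume, coh$rows$relative_volume)
})
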