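test_that("the default template has a complete, valid slice scheme", {
  expect_identical(nrow(validate_document(tpl)), 0L)
  slices <- Filter(function(s) !identical(s$level, "vesicle"), tpl$mask)
  expect_length(slices, 8)
  expect_equal(sum(vapply(slices, `[[`, numeric(1), "percentage")), 1)
  # every slice carries a peripheral-zone polygon
  expect_true(all(vapply(slices, function(s) "PZ" %in% names(s$zone_labels),
                         logical(1))))
})

test_that("simulation is deterministic for a given seed", {
  p <- cohort_params(seed = 123)
  a <- simulate_specimen(tpl, p, seed = 5)
  b <- simulate_specimen(tpl, p, seed = 5)
  expect_true(documents_equivalent(a$doc, b$doc))
  expect_identical(a$truth, b$truth)
  c_ <- simulate_specimen(tpl, p, seed = 6)
  expect_false(isTRUE(documents_equivalent(a$doc, c_$doc)))
})

test_that("simulated specimens are valid and truth matches the drawing", {
  res <- simulate_cohort(cohort_params(n_specimens = 6, seed = 17))
  for (i in seq_along(res$docs)) {
    d <- res$docs[[i]]
    t <- res$truth[[i]]
    expect_identical(nrow(validate_document(d)), 0L)
    expect_identical(length(cmdx:::pca_foci(d)), nrow(t$foci))
    # recorded area fractions agree with pixel counting within 2%
    v <- estimate_volume(d)
    expect_lt(abs(v$relative_volume - t$relative_volume), 0.02)
    # focality truth consistent with well-separated clustering
    if (!t$adjacent) {
      expect_identical(cluster_foci(d)$label, t$focality)
    }
  }
})

test_that("cohort writing produces packages and a manifest", {
  dir <- withr::local_tempdir()
  res <- simulate_cohort(cohort_params(n_specimens = 3, seed = 2),
                         dir = dir)
  expect_true(all(file.exists(file.path(dir, paste0(
    sprintf("spec%03d", 1:3), ".cmdx")))))
  man <- read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 3L)
  expect_true(all(c("id", "seed", "focality", "true_relative_volume")
                  %in% names(man)))
  back <- read_cmdx(file.path(dir, "spec001.cmdx"))
  expect_true(documents_equivalent(res$docs[[1]], back))
})

test_that("the multifocal rate parameter shifts the generated rate", {
  lo <- simulate_cohort(cohort_params(n_specimens = 30, seed = 8,
                                      multifocal_rate = 0.1))
  hi <- simulate_cohort(cohort_params(n_specimens = 30, seed = 8,
                                      multifocal_rate = 0.9))
  rate <- function(res) mean(vapply(res$truth, function(t)
    t$focality == "multifocal", logical(1)))
  expect_lt(rate(lo), rate(hi))
})
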