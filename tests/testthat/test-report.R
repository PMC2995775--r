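test_that("the PDF report is written and byte-deterministic", {
  d <- simulate_specimen(tpl, cohort_params(seed = 13), seed = 3)$doc
  f1 <- withr::local_tempfile(fileext = ".pdf")
  f2 <- withr::local_tempfile(fileext = ".pdf")
  export_report(d, f1)
  export_report(d, f2)
  b1 <- readBin(f1, "raw", n = file.size(f1))
  b2 <- readBin(f2, "raw", n = file.size(f2))
  expect_identical(rawToChar(b1[1:5]), "%PDF-")
  expect_identical(b1, b2)
})

test_that("encrypted patient fields are masked on the report", {
  d <- simulate_specimen(tpl, cohort_params(seed = 13), seed = 3)$doc
  f <- withr::local_tempfile(fileext = ".cmdx")
  write_cmdx(d, f, passphrase = "pw")
  locked <- read_cmdx(f)  # no passphrase: envelopes kept
  lines <- cmdx:::form_display_lines(locked$form)
  expect_true(any(grepl("\\[encrypted\\]", lines)))
  expect_false(any(grepl(d$form$patient_fields[[1]]$value, lines,
                         fixed = TRUE)))
})

test_that("an invalid document is refused", {
  d <- simulate_specimen(tpl, cohort_params(seed = 13), seed = 3)$doc
  d$form$prostat_volumen <- -1
  expect_error(export_report(d, tempfile(fileext = ".pdf")), "valid")
})
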