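test_that("field encryption round-trips, including non-ASCII text", {
  for (txt in c("Mustermann, Max", "O'Brien \"Bob\"", "Müller — 中文")) {
    env <- encrypt_field(txt, "correct horse")
    expect_s3_class(env, "cmdx_envelope")
    expect_identical(decrypt_field(env, "correct horse"), txt)
  }
})

test_that("each envelope uses fresh salt and IV", {
  a <- encrypt_field("same text", "pw")
  b <- encrypt_field("same text", "pw")
  expect_false(identical(a$salt, b$salt))
  expect_false(identical(a$iv, b$iv))
  expect_false(identical(a$ciphertext, b$ciphertext))
})

test_that("the wrong passphrase fails detectably, never silently", {
  env <- encrypt_field("secret name", "right")
  expect_error(decrypt_field(env, "wrong"), "authentication failed")
})

test_that("ciphertext tampering is detected", {
  env <- encrypt_field("secret name", "pw")
  raw_ct <- openssl::base64_decode(env$ciphertext)
  raw_ct[1] <- xor(raw_ct[1], as.raw(0x01))
  env$ciphertext <- openssl::base64_encode(raw_ct)
  expect_error(decrypt_field(env, "pw"), "authentication failed")
})

test_that("MAC tampering and scheme-tag tampering are detected", {
  env <- encrypt_field("x", "pw")
  env2 <- env
  raw_mac <- openssl::base64_decode(env2$mac)
  raw_mac[1] <- xor(raw_mac[1], as.raw(0xff))
  env2$mac <- openssl::base64_encode(raw_mac)
  expect_error(decrypt_field(env2, "pw"), "authentication failed")
  env3 <- env
  env3$scheme_tag <- "cmdx1-something-else"
  expect_error(decrypt_field(env3, "pw"), "scheme")
})
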