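# Field-level encryption for sensitive form entries.
#
# Scheme "cmdx1": AES-256-CBC with encrypt-then-MAC (HMAC-SHA256),
# per-field random salt and IV, keys derived from the passphrase with
# bcrypt_pbkdf. The MAC covers scheme tag, salt, IV and ciphertext, so
# tampering and wrong passphrases are detected before any plaintext is
# released.

CMDX_SCHEME_TAG <- "cmdx1-aes256cbc-hmacsha256"

derive_keys <- function(passphrase, salt, rounds) {
  km <- openssl::bcrypt_pbkdf(passphrase, salt, rounds = rounds, size = 64L)
  list(enc = km[1:32], mac = km[33:64])
}

envelope_mac <- function(keys, scheme_tag, salt, iv, ciphertext) {
  openssl::sha256(c(charToRaw(scheme_tag), salt, iv, ciphertext),
                  key = keys$mac)
}

#' Encrypt a sensitive text field
#'
#' @param plaintext character scalar (UTF-8)
#' @param passphrase non-empty character scalar
#' @param kdf_iterations bcrypt_pbkdf round count (work factor)
#' @return a `cmdx_envelope`: list with base64 `ciphertext`, `salt`, `iv`,
#'   `mac`, `kdf_iterations` and `scheme_tag`
#' @export
encrypt_field <- function(plaintext, passphrase, kdf_iterations = 16L) {
  stopifnot(is.character(plaintext), length(plaintext) == 1)
  if (!is.character(passphrase) || !nzchar(passphrase)) {
    stop("passphrase must be a non-empty string")
  }
  salt <- openssl::rand_bytes(16)
  iv <- openssl::rand_bytes(16)
  keys <- derive_keys(passphrase, salt, kdf_iterations)
  ct <- openssl::aes_cbc_encrypt(charToRaw(enc2utf8(plaintext)),
                                 key = keys$enc, iv = iv)
  attributes(ct) <- NULL
  mac <- envelope_mac(keys, CMDX_SCHEME_TAG, salt, iv, ct)
  structure(list(
    ciphertext = openssl::base64_encode(ct),
    salt = openssl::base64_encode(salt),
    iv = openssl::base64_encode(iv),
    mac = openssl::base64_encode(mac),
    kdf_iterations = as.integer(kdf_iterations),
    scheme_tag = CMDX_SCHEME_TAG
  ), class = "cmdx_envelope")
}

#' Decrypt a sensitive text field
#'
#' Verifies the envelope's MAC before decrypting; a wrong passphrase or a
#' tampered envelope raises an authentication error, never silent garbage.
#'
#' @param envelope a `cmdx_envelope` from [encrypt_field()]
#' @param passphrase the passphrase used at encryption
#' @return the plaintext character scalar
#' @export
decrypt_field <- function(envelope, passphrase) {
  if (!inherits(envelope, "cmdx_envelope")) {
    stop("not a cmdx_envelope")
  }
  if (!identical(envelope$scheme_tag, CMDX_SCHEME_TAG)) {
    stop("unsupported encryption scheme '", envelope$scheme_tag, "'")
  }
  if (!is.character(passphrase) || !nzchar(passphrase)) {
    stop("passphrase must be a non-empty string")
  }
  salt <- openssl::base64_decode(envelope$salt)
  iv <- openssl::base64_decode(envelope$iv)
  ct <- openssl::base64_decode(envelope$ciphertext)
  mac <- openssl::base64_decode(envelope$mac)
  keys <- derive_keys(passphrase, salt, envelope$kdf_iterations)
  expect <- envelope_mac(keys, envelope$scheme_tag, salt, iv, ct)
  if (length(mac) != length(expect) ||
      !identical(as.integer(sum(mac != expect)), 0L)) {
    stop("authentication failed: wrong passphrase or tampered envelope",
         call. = FALSE)
  }
  pt <- openssl::aes_cbc_decrypt(ct, key = keys$enc, iv = iv)
  rawToChar(pt)
}

#' @export
print.cmdx_envelope <- function(x, ...) {
  cat(sprintf("<cmdx_envelope %s, %d ct bytes>\n", x$scheme_tag,
              length(openssl::base64_decode(x$ciphertext))))
  invisible(x)
}
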