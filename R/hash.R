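#' Salted hash digests
#'
#' Deterministic pseudonymization by cryptographic (or fast non-
#' cryptographic) hashing of a salted identifier. The salt is a random
#' per-domain string, so the same identifier yields unlinkable pseudonyms
#' in different domains. The digest input is the UTF-8 byte sequence of
#' `identifier` followed immediately by `salt`.
#'
#' Supported algorithms and their hex output lengths:
#' `md5` (32), `sha1` (40), `sha2` (SHA-256, 64), `sha3` (SHA3-512, 128),
#' `blake3` (256-bit, 64), `xxhash` (64-bit, 16). All outputs are
#' lowercase hexadecimal, i.e. 64-512 bits.
#'
#' @param identifier Non-empty identifier string.
#' @param salt Salt string (may be empty, e.g. when reproducing published
#'   test vectors).
#' @param algorithm One of `"md5"`, `"sha1"`, `"sha2"`, `"sha3"`,
#'   `"blake3"`, `"xxhash"`.
#' @return Lowercase hex digest string.
#' @examples
#' hash_digest("abc", "", "md5")
#' @export
hash_digest <- function(identifier, salt, algorithm) {
  if (!is.character(identifier) || length(identifier) != 1L || !nzchar(identifier)) {
    err_validation("identifier must be a non-empty string")
  }
  if (!is.character(salt) || length(salt) != 1L) {
    err_validation("salt must be a single string")
  }
  input <- enc2utf8(paste0(identifier, salt))
  switch(algorithm,
    md5    = digest::digest(input, algo = "md5",      serialize = FALSE),
    sha1   = digest::digest(input, algo = "sha1",     serialize = FALSE),
    sha2   = digest::digest(input, algo = "sha256",   serialize = FALSE),
    blake3 = digest::digest(input, algo = "blake3",   serialize = FALSE),
    xxhash = digest::digest(input, algo = "xxhash64", serialize = FALSE),
    sha3   = paste(as.character(openssl::sha3(charToRaw(input), size = 512)),
                   collapse = ""),
    pt_abort("unknown_algorithm",
             sprintf("unknown hash algorithm '%s'", algorithm))
  )
}

hash_algorithms <- c("md5", "sha1", "sha2", "sha3", "blake3", "xxhash")
random_algorithms <- c("random_string", "random_number")

#' Pseudonymization algorithm names
#'
#' The nine supported generation algorithms: six salted hashes plus a
#' consecutive counter and two random generators (`random_number` draws
#' over the digits alphabet, `random_string` over the domain's alphabet).
#'
#' @return Character vector of algorithm names.
#' @export
pseudonym_algorithms <- function() {
  c(hash_algorithms, "consecutive", "random_number", "random_string")
}
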