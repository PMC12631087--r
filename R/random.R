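#' Random pseudonym bodies
#'
#' Draws each character uniformly and independently from an alphabet.
#' Two entropy sources are provided: `crypto_sampler()` draws from the
#' operating system CSPRNG (via OpenSSL) with rejection sampling so every
#' character is exactly uniform — this is the production default — and
#' `prng_sampler()` draws from R's seedable generator, intended for tests
#' and reproducible benchmarks only (a seeded generator makes pseudonyms
#' predictable and must not protect real identifiers).
#'
#' @param length Number of characters to draw (>= 1).
#' @param alphabet A [pseudonym_alphabet] or built-in alphabet name.
#' @param rng A sampler: `function(n, k)` returning `n` integers uniform
#'   on `1..k`.
#' @return A string of exactly `length` characters from `alphabet`.
#' @examples
#' set.seed(1)
#' random_body(8, "alphanumeric", prng_sampler())
#' @export
random_body <- function(length, alphabet, rng = crypto_sampler()) {
  if (!is.numeric(length) || length < 1L) {
    err_validation("length must be >= 1")
  }
  alphabet <- as_alphabet(alphabet)
  idx <- rng(as.integer(length), alphabet$size)
  paste(alphabet$characters[idx], collapse = "")
}

#' @rdname random_body
#' @export
crypto_sampler <- function() {
  function(n, k) {
    stopifnot(k >= 2L, k <= 256L)
    limit <- (256L %/% k) * k          # rejection bound for unbiased mod
    out <- integer(0L)
    while (length(out) < n) {
      b <- as.integer(openssl::rand_bytes(max(2L * (n - length(out)), 16L)))
      b <- b[b < limit]
      out <- c(out, b %% k + 1L)
    }
    out[seq_len(n)]
  }
}

#' @rdname random_body
#' @export
prng_sampler <- function() {
  function(n, k) sample.int(k, n, replace = TRUE)
}

#' Generate a random salt
#'
#' Salts are per-domain random strings mixed into hash inputs; 32 hex
#' characters (128 bits) by default.
#'
#' @param nchar Number of hex characters.
#' @param rng Sampler as in [random_body()].
#' @return Salt string.
#' @export
random_salt <- function(nchar = 32L, rng = crypto_sampler()) {
  random_body(nchar, "hexadecimal", rng)
}
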