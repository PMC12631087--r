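#' Luhn mod N check characters
#'
#' Appending a Luhn mod N check character lets downstream systems detect
#' every single-character substitution and almost all adjacent
#' transpositions in a manually transcribed pseudonym. The algorithm
#' doubles the value of every second character starting from the right,
#' folds doubled values back into the base (`v %/% N + v %% N`), sums, and
#' picks the check character that makes the total a multiple of the
#' alphabet size N.
#'
#' Both functions are vectorised over their first argument.
#'
#' @param payload Character vector; every character must be in `alphabet`.
#' @param alphabet A [pseudonym_alphabet] or built-in alphabet name; its
#'   size is the modulus N.
#' @return `luhn_check_char()`: the check character(s);
#'   `luhn_validate()`: logical, `TRUE` iff the last character of
#'   `candidate` is the correct check character for the preceding payload.
#' @examples
#' luhn_check_char("7992739871", "digits")  # "3"
#' luhn_validate("79927398713", "digits")   # TRUE
#' @export
luhn_check_char <- function(payload, alphabet) {
  alphabet <- as_alphabet(alphabet)
  n <- alphabet$size
  vapply(payload, function(p) {
    v <- alphabet_values(p, alphabet)
    # payload's rightmost character sits next to the future check char,
    # so doubling starts there
    s <- luhn_weighted_sum(v, n, double_rightmost = TRUE)
    alphabet$characters[((n - s %% n) %% n) + 1L]
  }, character(1L), USE.NAMES = FALSE)
}

#' @param candidate Character vector of full strings (payload + check
#'   character), length >= 2 each.
#' @rdname luhn_check_char
#' @export
luhn_validate <- function(candidate, alphabet) {
  alphabet <- as_alphabet(alphabet)
  n <- alphabet$size
  vapply(candidate, function(s) {
    if (nchar(s) < 2L) err_validation("candidate must have payload plus check character")
    v <- alphabet_values(s, alphabet)
    luhn_weighted_sum(v, n, double_rightmost = FALSE) %% n == 0L
  }, logical(1L), USE.NAMES = FALSE)
}

# Weighted Luhn sum of 0-based values v (left to right). When
# double_rightmost is TRUE the rightmost value is doubled (generation over
# a payload); otherwise the rightmost has weight 1 (validation of a full
# string ending in its check character).
luhn_weighted_sum <- function(v, n, double_rightmost) {
  L <- length(v)
  d <- L - seq_along(v)                     # distance from right, 0-based
  doubled <- if (double_rightmost) d %% 2L == 0L else d %% 2L == 1L
  w <- v
  w[doubled] <- v[doubled] * 2L
  w[doubled] <- w[doubled] %/% n + w[doubled] %% n
  sum(w)
}

# Matrix core used by exhaustive property sweeps: rows are equal-length
# payloads given as 0-based value matrices. Returns check values (0-based)
# for all rows at once.
luhn_check_values_matrix <- function(V, n) {
  L <- ncol(V)
  d <- L - seq_len(L)
  doubled <- d %% 2L == 0L
  W <- V
  W[, doubled] <- {
    x <- V[, doubled, drop = FALSE] * 2L
    x %/% n + x %% n
  }
  s <- rowSums(W)
  (n - s %% n) %% n
}

# Matrix validator: rows are full strings (payload + check) as 0-based
# values; TRUE where the Luhn sum is a multiple of n.
luhn_valid_matrix <- function(F, n) {
  L <- ncol(F)
  d <- L - seq_len(L)
  doubled <- d %% 2L == 1L
  W <- F
  W[, doubled] <- {
    x <- F[, doubled, drop = FALSE] * 2L
    x %/% n + x %% n
  }
  rowSums(W) %% n == 0L
}
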