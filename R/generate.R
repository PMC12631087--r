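#' Counter-based pseudonyms
#'
#' Renders the next value of a per-domain counter, left-padded to the
#' configured length. Counters start at 1 and are never inherited between
#' domains. Use with caution: consecutive numbers can leak temporal
#' patterns (the order in which records entered a domain).
#'
#' @param state Current counter state (number of values already issued,
#'   >= 0).
#' @param length Target body length.
#' @param padding_char Single padding character.
#' @return List with `state` (incremented) and `body` (padded rendering).
#' @examples
#' next_counter(10961, 8)$body  # "00010962"
#' @export
next_counter <- function(state, length, padding_char = "0") {
  if (!is.numeric(state) || state < 0) err_validation("counter state must be >= 0")
  new_state <- state + 1
  body <- pad_or_cut(format(new_state, scientific = FALSE, trim = TRUE),
                     length, padding_char, allow_cut = FALSE)
  list(state = new_state, body = body)
}

pad_or_cut <- function(raw, length, padding_char, allow_cut = TRUE) {
  n <- nchar(raw)
  if (n > length) {
    if (!allow_cut) err_counter_overflow(length)
    substr(raw, 1L, length)            # keep leftmost characters
  } else if (n < length) {
    paste0(strrep(padding_char, length - n), raw)
  } else raw
}

#' Format a raw pseudonym body
#'
#' Applies the domain's presentation rules to a raw generated value:
#' left-pads with the padding character or truncates (keeping the leftmost
#' characters) to the configured length, computes the Luhn mod N check
#' character over the prefix-less body, and prepends the prefix. The
#' prefix is routing metadata and is never part of the check-digit
#' payload.
#'
#' @param raw Raw body string (non-empty).
#' @param length Target body length, or `NA` to leave the body as is.
#' @param alphabet Alphabet used for the check-digit computation.
#' @param padding_char,prefix,check_digit Presentation options.
#' @return List with `body`, `check_char` (`NA` if disabled), `prefix` and
#'   `full` (`prefix + body + check_char`).
#' @examples
#' format_pseudonym("42", length = 5, alphabet = "digits", prefix = "PAT-")
#' @export
format_pseudonym <- function(raw, length = NA, alphabet = "digits",
                             padding_char = "0", prefix = "",
                             check_digit = FALSE) {
  if (!nzchar(raw)) err_validation("raw pseudonym body must be non-empty")
  body <- if (is.na(length)) raw else pad_or_cut(raw, length, padding_char)
  check <- NA_character_
  if (isTRUE(check_digit)) check <- luhn_check_char(body, alphabet)
  full <- paste0(prefix, body, if (!is.na(check)) check else "")
  list(body = body, check_char = check, prefix = prefix, full = full)
}

#' Generation configuration
#'
#' The effective (fully materialised) configuration a pseudonym is
#' generated under; normally assembled from a domain by the store, but
#' usable standalone for ad-hoc generation.
#'
#' @param algorithm One of [pseudonym_algorithms()].
#' @param alphabet Alphabet for random generation and check digits.
#' @param length Body length (`NA` = leave raw value unformatted; only
#'   meaningful for hash algorithms).
#' @param padding_char,prefix,check_digit Presentation options.
#' @param salt Salt for hash algorithms.
#' @param retries Maximum draws `m` for random algorithms.
#' @param counter_state Current counter (consecutive algorithm).
#' @param format_hash_length,format_hash_check Whether hash outputs are
#'   length-formatted / check-digit-suffixed. Hash digests are meant for
#'   automated pipelines and stay raw unless a domain explicitly
#'   configures length or check digits.
#' @return A `generation_config` list.
#' @export
generation_config <- function(algorithm, alphabet = "letters", length = NA,
                              padding_char = "0", prefix = "",
                              check_digit = FALSE, salt = "", retries = 3L,
                              counter_state = 0,
                              format_hash_length = FALSE,
                              format_hash_check = FALSE) {
  if (!algorithm %in% pseudonym_algorithms()) {
    pt_abort("unknown_algorithm", sprintf("unknown algorithm '%s'", algorithm))
  }
  structure(list(algorithm = algorithm, alphabet = as_alphabet(alphabet),
                 length = length, padding_char = padding_char,
                 prefix = prefix, check_digit = isTRUE(check_digit),
                 salt = salt, retries = as.integer(retries),
                 counter_state = counter_state,
                 format_hash_length = isTRUE(format_hash_length),
                 format_hash_check = isTRUE(format_hash_check)),
            class = "generation_config")
}

#' Generate one pseudonym
#'
#' Dispatches on the configured algorithm. Random algorithms draw fresh
#' candidates until the uniqueness predicate accepts one, for at most
#' `retries` attempts in total; hash and counter algorithms are
#' deterministic/sequential and attempted once.
#'
#' @param identifier Identifier to pseudonymize (used by hash algorithms;
#'   random and counter algorithms ignore it).
#' @param config A [generation_config()].
#' @param exists Predicate `function(full_pseudonym) -> logical`: does
#'   this pseudonym already exist in the domain?
#' @param rng Sampler as in [random_body()].
#' @return List with `full`, `body`, `check_char`, `prefix`,
#'   `counter_state` (updated state for the consecutive algorithm, else
#'   the input state) and `attempts`.
#' @export
generate_pseudonym <- function(identifier, config,
                               exists = function(p) FALSE,
                               rng = crypto_sampler()) {
  stopifnot(inherits(config, "generation_config"))
  alg <- config$algorithm

  if (alg %in% hash_algorithms) {
    raw <- hash_digest(identifier, config$salt, alg)
    p <- format_pseudonym(
      raw,
      length = if (config$format_hash_length) config$length else NA,
      alphabet = "hexadecimal",
      padding_char = config$padding_char, prefix = config$prefix,
      check_digit = config$format_hash_check && config$check_digit)
    if (exists(p$full)) {
      pt_abort("hash_collision",
               "hash pseudonym already exists for a different identifier")
    }
    return(c(p, list(counter_state = config$counter_state, attempts = 1L)))
  }

  if (alg == "consecutive") {
    nc <- next_counter(config$counter_state, config$length, config$padding_char)
    # counter bodies are decimal whatever the domain's display alphabet,
    # so their check digit is computed over the digits alphabet
    p <- format_pseudonym(nc$body, length = config$length,
                          alphabet = builtin_alphabet("digits"),
                          padding_char = config$padding_char,
                          prefix = config$prefix,
                          check_digit = config$check_digit)
    if (exists(p$full)) {
      err_uniqueness("counter pseudonym already exists in domain")
    }
    return(c(p, list(counter_state = nc$state, attempts = 1L)))
  }

  # random_string / random_number
  body_alphabet <- if (alg == "random_number") builtin_alphabet("digits")
                   else config$alphabet
  for (attempt in seq_len(config$retries)) {
    raw <- random_body(config$length, body_alphabet, rng)
    p <- format_pseudonym(raw, length = config$length,
                          alphabet = body_alphabet,
                          padding_char = config$padding_char,
                          prefix = config$prefix,
                          check_digit = config$check_digit)
    if (!exists(p$full)) {
      return(c(p, list(counter_state = config$counter_state,
                       attempts = attempt)))
    }
  }
  err_exhausted(config$retries)
}
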