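#' Pseudonym alphabets
#'
#' An alphabet is a named, ordered set of distinct single characters used
#' both for random pseudonym generation and as the base of the Luhn mod N
#' check-digit computation. Five alphabets are built in:
#'
#' * `hexadecimal` — `0-9a-f` (size 16), matching the encoding of hash
#'   digests;
#' * `digits` — `0-9` (size 10);
#' * `letters` — `A-Z` (size 26);
#' * `alphanumeric` — `A-Z0-9` (size 36);
#' * `reduced_alphanumeric` — `A-Z0-9` without `B`, `I`, `O` and `S`
#'   (size 32), which are easily confused with digits when pseudonyms are
#'   printed or read aloud.
#'
#' @param name Short identifier for the alphabet.
#' @param characters Either a single string or a character vector of
#'   single characters; must contain at least two distinct characters.
#' @return An object of class `pseudonym_alphabet` with fields `name`,
#'   `characters` (character vector) and `size`.
#' @examples
#' alphabet_size(builtin_alphabet("reduced_alphanumeric"))  # 32
#' pseudonym_alphabet("acgt", "acgt")
#' @export
pseudonym_alphabet <- function(name, characters) {
  if (length(characters) == 1L && nchar(characters) > 1L) {
    characters <- strsplit(characters, "", fixed = TRUE)[[1L]]
  }
  characters <- as.character(characters)
  if (any(nchar(characters) != 1L)) {
    err_validation("alphabet characters must be single characters")
  }
  if (anyDuplicated(characters)) {
    err_validation("alphabet characters must be unique")
  }
  if (length(characters) < 2L) {
    err_validation("an alphabet needs at least 2 characters")
  }
  structure(list(name = as.character(name)[1L], characters = characters,
                 size = length(characters)),
            class = "pseudonym_alphabet")
}

#' @export
print.pseudonym_alphabet <- function(x, ...) {
  cat(sprintf("<alphabet '%s'> size %d: %s\n", x$name, x$size,
              paste(x$characters, collapse = "")))
  invisible(x)
}

.builtin_alphabets <- function() {
  list(
    hexadecimal  = pseudonym_alphabet("hexadecimal", "0123456789abcdef"),
    digits       = pseudonym_alphabet("digits", "0123456789"),
    letters      = pseudonym_alphabet("letters", paste(LETTERS, collapse = "")),
    alphanumeric = pseudonym_alphabet("alphanumeric",
                                      paste0(paste(LETTERS, collapse = ""), "0123456789")),
    reduced_alphanumeric = pseudonym_alphabet(
      "reduced_alphanumeric",
      paste0(paste(setdiff(LETTERS, c("B", "I", "O", "S")), collapse = ""),
             "0123456789"))
  )
}

#' @rdname pseudonym_alphabet
#' @export
builtin_alphabets <- function() .builtin_alphabets()

#' @rdname pseudonym_alphabet
#' @export
builtin_alphabet <- function(name) {
  ab <- .builtin_alphabets()
  if (!name %in% names(ab)) {
    err_validation(sprintf("unknown built-in alphabet '%s' (available: %s)",
                           name, paste(names(ab), collapse = ", ")))
  }
  ab[[name]]
}

#' @rdname pseudonym_alphabet
#' @param x An alphabet, or the name of a built-in one.
#' @export
alphabet_size <- function(x) as_alphabet(x)$size

as_alphabet <- function(x) {
  if (inherits(x, "pseudonym_alphabet")) return(x)
  if (is.character(x) && length(x) == 1L) return(builtin_alphabet(x))
  err_validation("expected an alphabet object or built-in alphabet name")
}

# Map characters of a string to 0-based alphabet values; errors on
# characters outside the alphabet.
alphabet_values <- function(s, alphabet) {
  alphabet <- as_alphabet(alphabet)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  idx <- match(chars, alphabet$characters)
  if (anyNA(idx)) {
    pt_abort("character_not_in_alphabet",
             sprintf("character(s) %s not in alphabet '%s'",
                     paste(unique(chars[is.na(idx)]), collapse = ", "),
                     alphabet$name))
  }
  idx - 1L
}
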