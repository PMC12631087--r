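#' Validity periods
#'
#' A validity period limits the time during which an identifier-pseudonym
#' link (or a whole domain's links) may be resolved, e.g. to implement
#' consent revocation. Either bound may be unbounded (`NA`). Comparisons
#' are half-open: a time `t` is inside the period iff `start <= t < end`.
#' All timestamps are handled in UTC.
#'
#' @param start,end `POSIXct`, a parseable timestamp string, a numeric
#'   epoch-second value, or `NA` for unbounded.
#' @return An object of class `validity_period` holding numeric epoch
#'   seconds (`NA` = unbounded).
#' @examples
#' vp <- validity_period("2024-01-01", "2025-01-01")
#' validity_contains(vp, as.POSIXct("2024-06-01", tz = "UTC"))
#' @export
validity_period <- function(start = NA, end = NA) {
  start <- as_epoch(start)
  end <- as_epoch(end)
  if (!is.na(start) && !is.na(end) && start > end) {
    err_validation("validity start must not be after validity end")
  }
  structure(list(start = start, end = end), class = "validity_period")
}

as_epoch <- function(x) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) return(NA_real_)
  if (inherits(x, "POSIXt")) return(as.numeric(x))
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x)) {
    t <- suppressWarnings(as.POSIXct(x, tz = "UTC"))
    if (is.na(t)) err_validation(sprintf("cannot parse timestamp '%s'", x))
    return(as.numeric(t))
  }
  err_validation("unsupported timestamp type")
}

#' @rdname validity_period
#' @param period A `validity_period`.
#' @param at Time to test (same types as `start`).
#' @export
validity_contains <- function(period, at) {
  t <- as_epoch(at)
  (is.na(period$start) || period$start <= t) &&
    (is.na(period$end) || t < period$end)
}

#' @export
print.validity_period <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "unbounded" else
    format(as.POSIXct(v, tz = "UTC", origin = "1970-01-01"), usetz = TRUE)
  cat(sprintf("<validity [%s, %s)>\n", fmt(x$start), fmt(x$end)))
  invisible(x)
}
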