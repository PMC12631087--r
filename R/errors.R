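# Classed error conditions used throughout the package. Every public
# operation fails with a condition of class "pseudotree_error_<code>" so
# callers (and the endpoint router) can dispatch on the failure mode
# rather than parse messages.

pt_abort <- function(code, message, ...) {
  cond <- structure(
    class = c(paste0("pseudotree_error_", code), "pseudotree_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), code = code, ...)
  )
  stop(cond)
}

#' @export
print.pseudotree_error <- function(x, ...) {
  cat(sprintf("<pseudotree error: %s> %s\n", x$code, conditionMessage(x)))
  invisible(x)
}

# Shorthand constructors for the recurring failure modes.
err_not_found       <- function(what) pt_abort("not_found", paste0(what, " not found"))
err_duplicate_name  <- function(name) pt_abort("duplicate_name", sprintf("domain name '%s' already in use", name))
err_privilege       <- function(what) pt_abort("privilege_violation", paste0("privileged access required: ", what))
err_domain_not_empty<- function(name, why) pt_abort("domain_not_empty", sprintf("domain '%s' is not empty: %s", name, why))
err_unknown_attr    <- function(attr) pt_abort("unknown_attribute", sprintf("unknown domain attribute '%s'", attr))
err_unauthorized    <- function(msg = "access denied") pt_abort("unauthorized", msg)
err_expired         <- function(msg = "record outside its validity period") pt_abort("expired", msg)
err_exhausted       <- function(m) pt_abort("exhausted_retries", sprintf("no unused pseudonym found within %d attempts", m))
err_counter_overflow<- function(len) pt_abort("counter_overflow", sprintf("counter value no longer fits in %d characters", len))
err_uniqueness      <- function(msg) pt_abort("uniqueness_violation", msg)
err_validation      <- function(msg) pt_abort("validation_error", msg)
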