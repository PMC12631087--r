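# Pseudonym records: the central fact table linking identifiers to
# pseudonyms, each link carrying its own validity period with
# per-attribute inheritance flags mirroring the domain mechanism.

record_from_row <- function(row) {
  structure(list(
    domain = row$domain,
    identifier = row$identifier,
    pseudonym = row$pseudonym,
    validity = validity_period(row$validity_start, row$validity_end),
    inherited = c("validity.start" = as.logical(row$validity_start_inherited),
                  "validity.end"   = as.logical(row$validity_end_inherited)),
    created_at = row$created_at,
    updated_at = row$updated_at
  ), class = "pseudonym_record")
}

#' @export
print.pseudonym_record <- function(x, ...) {
  cat(sprintf("<pseudonym '%s' <-> '%s' in domain '%s'>\n",
              x$identifier, x$pseudonym, x$domain))
  invisible(x)
}

record_row <- function(store, domain, key, by = c("identifier", "pseudonym")) {
  by <- match.arg(by)
  DBI::dbGetQuery(store$con,
    sprintf("SELECT * FROM pseudonym WHERE domain = ? AND %s = ?", by),
    params = list(domain, key))
}

#' Create (pseudonymize) an identifier in a domain
#'
#' Generates a pseudonym for `identifier` under the domain's effective
#' configuration and stores the protected link. Creation is idempotent:
#' if the identifier is already mapped in the domain, the existing record
#' is returned unchanged, so batch re-runs are safe. The record's
#' validity period is inherited from the domain unless bounds are given
#' explicitly (each bound inherits independently).
#'
#' @param store A [pseudonym_store()].
#' @param domain Domain name.
#' @param identifier Identifier to pseudonymize.
#' @param validity_start,validity_end Explicit validity bounds (`NULL` =
#'   inherit from the domain; `NA` = unbounded).
#' @param actor,actor_class Audit attribution.
#' @return A `pseudonym_record`.
#' @export
pseudonym_create <- function(store, domain, identifier,
                             validity_start = NULL, validity_end = NULL,
                             actor = "system", actor_class = "technical") {
  audited(store, "pseudonym_create", "create", domain, actor, actor_class, {
    drow <- require_domain(store, domain)
    if (!nzchar(identifier)) err_validation("identifier must be non-empty")
    existing <- record_row(store, domain, identifier, "identifier")
    if (nrow(existing)) return(record_from_row(existing))

    cfg <- build_generation_config(drow)
    exists_in_domain <- function(p) {
      nrow(record_row(store, domain, p, "pseudonym")) > 0L
    }
    gen <- generate_pseudonym(identifier, cfg, exists = exists_in_domain,
                              rng = store$rng)
    if (cfg$algorithm == "consecutive") {
      DBI::dbExecute(store$con,
        "UPDATE domain SET counter_state = ? WHERE name = ?",
        params = list(gen$counter_state, domain))
    }

    vs <- if (is.null(validity_start)) drow$validity_start else as_epoch(validity_start)
    ve <- if (is.null(validity_end)) drow$validity_end else as_epoch(validity_end)
    now <- as.numeric(Sys.time())
    DBI::dbExecute(store$con,
      "INSERT INTO pseudonym (domain, identifier, pseudonym,
         validity_start, validity_start_inherited,
         validity_end, validity_end_inherited, created_at, updated_at)
       VALUES (?,?,?,?,?,?,?,?,?)",
      params = list(domain, identifier, gen$full,
                    vs, as.integer(is.null(validity_start)),
                    ve, as.integer(is.null(validity_end)), now, now))
    record_from_row(record_row(store, domain, identifier, "identifier"))
  })
}

#' Resolve a pseudonym link
#'
#' Looks a record up by identifier (pseudonymize direction) or by
#' pseudonym (depseudonymize direction — gate this behind separate
#' authorization). The link is only returned while `at` lies inside the
#' record's validity period (half-open `[start, end)`); outside it an
#' `expired` error is raised. Lookups, including failed ones, are
#' audited.
#'
#' @param store A [pseudonym_store()].
#' @param domain Domain name.
#' @param key Identifier or pseudonym, per `direction`.
#' @param direction `"identifier"` (find the pseudonym) or `"pseudonym"`
#'   (find the identifier).
#' @param at Resolution time (default: now).
#' @param actor,actor_class Audit attribution.
#' @return A `pseudonym_record`.
#' @export
pseudonym_resolve <- function(store, domain, key,
                              direction = c("identifier", "pseudonym"),
                              at = Sys.time(), actor = "system",
                              actor_class = "technical") {
  direction <- match.arg(direction)
  audited(store, "pseudonym_resolve", "read", domain, actor, actor_class, {
    require_domain(store, domain)
    row <- record_row(store, domain, key, direction)
    if (nrow(row) == 0L) {
      err_not_found(sprintf("%s '%s' in domain '%s'", direction, key, domain))
    }
    rec <- record_from_row(row)
    if (!validity_contains(rec$validity, at)) err_expired()
    rec
  })
}

#' Update a pseudonym record
#'
#' Standard callers may only change the validity period; changing the
#' pseudonym string itself requires the privileged variant, which
#' re-checks `(domain, pseudonym)` uniqueness. Changed validity bounds
#' are flagged overwritten.
#'
#' @inheritParams pseudonym_resolve
#' @param pseudonym The record's pseudonym.
#' @param validity_start,validity_end New bounds (`NULL` = unchanged,
#'   `NA` = unbounded).
#' @param new_pseudonym Replacement pseudonym (privileged only).
#' @param privileged Caller holds elevated rights?
#' @return The updated `pseudonym_record`.
#' @export
pseudonym_update <- function(store, domain, pseudonym,
                             validity_start = NULL, validity_end = NULL,
                             new_pseudonym = NULL, privileged = FALSE,
                             actor = "system", actor_class = "technical") {
  audited(store, "pseudonym_update", "update", domain, actor, actor_class, {
    require_domain(store, domain)
    row <- record_row(store, domain, pseudonym, "pseudonym")
    if (nrow(row) == 0L) {
      err_not_found(sprintf("pseudonym '%s' in domain '%s'", pseudonym, domain))
    }
    if (!is.null(new_pseudonym) && !privileged) err_privilege("changing the pseudonym")
    now <- as.numeric(Sys.time())
    if (!is.null(validity_start)) {
      DBI::dbExecute(store$con,
        "UPDATE pseudonym SET validity_start = ?, validity_start_inherited = 0,
           updated_at = ? WHERE domain = ? AND pseudonym = ?",
        params = list(as_epoch(validity_start), now, domain, pseudonym))
    }
    if (!is.null(validity_end)) {
      DBI::dbExecute(store$con,
        "UPDATE pseudonym SET validity_end = ?, validity_end_inherited = 0,
           updated_at = ? WHERE domain = ? AND pseudonym = ?",
        params = list(as_epoch(validity_end), now, domain, pseudonym))
    }
    key <- pseudonym
    if (!is.null(new_pseudonym)) {
      if (nrow(record_row(store, domain, new_pseudonym, "pseudonym"))) {
        err_uniqueness(sprintf("pseudonym '%s' already used in domain '%s'",
                               new_pseudonym, domain))
      }
      DBI::dbExecute(store$con,
        "UPDATE pseudonym SET pseudonym = ?, updated_at = ?
           WHERE domain = ? AND pseudonym = ?",
        params = list(new_pseudonym, now, domain, pseudonym))
      key <- new_pseudonym
    }
    record_from_row(record_row(store, domain, key, "pseudonym"))
  })
}

#' Delete a pseudonym record
#'
#' The record's audit history is retained until it expires under the
#' configured retention period.
#'
#' @inheritParams pseudonym_update
#' @return `TRUE`, invisibly.
#' @export
pseudonym_delete <- function(store, domain, pseudonym,
                             actor = "system", actor_class = "technical") {
  audited(store, "pseudonym_delete", "delete", domain, actor, actor_class, {
    require_domain(store, domain)
    n <- DBI::dbExecute(store$con,
      "DELETE FROM pseudonym WHERE domain = ? AND pseudonym = ?",
      params = list(domain, pseudonym))
    if (n == 0L) {
      err_not_found(sprintf("pseudonym '%s' in domain '%s'", pseudonym, domain))
    }
    invisible(TRUE)
  })
}

#' Batch processing of pseudonyms
#'
#' Executes one operation over many items inside a single transaction.
#' Item-level failures (unknown key, exhausted retries, ...) are reported
#' per item without aborting the rest; only a storage-level failure rolls
#' the whole batch back. Each item is audited individually so the access
#' history of every pseudonym stays complete.
#'
#' @param store A [pseudonym_store()].
#' @param domain Domain name.
#' @param operation `"create"`, `"read"`, `"update"` or `"delete"`.
#' @param items For create: identifiers; for read/delete: keys; for
#'   update: a list of argument lists for [pseudonym_update()].
#' @param direction Lookup direction for reads.
#' @param privileged Passed through to updates.
#' @param actor,actor_class Audit attribution.
#' @return Data frame with one row per item: `key`, `ok`, `result`
#'   (pseudonym or identifier), `error` (failure code or `NA`).
#' @export
pseudonym_batch <- function(store, domain,
                            operation = c("create", "read", "update", "delete"),
                            items, direction = "identifier",
                            privileged = FALSE, actor = "system",
                            actor_class = "technical") {
  operation <- match.arg(operation)
  if (length(items) < 1L) err_validation("batch requires at least one item")
  with_transaction(store, {
    require_domain(store, domain)
    rows <- lapply(seq_along(items), function(i) {
      item <- items[[i]]
      key <- if (operation == "update") item$pseudonym else item
      res <- tryCatch({
        out <- switch(operation,
          create = pseudonym_create(store, domain, item,
                                    actor = actor, actor_class = actor_class),
          read   = pseudonym_resolve(store, domain, item, direction = direction,
                                     actor = actor, actor_class = actor_class),
          update = do.call(pseudonym_update,
                           c(list(store, domain), item,
                             list(privileged = privileged, actor = actor,
                                  actor_class = actor_class))),
          delete = pseudonym_delete(store, domain, item,
                                    actor = actor, actor_class = actor_class))
        val <- if (isTRUE(out)) NA_character_
               else if (direction == "pseudonym" && operation == "read") out$identifier
               else out$pseudonym
        list(ok = TRUE, result = val, error = NA_character_)
      }, pseudotree_error = function(e) {
        list(ok = FALSE, result = NA_character_, error = e$code)
      })
      data.frame(key = key, ok = res$ok, result = res$result,
                 error = res$error, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
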