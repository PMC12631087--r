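# Hierarchical domains. Each domain row stores the materialised value of
# every inheritable attribute together with a flag marking it inherited
# (copied from the parent and tracking it under propagation) or
# overwritten (explicitly set). Salt and counter state are strictly
# per-domain and never inherit.

# Canonical inheritable attribute names (validity bounds inherit
# independently of each other).
inheritable_attributes <- function() {
  c("algorithm", "alphabet", "length", "padding_char", "prefix",
    "check_digit", "retries", "capacity_target", "success_threshold",
    "validity.start", "validity.end")
}

# attribute name -> db value column
attr_column <- function(attr) {
  switch(attr,
    "validity.start" = "validity_start",
    "validity.end"   = "validity_end",
    "alphabet"       = "alphabet_chars",
    attr)
}
attr_flag_column <- function(attr) {
  paste0(sub("alphabet_chars", "alphabet",
             sub("validity_", "validity_", attr_column(attr))), "_inherited")
}

privileged_create_attrs <- c("salt", "length", "padding_char")

domain_row <- function(store, name) {
  DBI::dbGetQuery(store$con, "SELECT * FROM domain WHERE name = ?",
                  params = list(name))
}

domain_exists <- function(store, name) nrow(domain_row(store, name)) > 0L

require_domain <- function(store, name) {
  row <- domain_row(store, name)
  if (nrow(row) == 0L) err_not_found(sprintf("domain '%s'", name))
  row
}

domain_children <- function(store, name) {
  DBI::dbGetQuery(store$con, "SELECT name FROM domain WHERE parent = ?",
                  params = list(name))$name
}

domain_record_count <- function(store, name) {
  DBI::dbGetQuery(store$con,
    "SELECT COUNT(*) AS n FROM pseudonym WHERE domain = ?",
    params = list(name))$n
}

# Defaults applied to root domains when an attribute is not specified.
root_defaults <- function() {
  list(algorithm = "random_string",
       alphabet = builtin_alphabet("letters"),
       length = NULL,                   # auto-computed from q, m, T, a
       padding_char = "0",
       prefix = "",
       check_digit = TRUE,
       retries = 3L,
       capacity_target = 1e8,
       success_threshold = 0.99999998,
       validity.start = NA_real_,
       validity.end = NA_real_)
}

#' Create a domain
#'
#' A domain is a named pseudonym space carrying the full generation
#' configuration. Unspecified inheritable attributes are copied from the
#' parent (flagged *inherited*); explicitly supplied values are flagged
#' *overwritten*. Root domains fall back to the package defaults
#' (random 10-character letter strings with check digits, sized for
#' `q = 1e8` pseudonyms at `T = 0.99999998` with `m = 3` retries). When no
#' length is given it is auto-computed from the capacity target via
#' [required_length()]. Every domain receives its own random salt; salts
#' never inherit, so identical identifiers stay unlinkable across domains.
#'
#' Salt, length and padding character may only be supplied by privileged
#' callers.
#'
#' @param store A [pseudonym_store()].
#' @param name Unique domain name.
#' @param parent Optional parent domain name.
#' @param algorithm,alphabet,length,padding_char,prefix,check_digit,retries
#'   Generation configuration; `NULL` means inherit/default.
#' @param capacity_target Maximum number of pseudonyms the domain must
#'   hold (`q`).
#' @param success_threshold Minimum fill-success probability (`T`).
#' @param validity_start,validity_end Validity bounds (each `NULL` =
#'   inherit/unbounded; they inherit independently).
#' @param salt Explicit salt (privileged; random when absent).
#' @param privileged Caller holds elevated rights?
#' @param actor,actor_class Audit attribution.
#' @return The created domain configuration (`domain_config`).
#' @export
domain_create <- function(store, name, parent = NULL,
                          algorithm = NULL, alphabet = NULL, length = NULL,
                          padding_char = NULL, prefix = NULL,
                          check_digit = NULL, retries = NULL,
                          capacity_target = NULL, success_threshold = NULL,
                          validity_start = NULL, validity_end = NULL,
                          salt = NULL, privileged = FALSE,
                          actor = "system", actor_class = "technical") {
  given <- list(algorithm = algorithm, alphabet = alphabet, length = length,
                padding_char = padding_char, prefix = prefix,
                check_digit = check_digit, retries = retries,
                capacity_target = capacity_target,
                success_threshold = success_threshold,
                "validity.start" = validity_start,
                "validity.end" = validity_end)

  audited(store, "domain_create", "create", name, actor, actor_class, {
    if (domain_exists(store, name)) err_duplicate_name(name)
    if (!is.null(parent) && !domain_exists(store, parent)) {
      err_not_found(sprintf("parent domain '%s'", parent))
    }
    if (!privileged) {
      supplied <- c("salt"[!is.null(salt)], "length"[!is.null(length)],
                    "padding_char"[!is.null(padding_char)])
      if (length(supplied)) err_privilege(paste(supplied, collapse = ", "))
    }

    prow <- if (!is.null(parent)) domain_row(store, parent) else NULL
    defaults <- root_defaults()
    value <- list(); inherited <- list()
    for (attr in inheritable_attributes()) {
      if (!is.null(given[[attr]])) {
        value[[attr]] <- given[[attr]]
        inherited[[attr]] <- FALSE
      } else if (!is.null(prow)) {
        value[[attr]] <- parent_attr_value(prow, attr)
        inherited[[attr]] <- TRUE
      } else {
        value[[attr]] <- defaults[[attr]]
        inherited[[attr]] <- FALSE
      }
    }

    value <- validate_domain_values(value)
    if (is.null(value$length)) {
      value$length <- required_length(value$capacity_target, value$retries,
                                      value$success_threshold,
                                      value$alphabet$size)
      inherited$length <- FALSE
    }
    if (is.null(salt)) salt <- random_salt(rng = store$rng)

    now <- as.numeric(Sys.time())
    DBI::dbExecute(store$con,
      "INSERT INTO domain (name, parent,
         algorithm, algorithm_inherited,
         alphabet_name, alphabet_chars, alphabet_inherited,
         length, length_inherited, length_explicit,
         padding_char, padding_char_inherited,
         prefix, prefix_inherited,
         check_digit, check_digit_inherited, check_digit_explicit,
         retries, retries_inherited,
         capacity_target, capacity_target_inherited,
         success_threshold, success_threshold_inherited,
         validity_start, validity_start_inherited,
         validity_end, validity_end_inherited,
         salt, counter_state, created_at, updated_at)
       VALUES (?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?,?)",
      params = list(name, if (is.null(parent)) NA_character_ else parent,
        value$algorithm, as.integer(inherited$algorithm),
        value$alphabet$name, paste(value$alphabet$characters, collapse = ""),
        as.integer(inherited$alphabet),
        as.integer(value$length), as.integer(inherited$length),
        as.integer(!is.null(given$length)),
        value$padding_char, as.integer(inherited$padding_char),
        value$prefix, as.integer(inherited$prefix),
        as.integer(value$check_digit), as.integer(inherited$check_digit),
        as.integer(!is.null(given$check_digit)),
        as.integer(value$retries), as.integer(inherited$retries),
        as.numeric(value$capacity_target),
        as.integer(inherited$capacity_target),
        as.numeric(value$success_threshold),
        as.integer(inherited$success_threshold),
        value[["validity.start"]], as.integer(inherited[["validity.start"]]),
        value[["validity.end"]], as.integer(inherited[["validity.end"]]),
        salt, 0, now, now))
    domain_config_from_row(domain_row(store, name), privileged = privileged)
  })
}

parent_attr_value <- function(prow, attr) {
  switch(attr,
    alphabet = pseudonym_alphabet(prow$alphabet_name, prow$alphabet_chars),
    "validity.start" = prow$validity_start,
    "validity.end"   = prow$validity_end,
    check_digit = as.logical(prow$check_digit),
    prow[[attr]])
}

validate_domain_values <- function(v) {
  if (!v$algorithm %in% pseudonym_algorithms()) {
    pt_abort("unknown_algorithm", sprintf("unknown algorithm '%s'", v$algorithm))
  }
  v$alphabet <- as_alphabet(v$alphabet)
  if (!is.null(v$length) && (!is.numeric(v$length) || v$length < 1)) {
    err_validation("length must be a positive integer")
  }
  if (nchar(v$padding_char) != 1L) err_validation("padding_char must be a single character")
  if (!is.numeric(v$retries) || v$retries < 1) err_validation("retries must be >= 1")
  if (!is.numeric(v$capacity_target) || v$capacity_target < 1) {
    err_validation("capacity_target must be >= 1")
  }
  if (!(v$success_threshold > 0 && v$success_threshold < 1)) {
    err_validation("success_threshold must be in (0, 1)")
  }
  v[["validity.start"]] <- as_epoch(v[["validity.start"]])
  v[["validity.end"]] <- as_epoch(v[["validity.end"]])
  if (!is.na(v[["validity.start"]]) && !is.na(v[["validity.end"]]) &&
      v[["validity.start"]] > v[["validity.end"]]) {
    err_validation("validity start must not be after validity end")
  }
  v$check_digit <- isTRUE(as.logical(v$check_digit))
  v
}

domain_config_from_row <- function(row, privileged = FALSE) {
  attrs <- inheritable_attributes()
  inherited <- vapply(attrs, function(a) as.logical(row[[attr_flag_column(a)]]),
                      logical(1))
  structure(list(
    name = row$name,
    parent = if (is.na(row$parent)) NULL else row$parent,
    algorithm = row$algorithm,
    alphabet = pseudonym_alphabet(row$alphabet_name, row$alphabet_chars),
    length = row$length,
    padding_char = row$padding_char,
    prefix = row$prefix,
    check_digit = as.logical(row$check_digit),
    retries = row$retries,
    capacity_target = row$capacity_target,
    success_threshold = row$success_threshold,
    validity = validity_period(row$validity_start, row$validity_end),
    counter_state = row$counter_state,
    salt = if (privileged) row$salt else NULL,
    inherited = inherited
  ), class = "domain_config")
}

#' @export
print.domain_config <- function(x, ...) {
  cat(sprintf("<domain '%s'>%s\n", x$name,
              if (is.null(x$parent)) "" else paste0(" parent: ", x$parent)))
  flag <- function(a) if (x$inherited[[a]]) "inherited" else "overwritten"
  cat(sprintf("  algorithm: %s (%s), alphabet: %s (a=%d, %s), length: %d (%s)\n",
              x$algorithm, flag("algorithm"), x$alphabet$name,
              x$alphabet$size, flag("alphabet"), x$length, flag("length")))
  cat(sprintf("  check_digit: %s, retries: %d, q: %g, T: %.8f\n",
              x$check_digit, x$retries, x$capacity_target,
              x$success_threshold))
  invisible(x)
}

#' Read a domain
#'
#' @param store A [pseudonym_store()].
#' @param name Domain name.
#' @param privileged Include the salt in the result?
#' @param actor,actor_class Audit attribution.
#' @return A `domain_config`.
#' @export
domain_get <- function(store, name, privileged = FALSE,
                       actor = "system", actor_class = "technical") {
  audited(store, "domain_get", "read", name, actor, actor_class, {
    domain_config_from_row(require_domain(store, name), privileged = privileged)
  })
}

#' Read one domain attribute with its inheritance flag
#'
#' @inheritParams domain_get
#' @param attribute One of the inheritable attribute names
#'   (`"validity.start"` / `"validity.end"` for the validity bounds) or
#'   `"salt"` (privileged callers only).
#' @return List with `value` and `inherited`.
#' @export
domain_attribute <- function(store, name, attribute, privileged = FALSE,
                             actor = "system", actor_class = "technical") {
  audited(store, "domain_attribute", "read", name, actor, actor_class, {
    row <- require_domain(store, name)
    if (attribute == "salt") {
      if (!privileged) err_privilege("salt")
      return(list(value = row$salt, inherited = FALSE))
    }
    if (!attribute %in% inheritable_attributes()) err_unknown_attr(attribute)
    list(value = parent_attr_value(row, attribute),
         inherited = as.logical(row[[attr_flag_column(attribute)]]))
  })
}

#' Update a domain, optionally propagating to inheriting descendants
#'
#' Each changed attribute is flagged *overwritten* on the target. With
#' `propagate = TRUE` the new value also descends recursively into child
#' domains — but only where the child's flag for that attribute is
#' *inherited*; an overwritten descendant is untouched and shields its own
#' subtree. Changes to the validity bounds additionally descend into
#' pseudonym records whose corresponding flag is inherited. Changing
#' generation parameters only affects future pseudonyms; existing records
#' are never rewritten.
#'
#' @inheritParams domain_get
#' @param changes Named list of attribute changes (inheritable attributes
#'   only; use `"validity.start"` / `"validity.end"` for validity bounds,
#'   value `NA` = unbounded).
#' @param propagate Propagate into inheriting descendants?
#' @param privileged Required to change length or padding_char.
#' @return List with the names of updated `domains` and the number of
#'   updated pseudonym `records`, invisibly.
#' @export
domain_update <- function(store, name, changes, propagate = FALSE,
                          privileged = FALSE, actor = "system",
                          actor_class = "technical") {
  invisible(audited(store, "domain_update", "update", name, actor, actor_class, {
    require_domain(store, name)
    bad <- setdiff(names(changes), inheritable_attributes())
    if (length(bad)) err_unknown_attr(paste(bad, collapse = ", "))
    priv_only <- intersect(names(changes), c("length", "padding_char"))
    if (length(priv_only) && !privileged) {
      err_privilege(paste(priv_only, collapse = ", "))
    }

    affected_domains <- character(0)
    affected_records <- 0L
    for (attr in names(changes)) {
      val <- normalize_attr_value(attr, changes[[attr]])
      set_domain_attr(store, name, attr, val, inherited = FALSE,
                      explicit = TRUE)
      affected_domains <- union(affected_domains, name)
      if (propagate) {
        res <- propagate_attr(store, name, attr, val)
        affected_domains <- union(affected_domains, res$domains)
        affected_records <- affected_records + res$records
      }
    }
    list(domains = affected_domains, records = affected_records)
  }))
}

normalize_attr_value <- function(attr, val) {
  switch(attr,
    alphabet = as_alphabet(val),
    "validity.start" = as_epoch(val),
    "validity.end"   = as_epoch(val),
    check_digit = isTRUE(as.logical(val)),
    algorithm = {
      if (!val %in% pseudonym_algorithms())
        pt_abort("unknown_algorithm", sprintf("unknown algorithm '%s'", val))
      val
    },
    length = { if (!is.numeric(val) || val < 1) err_validation("length must be >= 1"); as.integer(val) },
    retries = { if (!is.numeric(val) || val < 1) err_validation("retries must be >= 1"); as.integer(val) },
    padding_char = { if (nchar(val) != 1L) err_validation("padding_char must be a single character"); val },
    val)
}

set_domain_attr <- function(store, name, attr, val, inherited, explicit = FALSE) {
  now <- as.numeric(Sys.time())
  if (attr == "alphabet") {
    al <- as_alphabet(val)
    DBI::dbExecute(store$con,
      "UPDATE domain SET alphabet_name = ?, alphabet_chars = ?,
         alphabet_inherited = ?, updated_at = ? WHERE name = ?",
      params = list(al$name, paste(al$characters, collapse = ""),
                    as.integer(inherited), now, name))
    return(invisible())
  }
  col <- attr_column(attr)
  flag <- attr_flag_column(attr)
  sql_val <- switch(attr,
    check_digit = as.integer(val),
    "validity.start" = if (is.na(val)) NA_real_ else as.numeric(val),
    "validity.end"   = if (is.na(val)) NA_real_ else as.numeric(val),
    val)
  extra <- ""
  if (explicit && attr %in% c("length", "check_digit")) {
    extra <- sprintf(", %s_explicit = 1", attr)
  }
  DBI::dbExecute(store$con,
    sprintf("UPDATE domain SET %s = ?, %s = ?%s, updated_at = ? WHERE name = ?",
            col, flag, extra),
    params = list(sql_val, as.integer(inherited), now, name))
  invisible()
}

# Recursively push `val` for `attr` into inheriting children (and
# inheriting pseudonym records for the validity bounds). An overwritten
# child blocks descent into its subtree.
propagate_attr <- function(store, domain, attr, val) {
  domains <- character(0)
  records <- 0L
  if (attr %in% c("validity.start", "validity.end")) {
    col <- attr_column(attr)
    records <- records + DBI::dbExecute(store$con,
      sprintf("UPDATE pseudonym SET %s = ?, updated_at = ?
               WHERE domain = ? AND %s_inherited = 1", col, col),
      params = list(if (is.na(val)) NA_real_ else as.numeric(val),
                    as.numeric(Sys.time()), domain))
  }
  flag <- attr_flag_column(attr)
  kids <- domain_children(store, domain)
  for (kid in kids) {
    krow <- domain_row(store, kid)
    if (!as.logical(krow[[flag]])) next   # overwritten: blocks its subtree
    set_domain_attr(store, kid, attr, val, inherited = TRUE)
    domains <- c(domains, kid)
    res <- propagate_attr(store, kid, attr, val)
    domains <- c(domains, res$domains)
    records <- records + res$records
  }
  list(domains = domains, records = records)
}

#' Overwrite the salt of an empty domain
#'
#' Only allowed while the domain holds no pseudonym records, since
#' changing the salt would silently break the determinism of existing
#' hash-based pseudonyms.
#'
#' @inheritParams domain_get
#' @param salt New salt string.
#' @return The updated `domain_config` (with salt, as this is a
#'   privileged operation).
#' @export
domain_set_salt <- function(store, name, salt, actor = "system",
                            actor_class = "technical") {
  audited(store, "domain_set_salt", "update", name, actor, actor_class, {
    require_domain(store, name)
    if (domain_record_count(store, name) > 0L) {
      err_domain_not_empty(name, "it already holds pseudonym records")
    }
    DBI::dbExecute(store$con,
      "UPDATE domain SET salt = ?, updated_at = ? WHERE name = ?",
      params = list(salt, as.numeric(Sys.time()), name))
    domain_config_from_row(domain_row(store, name), privileged = TRUE)
  })
}

#' Delete an empty leaf domain
#'
#' A domain can only be deleted when it has no child domains and holds no
#' pseudonym records.
#'
#' @inheritParams domain_get
#' @return `TRUE`, invisibly.
#' @export
domain_delete <- function(store, name, actor = "system",
                          actor_class = "technical") {
  audited(store, "domain_delete", "delete", name, actor, actor_class, {
    require_domain(store, name)
    if (length(domain_children(store, name))) {
      err_domain_not_empty(name, "it has child domains")
    }
    if (domain_record_count(store, name) > 0L) {
      err_domain_not_empty(name, "it holds pseudonym records")
    }
    DBI::dbExecute(store$con, "DELETE FROM domain WHERE name = ?",
                   params = list(name))
    invisible(TRUE)
  })
}

domain_ancestry <- function(store, name) {
  path <- character(0)
  cur <- name
  while (!is.null(cur) && !is.na(cur)) {
    if (cur %in% path) err_validation(sprintf("cycle in domain tree at '%s'", cur))
    path <- c(path, cur)
    cur <- domain_row(store, cur)$parent
  }
  path                                  # self first, root last
}

#' Deepest common ancestor of two domains
#'
#' @inheritParams domain_get
#' @param d1,d2 Domain names.
#' @return The name of the deepest domain that is an ancestor-or-self of
#'   both, or `NULL` when the domains live in disjoint trees.
#' @export
domain_common_ancestor <- function(store, d1, d2) {
  require_domain(store, d1)
  require_domain(store, d2)
  a1 <- domain_ancestry(store, d1)
  a2 <- domain_ancestry(store, d2)
  common <- a1[a1 %in% a2]
  if (!length(common)) NULL else common[[1L]]
}

# Effective generation configuration for a domain row. Hash outputs stay
# raw (no padding/cutting, no check digit) unless the domain explicitly
# configured length or check digits.
build_generation_config <- function(row) {
  generation_config(
    algorithm = row$algorithm,
    alphabet = pseudonym_alphabet(row$alphabet_name, row$alphabet_chars),
    length = row$length,
    padding_char = row$padding_char,
    prefix = row$prefix,
    check_digit = as.logical(row$check_digit),
    salt = row$salt,
    retries = row$retries,
    counter_state = row$counter_state,
    format_hash_length = as.logical(row$length_explicit),
    format_hash_check = as.logical(row$check_digit_explicit))
}

#' Export / import domain configurations
#'
#' Serialises all domains (parents referenced by name) as pretty-printed
#' JSON; the import recreates them in an empty store, parents first.
#' Salts are included, so treat exports as sensitive.
#'
#' @param store A [pseudonym_store()].
#' @param path Optional file; when `NULL`, `domain_export()` returns the
#'   JSON string.
#' @return `domain_export()`: JSON string (invisibly when writing a
#'   file); `domain_import()`: the names of the created domains.
#' @export
domain_export <- function(store, path = NULL) {
  rows <- DBI::dbGetQuery(store$con, "SELECT * FROM domain ORDER BY name")
  json <- jsonlite::toJSON(rows, auto_unbox = TRUE, pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(as.character(json))
}

#' @rdname domain_export
#' @param json JSON string or file path produced by `domain_export()`.
#' @export
domain_import <- function(store, json) {
  if (nchar(json) < 1000L && file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  rows <- jsonlite::fromJSON(json)
  if (nrow(rows) == 0L) return(character(0))
  done <- character(0)
  with_transaction(store, {
    remaining <- rows
    while (nrow(remaining) > 0L) {
      ready <- is.na(remaining$parent) | remaining$parent %in% done |
        vapply(remaining$parent, function(p) !is.na(p) && domain_exists(store, p),
               logical(1))
      if (!any(ready)) err_validation("domain import: unresolvable parent references")
      for (i in which(ready)) {
        r <- remaining[i, , drop = FALSE]
        cols <- names(r)
        DBI::dbExecute(store$con,
          sprintf("INSERT INTO domain (%s) VALUES (%s)",
                  paste(cols, collapse = ", "),
                  paste(rep("?", length(cols)), collapse = ", ")),
          params = unname(as.list(r)))
        done <- c(done, r$name)
      }
      remaining <- remaining[!ready, , drop = FALSE]
    }
  })
  done
}
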