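#' Open a pseudonym store
#'
#' The store persists domains, identifier-pseudonym links and the audit
#' trail in an embedded SQL database laid out as a star schema: a central
#' `pseudonym` fact table referencing a self-referential `domain`
#' dimension table, plus a stand-alone `audit_event` table. Every
#' attribute that can be inherited carries a companion flag column
#' recording whether its value was inherited or overwritten. All
#' operations run inside database transactions, and audit events commit
#' atomically with the operation they record.
#'
#' @param path Database file path, or `":memory:"` (default) for an
#'   in-memory store.
#' @param retention Audit retention period in seconds (default 10 years).
#'   Events older than this are removed by [audit_purge()].
#' @param random `"crypto"` (operating-system CSPRNG; default) or
#'   `"prng"` (R's seedable generator, for tests and reproducible
#'   benchmarks only).
#' @return A `pseudonym_store` object.
#' @examples
#' store <- pseudonym_store()
#' domain_create(store, "study")
#' pseudonym_create(store, "study", "patient-0001")
#' store_close(store)
#' @export
pseudonym_store <- function(path = ":memory:", retention = 10 * 365.25 * 86400,
                            random = c("crypto", "prng")) {
  random <- match.arg(random)
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  store <- new.env(parent = emptyenv())
  store$con <- con
  store$txn_depth <- 0L
  store$retention <- retention
  store$audit_policy <- list(default = TRUE, rules = list())
  store$rng <- if (random == "crypto") crypto_sampler() else prng_sampler()
  class(store) <- "pseudonym_store"
  init_schema(con)
  store
}

#' @rdname pseudonym_store
#' @param store A `pseudonym_store`.
#' @export
store_close <- function(store) {
  DBI::dbDisconnect(store$con)
  invisible(TRUE)
}

#' @export
print.pseudonym_store <- function(x, ...) {
  nd <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM domain")$n
  np <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM pseudonym")$n
  na <- DBI::dbGetQuery(x$con, "SELECT COUNT(*) AS n FROM audit_event")$n
  cat(sprintf("<pseudonym_store> %d domain(s), %d pseudonym(s), %d audit event(s)\n",
              nd, np, na))
  invisible(x)
}

init_schema <- function(con) {
  for (ddl in schema_ddl()) DBI::dbExecute(con, ddl)
}

#' Star-schema DDL
#'
#' The SQL statements creating the three tables (`domain`, `pseudonym`,
#' `audit_event`), exposed for inspection and for provisioning a
#' server-grade SQL backend with the same layout.
#'
#' @return Character vector of DDL statements.
#' @export
schema_ddl <- function() c(
  "CREATE TABLE IF NOT EXISTS domain (
     name TEXT PRIMARY KEY,
     parent TEXT REFERENCES domain(name),
     algorithm TEXT NOT NULL,            algorithm_inherited INTEGER NOT NULL,
     alphabet_name TEXT NOT NULL,
     alphabet_chars TEXT NOT NULL,       alphabet_inherited INTEGER NOT NULL,
     length INTEGER NOT NULL,            length_inherited INTEGER NOT NULL,
     length_explicit INTEGER NOT NULL DEFAULT 0,
     padding_char TEXT NOT NULL,         padding_char_inherited INTEGER NOT NULL,
     prefix TEXT NOT NULL,               prefix_inherited INTEGER NOT NULL,
     check_digit INTEGER NOT NULL,       check_digit_inherited INTEGER NOT NULL,
     check_digit_explicit INTEGER NOT NULL DEFAULT 0,
     retries INTEGER NOT NULL,           retries_inherited INTEGER NOT NULL,
     capacity_target REAL NOT NULL,      capacity_target_inherited INTEGER NOT NULL,
     success_threshold REAL NOT NULL,    success_threshold_inherited INTEGER NOT NULL,
     validity_start REAL,                validity_start_inherited INTEGER NOT NULL,
     validity_end REAL,                  validity_end_inherited INTEGER NOT NULL,
     salt TEXT NOT NULL,
     counter_state REAL NOT NULL DEFAULT 0,
     created_at REAL NOT NULL,
     updated_at REAL NOT NULL
   )",
  "CREATE TABLE IF NOT EXISTS pseudonym (
     domain TEXT NOT NULL REFERENCES domain(name),
     identifier TEXT NOT NULL,
     pseudonym TEXT NOT NULL,
     validity_start REAL,                validity_start_inherited INTEGER NOT NULL,
     validity_end REAL,                  validity_end_inherited INTEGER NOT NULL,
     created_at REAL NOT NULL,
     updated_at REAL NOT NULL,
     UNIQUE (domain, identifier),
     UNIQUE (domain, pseudonym)
   )",
  "CREATE INDEX IF NOT EXISTS idx_pseudonym_domain ON pseudonym(domain)",
  "CREATE TABLE IF NOT EXISTS audit_event (
     id INTEGER PRIMARY KEY AUTOINCREMENT,
     timestamp REAL NOT NULL,
     actor TEXT NOT NULL,
     actor_class TEXT NOT NULL,
     action TEXT NOT NULL,
     operation TEXT NOT NULL,
     domain TEXT,
     outcome TEXT NOT NULL
   )"
)

#' Run work in one transaction
#'
#' All storage effects of `code` — records, domain changes and their
#' audit events — commit together or not at all. Transactions nest via
#' savepoints, so a failing inner operation can be confined while an
#' error escaping the outermost level rolls everything back.
#'
#' @param store A [pseudonym_store()].
#' @param code Code block to evaluate.
#' @return The value of `code`.
#' @examples
#' store <- pseudonym_store()
#' domain_create(store, "d")
#' try(with_transaction(store, {
#'   pseudonym_create(store, "d", "x")
#'   stop("boom")                      # record and audit event roll back
#' }), silent = TRUE)
#' store_close(store)
#' @export
with_transaction <- function(store, code) {
  con <- store$con
  depth <- store$txn_depth
  sp <- sprintf("sp%d", depth)
  if (depth == 0L) DBI::dbBegin(con) else
    DBI::dbExecute(con, paste("SAVEPOINT", sp))
  store$txn_depth <- depth + 1L
  done <- FALSE
  on.exit({
    store$txn_depth <- depth
    if (!done) {
      if (depth == 0L) {
        try(DBI::dbRollback(con), silent = TRUE)
      } else {
        try(DBI::dbExecute(con, paste("ROLLBACK TO", sp)), silent = TRUE)
        try(DBI::dbExecute(con, paste("RELEASE", sp)), silent = TRUE)
      }
    }
  })
  result <- force(code)
  if (depth == 0L) DBI::dbCommit(con) else
    DBI::dbExecute(con, paste("RELEASE", sp))
  done <- TRUE
  result
}

# ---- audit trail ----------------------------------------------------------

should_audit <- function(policy, operation, action, actor_class) {
  rule <- policy$rules[[operation]]
  if (is.null(rule)) return(isTRUE(policy$default))
  (is.null(rule$actions) || action %in% rule$actions) &&
    (is.null(rule$actor_classes) || actor_class %in% rule$actor_classes)
}

#' Configure the audit policy
#'
#' Which (action, actor class) combinations are recorded can be set per
#' operation, e.g. to audit an endpoint only for human users. Operations
#' without a rule follow `default`.
#'
#' @param store A [pseudonym_store()].
#' @param default Audit operations without a specific rule?
#' @param rules Named list: `operation -> list(actions =, actor_classes =)`;
#'   omit a field to match everything.
#' @param retention Optional new retention period (seconds, > 0).
#' @return The store, invisibly.
#' @export
audit_configure <- function(store, default = TRUE, rules = list(),
                            retention = NULL) {
  store$audit_policy <- list(default = isTRUE(default), rules = rules)
  if (!is.null(retention)) {
    if (retention <= 0) err_validation("retention period must be positive")
    store$retention <- retention
  }
  invisible(store)
}

# Insert one audit event (inside the caller's transaction).
audit_write <- function(store, action, operation, domain, outcome,
                        actor, actor_class) {
  if (!should_audit(store$audit_policy, operation, action, actor_class)) {
    return(invisible(FALSE))
  }
  DBI::dbExecute(store$con,
    "INSERT INTO audit_event (timestamp, actor, actor_class, action,
       operation, domain, outcome) VALUES (?, ?, ?, ?, ?, ?, ?)",
    params = list(as.numeric(Sys.time()), actor, actor_class, action,
                  operation, if (is.null(domain)) NA_character_ else domain,
                  outcome))
  invisible(TRUE)
}

# Run `code` as one audited primitive operation: on success the audit
# event commits with the operation's effects; on a domain-level failure
# the effects roll back and a single failure event is recorded instead.
audited <- function(store, operation, action, domain, actor, actor_class,
                    code) {
  tryCatch(
    with_transaction(store, {
      r <- force(code)
      audit_write(store, action, operation, domain, "success",
                  actor, actor_class)
      r
    }),
    pseudotree_error = function(e) {
      with_transaction(store, {
        audit_write(store, action, operation, domain, e$code,
                    actor, actor_class)
      })
      stop(e)
    }
  )
}

#' Read the audit trail
#'
#' @param store A [pseudonym_store()].
#' @param operation,domain Optional filters.
#' @return Data frame of audit events (oldest first).
#' @export
audit_events <- function(store, operation = NULL, domain = NULL) {
  q <- "SELECT * FROM audit_event"
  where <- character(0)
  params <- list()
  if (!is.null(operation)) { where <- c(where, "operation = ?"); params <- c(params, operation) }
  if (!is.null(domain))    { where <- c(where, "domain = ?");    params <- c(params, domain) }
  if (length(where)) q <- paste(q, "WHERE", paste(where, collapse = " AND "))
  q <- paste(q, "ORDER BY id")
  if (length(params)) DBI::dbGetQuery(store$con, q, params = params)
  else DBI::dbGetQuery(store$con, q)
}

#' Purge expired audit events
#'
#' Removes events older than the configured retention period. The purge
#' itself is logged.
#'
#' @param store A [pseudonym_store()].
#' @param now Reference time (default: current time).
#' @param actor,actor_class Attribution for the purge event.
#' @return Number of events purged.
#' @export
audit_purge <- function(store, now = Sys.time(), actor = "system",
                        actor_class = "technical") {
  cutoff <- as_epoch(now) - store$retention
  with_transaction(store, {
    n <- DBI::dbExecute(store$con,
      "DELETE FROM audit_event WHERE timestamp < ?", params = list(cutoff))
    audit_write(store, "delete", "audit_purge", NULL,
                sprintf("purged=%d", n), actor, actor_class)
    n
  })
}

#' Export audit events as newline-delimited JSON
#'
#' @param store A [pseudonym_store()].
#' @param path Optional file to write to; otherwise the lines are returned.
#' @return Character vector of JSON lines (invisibly when writing a file).
#' @export
audit_export <- function(store, path = NULL) {
  ev <- audit_events(store)
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    jsonlite::toJSON(as.list(ev[i, , drop = FALSE]), auto_unbox = TRUE)
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
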