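test_that("pseudonymization round-trips and creation is idempotent", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "d")
  r1 <- pseudonym_create(s, "d", "alice")
  expect_equal(pseudonym_resolve(s, "d", r1$pseudonym,
                                 direction = "pseudonym")$identifier, "alice")
  r2 <- pseudonym_create(s, "d", "alice")
  expect_identical(r1$pseudonym, r2$pseudonym)
  expect_equal(DBI::dbGetQuery(s$con,
    "SELECT COUNT(*) AS n FROM pseudonym")$n, 1)
  r3 <- pseudonym_create(s, "d", "bob")
  expect_false(r3$pseudonym == r1$pseudonym)
  expect_error(pseudonym_resolve(s, "d", "ZZZ", direction = "pseudonym"),
               class = "pseudotree_error_not_found")
  expect_error(pseudonym_create(s, "nope", "x"),
               class = "pseudotree_error_not_found")
})

test_that("resolution honours the record validity period half-openly", {
  s <- new_test_store()
  on.exit(store_close(s))
  t0 <- as_utc("2025-01-01"); t1 <- as_utc("2026-01-01")
  domain_create(s, "d", validity_start = t0, validity_end = t1)
  rec <- pseudonym_create(s, "d", "alice")
  expect_true(rec$inherited[["validity.start"]])
  mid <- as_utc("2025-06-01")
  expect_equal(pseudonym_resolve(s, "d", "alice", at = mid)$pseudonym,
               rec$pseudonym)
  expect_equal(pseudonym_resolve(s, "d", "alice", at = t0)$pseudonym,
               rec$pseudonym)                      # start inclusive
  expect_error(pseudonym_resolve(s, "d", "alice", at = t1),
               class = "pseudotree_error_expired") # end exclusive
  expect_error(pseudonym_resolve(s, "d", "alice", at = t0 - 1),
               class = "pseudotree_error_expired")
  # explicit record bounds override the domain and are flagged overwritten
  rec2 <- pseudonym_create(s, "d", "bob", validity_end = as_utc("2025-03-01"))
  expect_false(rec2$inherited[["validity.end"]])
  expect_true(rec2$inherited[["validity.start"]])
})

test_that("standard updates change only validity; pseudonym changes need privilege", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "d")
  r <- pseudonym_create(s, "d", "alice")
  t1 <- as_utc("2030-01-01")
  u <- pseudonym_update(s, "d", r$pseudonym, validity_end = t1)
  expect_equal(u$validity$end, t1)
  expect_false(u$inherited[["validity.end"]])
  expect_error(pseudonym_update(s, "d", r$pseudonym, new_pseudonym = "NEW"),
               class = "pseudotree_error_privilege_violation")
  other <- pseudonym_create(s, "d", "bob")
  expect_error(pseudonym_update(s, "d", r$pseudonym,
                                new_pseudonym = other$pseudonym,
                                privileged = TRUE),
               class = "pseudotree_error_uniqueness_violation")
  u2 <- pseudonym_update(s, "d", r$pseudonym, new_pseudonym = "CUSTOM01",
                         privileged = TRUE)
  expect_equal(u2$pseudonym, "CUSTOM01")
  expect_equal(pseudonym_resolve(s, "d", "CUSTOM01",
                                 direction = "pseudonym")$identifier, "alice")
})

test_that("deletes are permanent and retries exhaust in a full namespace", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "tiny", algorithm = "random_string", alphabet = "digits",
                length = 1, check_digit = FALSE, retries = 1000,
                privileged = TRUE)
  for (i in 1:10) pseudonym_create(s, "tiny", paste0("id", i))
  expect_error(pseudonym_create(s, "tiny", "id11"),
               class = "pseudotree_error_exhausted_retries")
  p1 <- pseudonym_resolve(s, "tiny", "id1")$pseudonym
  pseudonym_delete(s, "tiny", p1)
  expect_error(pseudonym_resolve(s, "tiny", p1, direction = "pseudonym"),
               class = "pseudotree_error_not_found")
  expect_error(pseudonym_delete(s, "tiny", p1),
               class = "pseudotree_error_not_found")
  # freed slot can be re-issued
  r <- pseudonym_create(s, "tiny", "id12")
  expect_equal(r$pseudonym, p1)
})

test_that("batches run in one transaction with per-item outcomes and audit events", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "d")
  ids <- sprintf("id-%03d", 1:100)
  res <- pseudonym_batch(s, "d", "create", ids)
  expect_equal(nrow(res), 100)
  expect_true(all(res$ok))
  expect_equal(length(unique(res$result)), 100)
  expect_equal(nrow(audit_events(s, operation = "pseudonym_create")), 100)

  keys <- c(ids[1:99], "unknown-id")
  rres <- pseudonym_batch(s, "d", "read", keys)
  expect_equal(sum(rres$ok), 99)
  expect_equal(rres$error[!rres$ok], "not_found")

  # storage-level failure rolls back the entire batch
  before <- DBI::dbGetQuery(s$con, "SELECT COUNT(*) AS n FROM pseudonym")$n
  expect_error(with_transaction(s, {
    pseudonym_batch(s, "d", "create", c("zz-1", "zz-2"))
    stop("disk on fire")
  }), "disk on fire")
  after <- DBI::dbGetQuery(s$con, "SELECT COUNT(*) AS n FROM pseudonym")$n
  expect_equal(after, before)
  expect_error(pseudonym_batch(s, "d", "create", character(0)),
               class = "pseudotree_error_validation_error")
})

test_that("rollback leaves pseudonym and audit tables untouched", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "d")
  pseudonym_create(s, "d", "keep")
  snap_p <- DBI::dbGetQuery(s$con, "SELECT * FROM pseudonym ORDER BY identifier")
  snap_a <- DBI::dbGetQuery(s$con, "SELECT * FROM audit_event ORDER BY id")
  expect_error(with_transaction(s, {
    pseudonym_create(s, "d", "gone")
    pseudonym_update(s, "d", pseudonym_resolve(s, "d", "keep")$pseudonym,
                     validity_end = as_utc("2030-01-01"))
    stop("injected failure")
  }), "injected failure")
  expect_identical(
    DBI::dbGetQuery(s$con, "SELECT * FROM pseudonym ORDER BY identifier"),
    snap_p)
  expect_identical(
    DBI::dbGetQuery(s$con, "SELECT * FROM audit_event ORDER BY id"), snap_a)
})

test_that("audit policy filters by operation and actor class; purge honours retention", {
  s <- new_test_store()
  on.exit(store_close(s))
  audit_configure(s, default = TRUE, rules = list(
    pseudonym_resolve = list(actor_classes = "human")))
  domain_create(s, "d")
  r <- pseudonym_create(s, "d", "x")
  pseudonym_resolve(s, "d", "x", actor = "svc", actor_class = "technical")
  pseudonym_resolve(s, "d", "x", actor = "dr", actor_class = "human")
  ev <- audit_events(s, operation = "pseudonym_resolve")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$actor, "dr")

  # purge: only events older than retention go; the purge is logged
  audit_configure(s, retention = 3600)
  DBI::dbExecute(s$con, "UPDATE audit_event SET timestamp = timestamp - 7200
                         WHERE actor = 'dr'")
  n_before <- nrow(audit_events(s))
  purged <- audit_purge(s)
  expect_equal(purged, 1)
  ev2 <- audit_events(s)
  expect_equal(nrow(ev2), n_before - 1 + 1)   # one removed, purge logged
  expect_equal(ev2$operation[nrow(ev2)], "audit_purge")
  expect_equal(audit_purge(s), 0)
  expect_error(audit_configure(s, retention = 0),
               class = "pseudotree_error_validation_error")
})
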