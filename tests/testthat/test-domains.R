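test_that("root domains get documented defaults with an auto-computed length", {
  s <- new_test_store()
  on.exit(store_close(s))
  d <- domain_create(s, "root")
  expect_equal(d$algorithm, "random_string")
  expect_equal(d$alphabet$name, "letters")
  expect_equal(d$retries, 3)
  expect_equal(d$capacity_target, 1e8)
  expect_equal(d$success_threshold, 0.99999998)
  expect_true(d$check_digit)
  expect_equal(d$length, 10)              # sized for q=1e8, m=3, a=26
  expect_null(d$salt)                     # hidden from standard callers
  expect_equal(domain_attribute(s, "root", "salt", privileged = TRUE)$value,
               domain_get(s, "root", privileged = TRUE)$salt)
})

test_that("children inherit unspecified attributes and flag explicit ones overwritten", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "p", algorithm = "random_string", retries = 7)
  d <- domain_create(s, "c", parent = "p", prefix = "C-")
  expect_equal(d$algorithm, "random_string")
  expect_true(d$inherited[["algorithm"]])
  expect_equal(d$retries, 7)
  expect_true(d$inherited[["retries"]])
  expect_equal(d$prefix, "C-")
  expect_false(d$inherited[["prefix"]])
  # salts never inherit
  sp <- domain_get(s, "p", privileged = TRUE)$salt
  sc <- domain_get(s, "c", privileged = TRUE)$salt
  expect_false(sp == sc)
  # counter state independent
  expect_equal(d$counter_state, 0)
})

test_that("creation enforces names, parents and privileged attributes", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "a")
  expect_error(domain_create(s, "a"), class = "pseudotree_error_duplicate_name")
  expect_error(domain_create(s, "b", parent = "nope"),
               class = "pseudotree_error_not_found")
  expect_error(domain_create(s, "b", length = 4),
               class = "pseudotree_error_privilege_violation")
  expect_error(domain_create(s, "b", salt = "x"),
               class = "pseudotree_error_privilege_violation")
  expect_error(domain_create(s, "b", padding_char = "#"),
               class = "pseudotree_error_privilege_violation")
  d <- domain_create(s, "b", length = 4, padding_char = "#", salt = "fixed",
                     privileged = TRUE)
  expect_equal(d$length, 4)
  expect_equal(d$salt, "fixed")
})

test_that("length is derived from an explicit capacity target when absent", {
  s <- new_test_store()
  on.exit(store_close(s))
  d <- domain_create(s, "sized", alphabet = "alphanumeric",
                     capacity_target = 1e7, retries = 5)
  expect_equal(d$length, required_length(1e7, 5, 0.99999998, 36))
})

test_that("updates propagate only into inheriting descendants and their records", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "top")
  domain_create(s, "mid", parent = "top")
  domain_create(s, "leaf", parent = "mid")
  domain_update(s, "leaf", list(retries = 9))          # overwritten shield
  res <- domain_update(s, "top", list(retries = 5), propagate = TRUE)
  expect_setequal(res$domains, c("top", "mid"))
  expect_equal(domain_attribute(s, "mid", "retries"),
               list(value = 5, inherited = TRUE))
  expect_equal(domain_attribute(s, "leaf", "retries"),
               list(value = 9, inherited = FALSE))

  # without propagate, children are untouched
  domain_update(s, "top", list(retries = 6))
  expect_equal(domain_attribute(s, "mid", "retries")$value, 5)

  # validity propagation reaches inheriting pseudonym records
  rec <- pseudonym_create(s, "mid", "id-1")
  expect_true(rec$inherited[["validity.end"]])
  t_end <- as_utc("2030-01-01")
  res2 <- domain_update(s, "top", list("validity.end" = t_end), propagate = TRUE)
  expect_equal(res2$records, 1)
  rec2 <- pseudonym_resolve(s, "mid", "id-1")
  expect_equal(rec2$validity$end, t_end)

  expect_error(domain_update(s, "none", list(retries = 2)),
               class = "pseudotree_error_not_found")
  expect_error(domain_update(s, "top", list(length = 5)),
               class = "pseudotree_error_privilege_violation")
  expect_error(domain_update(s, "top", list(bogus = 1)),
               class = "pseudotree_error_unknown_attribute")
})

test_that("inheritance closure holds under always-propagated random workloads", {
  s <- new_test_store(7)
  on.exit(store_close(s))
  domains <- "d1"
  parents <- c(d1 = NA)
  domain_create(s, "d1")
  set.seed(7)
  for (i in 2:12) {
    nm <- paste0("d", i)
    par <- sample(domains, 1)
    domain_create(s, nm, parent = par)
    domains <- c(domains, nm)
    parents[nm] <- par
  }
  for (i in 1:20) {
    target <- sample(domains, 1)
    domain_update(s, target, list(retries = sample(1:50, 1)),
                  propagate = TRUE)
  }
  # every inherited flag must equal the nearest ancestor's value
  for (nm in domains) {
    at <- domain_attribute(s, nm, "retries")
    if (at$inherited) {
      anc <- parents[[nm]]
      expect_equal(at$value, domain_attribute(s, anc, "retries")$value)
    }
  }
})

test_that("salt overwrite requires an empty domain", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "d")
  d <- domain_set_salt(s, "d", "fresh-salt")
  expect_equal(d$salt, "fresh-salt")
  pseudonym_create(s, "d", "x")
  expect_error(domain_set_salt(s, "d", "again"),
               class = "pseudotree_error_domain_not_empty")
  expect_error(domain_set_salt(s, "nope", "x"),
               class = "pseudotree_error_not_found")
})

test_that("only empty leaves can be deleted, and only once", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "p")
  domain_create(s, "c", parent = "p")
  expect_error(domain_delete(s, "p"), class = "pseudotree_error_domain_not_empty")
  pseudonym_create(s, "c", "x")
  expect_error(domain_delete(s, "c"), class = "pseudotree_error_domain_not_empty")
  pseudonym_delete(s, "c", pseudonym_resolve(s, "c", "x")$pseudonym)
  expect_true(domain_delete(s, "c"))
  expect_error(domain_delete(s, "c"), class = "pseudotree_error_not_found")
  expect_true(domain_delete(s, "p"))
})

test_that("common ancestors resolve within a tree and not across trees", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "r")
  domain_create(s, "a", parent = "r")
  domain_create(s, "b", parent = "r")
  domain_create(s, "aa", parent = "a")
  domain_create(s, "other")
  expect_equal(domain_common_ancestor(s, "a", "a"), "a")
  expect_equal(domain_common_ancestor(s, "a", "b"), "r")
  expect_equal(domain_common_ancestor(s, "aa", "b"), "r")
  expect_equal(domain_common_ancestor(s, "aa", "a"), "a")
  expect_null(domain_common_ancestor(s, "a", "other"))
  expect_error(domain_common_ancestor(s, "a", "nope"),
               class = "pseudotree_error_not_found")
})

test_that("domain configurations survive an export/import round trip", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "p", retries = 4)
  domain_create(s, "c", parent = "p", prefix = "X-")
  json <- domain_export(s)
  s2 <- pseudonym_store()
  on.exit(store_close(s2), add = TRUE)
  created <- domain_import(s2, json)
  expect_setequal(created, c("p", "c"))
  expect_equal(domain_get(s2, "c", privileged = TRUE)$prefix, "X-")
  expect_equal(domain_get(s2, "c", privileged = TRUE)$salt,
               domain_get(s, "c", privileged = TRUE)$salt)
  expect_true(domain_attribute(s2, "c", "retries")$inherited)
})
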