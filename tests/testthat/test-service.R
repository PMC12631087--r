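test_that("authorization demands the exact group path and never inherits", {
  p <- principal("alice", c("/record-read/study", "/domain-read/study"))
  expect_true(authorize(p, "record-read", "study"))
  expect_false(authorize(p, "record-read", "other"))
  expect_false(authorize(p, "record-create", "study"))
  # rights on a parent do not extend to its children (or vice versa)
  expect_false(authorize(p, "record-read", "study/visit-1"))
  expect_false(authorize(principal("x"), "record-read", "study"))
  expect_false(authorize(NULL, "record-read", "study"))

  # fuzz: membership of the exact path string is the whole decision
  set.seed(11)
  acs <- action_classes()
  doms <- paste0("d", 1:6)
  for (i in 1:200) {
    groups <- paste0("/", sample(acs, 5, replace = TRUE), "/",
                     sample(doms, 5, replace = TRUE))
    pr <- principal("u", groups)
    ac <- sample(acs, 1); d <- sample(doms, 1)
    expect_identical(authorize(pr, ac, d),
                     paste0("/", ac, "/", d) %in% groups)
  }
})

test_that("the endpoint table is well formed", {
  e <- endpoints()
  expect_true(all(e$method %in% c("GET", "POST", "PUT", "DELETE")))
  expect_true(all(is.na(e$action_class) | e$action_class %in% action_classes()))
  expect_false(any(duplicated(paste(e$method, e$path))))
  expect_true("/ping" %in% e$path)
  expect_true(is.na(e$action_class[e$path == "/ping"]))
  # every privileged endpoint is guarded by a *-privileged or salt class
  priv <- e[which(e$privileged), ]
  expect_true(all(grepl("privileged|salt", priv$action_class)))
})

test_that("ping answers without a principal and without touching storage", {
  s <- new_test_store()
  on.exit(store_close(s))
  r <- handle(s, "GET", "/ping")
  expect_equal(r$status, 200L)
  expect_equal(r$data, "pong")
  expect_equal(handle(s, "GET", "/ping", accept = "text")$body, "pong")
  expect_equal(nrow(audit_events(s)), 0)
  expect_equal(DBI::dbGetQuery(s$con,
    "SELECT COUNT(*) AS n FROM domain")$n, 0)
})

test_that("requests are denied without the right and served with it", {
  s <- new_test_store()
  on.exit(store_close(s))
  admin <- principal("admin", c("/domain-create/study",
                                "/record-create/study",
                                "/record-read/study"))
  expect_equal(handle(s, "POST", "/domain", list(name = "study"))$status, 401L)
  expect_equal(handle(s, "POST", "/domain", list(name = "study"),
                      principal("nobody"))$status, 401L)
  r <- handle(s, "POST", "/domain", list(name = "study"), admin)
  expect_equal(r$status, 200L)
  expect_equal(r$data$name, "study")
  # same right on a different domain is not enough
  expect_equal(handle(s, "POST", "/domain", list(name = "study2"),
                      admin)$status, 401L)

  rc <- handle(s, "POST", "/domains/study/pseudonym",
               list(identifier = "alice"), admin)
  expect_equal(rc$status, 200L)
  pseu <- rc$data$pseudonym
  rr <- handle(s, "GET", "/domains/study/pseudonym",
               list(key = "alice"), admin)
  expect_equal(rr$data$pseudonym, pseu)
  # record rights do not imply update/delete rights
  expect_equal(handle(s, "PUT", "/domains/study/pseudonym",
                      list(pseudonym = pseu), admin)$status, 401L)
  expect_equal(handle(s, "DELETE", "/domains/study/pseudonym",
                      list(pseudonym = pseu), admin)$status, 401L)
})

test_that("privileged endpoints require their own action classes", {
  s <- new_test_store()
  on.exit(store_close(s))
  std <- principal("u", c("/domain-create/d", "/domain-update/d",
                          "/record-update/d"))
  priv <- principal("pu", c("/domain-create-privileged/d",
                            "/domain-update-privileged/d", "/domain-salt/d",
                            "/record-update-privileged/d",
                            "/record-create/d", "/record-read/d"))
  expect_equal(handle(s, "POST", "/domain/privileged",
                      list(name = "d", length = 4), std)$status, 401L)
  r <- handle(s, "POST", "/domain/privileged", list(name = "d", length = 4),
              priv)
  expect_equal(r$status, 200L)
  expect_equal(r$data$length, 4)
  # the standard update endpoint refuses privileged attributes even when
  # the caller could have used the privileged endpoint
  expect_equal(handle(s, "PUT", "/domain",
                      list(name = "d", changes = list(length = 6)),
                      std)$status, 403L)
  expect_equal(handle(s, "PUT", "/domain/privileged",
                      list(name = "d", changes = list(length = 6)),
                      priv)$status, 200L)
  expect_equal(handle(s, "PUT", "/domains/d/salt", list(salt = "s2"),
                      std)$status, 401L)
  expect_equal(handle(s, "PUT", "/domains/d/salt", list(salt = "s2"),
                      priv)$status, 200L)

  rc <- handle(s, "POST", "/domains/d/pseudonym", list(identifier = "x"),
               priv)
  expect_equal(handle(s, "PUT", "/domains/d/pseudonym/privileged",
                      list(pseudonym = rc$data$pseudonym,
                           new_pseudonym = "CUSTOM"), std)$status, 401L)
  r2 <- handle(s, "PUT", "/domains/d/pseudonym/privileged",
               list(pseudonym = rc$data$pseudonym, new_pseudonym = "CUSTOM"),
               priv)
  expect_equal(r2$status, 200L)
  expect_equal(r2$data$pseudonym, "CUSTOM")
})

test_that("error conditions map to distinguishable statuses", {
  s <- new_test_store()
  on.exit(store_close(s))
  p <- principal("u", c("/domain-create/d", "/record-create/d",
                        "/record-read/d", "/domain-read/d"))
  expect_equal(handle(s, "GET", "/nope", list(), p)$status, 404L)
  handle(s, "POST", "/domain", list(name = "d"), p)
  expect_equal(handle(s, "POST", "/domain", list(name = "d"), p)$status, 409L)
  expect_equal(handle(s, "GET", "/domains/d/pseudonym", list(key = "none"),
                      p)$status, 404L)
  handle(s, "POST", "/domains/d/pseudonym",
         list(identifier = "a", validity_end = as_utc("2020-01-01")), p)
  r <- handle(s, "GET", "/domains/d/pseudonym", list(key = "a"), p)
  expect_equal(r$status, 410L)
  expect_equal(r$data$error, "expired")
  expect_equal(handle(s, "GET", "/domains/d/bogus-attribute", list(),
                      p)$status, 400L)
})

test_that("responses honour content negotiation", {
  s <- new_test_store()
  on.exit(store_close(s))
  p <- principal("u", c("/domain-create/d", "/record-create/d",
                        "/record-read/d"))
  handle(s, "POST", "/domain", list(name = "d"), p)
  rj <- handle(s, "POST", "/domains/d/pseudonym", list(identifier = "a"), p)
  parsed <- jsonlite::fromJSON(rj$body)
  expect_equal(parsed$identifier, "a")
  expect_equal(parsed$pseudonym, rj$data$pseudonym)
  rt <- handle(s, "GET", "/domains/d/pseudonym", list(key = "a"), p,
               accept = "text")
  expect_equal(rt$body, rj$data$pseudonym)
  # errors serialise in both formats too
  et <- handle(s, "GET", "/domains/d/pseudonym", list(key = "zz"), p,
               accept = "text")
  expect_equal(et$body, "not_found")
  ej <- handle(s, "GET", "/domains/d/pseudonym", list(key = "zz"), p)
  expect_equal(jsonlite::fromJSON(ej$body)$error, "not_found")
})

test_that("reads are idempotent at the storage level", {
  s <- new_test_store()
  on.exit(store_close(s))
  p <- principal("u", c("/domain-create/d", "/record-create/d",
                        "/record-read/d"))
  handle(s, "POST", "/domain", list(name = "d"), p)
  handle(s, "POST", "/domains/d/pseudonym", list(identifier = "a"), p)
  snap <- DBI::dbGetQuery(s$con, "SELECT * FROM pseudonym")
  for (i in 1:5) handle(s, "GET", "/domains/d/pseudonym", list(key = "a"), p)
  expect_identical(DBI::dbGetQuery(s$con, "SELECT * FROM pseudonym"), snap)
})

test_that("linked pseudonyms are found across siblings, chains, and closed transitively", {
  s <- new_test_store()
  on.exit(store_close(s))
  domain_create(s, "study")
  domain_create(s, "arm-a", parent = "study")
  domain_create(s, "arm-b", parent = "study")
  domain_create(s, "samples", parent = "arm-a")
  domain_create(s, "island")

  # sibling link: the same identifier pseudonymized in both arms
  ra <- pseudonym_create(s, "arm-a", "subject-1")
  rb <- pseudonym_create(s, "arm-b", "subject-1")
  expect_equal(linked_pseudonyms(s, ra$pseudonym, "arm-a", "arm-b"),
               rb$pseudonym)
  # chain link: the arm-a pseudonym reused as identifier one level down
  rs <- pseudonym_create(s, "samples", ra$pseudonym)
  expect_equal(linked_pseudonyms(s, ra$pseudonym, "arm-a", "samples"),
               rs$pseudonym)
  # transitive closure: sibling + chain in one walk
  expect_equal(linked_pseudonyms(s, rs$pseudonym, "samples", "arm-b"),
               rb$pseudonym)
  # unrelated subjects never leak in
  pseudonym_create(s, "arm-b", "subject-2")
  expect_equal(linked_pseudonyms(s, ra$pseudonym, "arm-a", "arm-b"),
               rb$pseudonym)
  # no link -> empty result; disjoint trees -> not found
  r3 <- pseudonym_create(s, "arm-a", "subject-3")
  expect_length(linked_pseudonyms(s, r3$pseudonym, "arm-a", "arm-b"), 0)
  expect_error(linked_pseudonyms(s, ra$pseudonym, "arm-a", "island"),
               class = "pseudotree_error_not_found")
  expect_error(linked_pseudonyms(s, "ZZZ", "arm-a", "arm-b"),
               class = "pseudotree_error_not_found")

  # via the router, both source and target domain need read rights
  p1 <- principal("u", "/record-read/arm-a")
  p2 <- principal("u", c("/record-read/arm-a", "/record-read/arm-b"))
  q <- list(source_pseudonym = ra$pseudonym, source_domain = "arm-a",
            target_domain = "arm-b")
  expect_equal(handle(s, "GET", "/domains/linked-pseudonyms", q, p1)$status,
               401L)
  rr <- handle(s, "GET", "/domains/linked-pseudonyms", q, p2)
  expect_equal(rr$status, 200L)
  expect_equal(rr$data, rb$pseudonym)
})
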