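# Shared fixtures and independent oracles.

new_test_store <- function(seed = 42L) {
  set.seed(seed)
  pseudonym_store(random = "prng")
}

# Independent Luhn mod N oracle: scalar right-to-left walk with explicit
# parity tracking and base-N digit folding; deliberately structured unlike
# the package's vectorised weight computation.
oracle_luhn_valid <- function(s, chars) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1L]], chars) - 1L
  stopifnot(!anyNA(v))
  n <- length(chars)
  total <- 0L
  pos <- 0L
  for (i in rev(seq_along(v))) {
    x <- v[i]
    if (pos %% 2L == 1L) {
      x <- 2L * x
      x <- x %% n + x %/% n
    }
    total <- total + x
    pos <- pos + 1L
  }
  total %% n == 0L
}

oracle_luhn_check <- function(payload, chars) {
  for (c in chars) {
    if (oracle_luhn_valid(paste0(payload, c), chars)) return(c)
  }
  stop("no valid check character found")
}

# Study/visits scenario: a domain tree in which an algorithm set on the
# "telephone visits" domain is inherited by both visit subdomains and then
# overwritten in visit 2; validity end is overwritten in visit 1 and
# validity start in visit 2 (propagating into the PROMs subdomain and its
# pseudonym); the child of visit 1 overwrites both bounds, and its
# pseudonym overwrites only the start (its creation time), inheriting the
# end date.
build_visits_tree <- function(store) {
  t_end1 <- as_utc("2026-06-30")
  t_start2 <- as_utc("2025-02-01")
  t_start_q <- as_utc("2025-03-01")
  t_end_q <- as_utc("2027-01-01")
  t_rec_start <- as_utc("2025-04-15")

  domain_create(store, "study")
  domain_create(store, "telephone-visits", parent = "study")
  domain_create(store, "visit-1", parent = "telephone-visits")
  domain_create(store, "visit-2", parent = "telephone-visits")

  # algorithm set on the parent propagates into both inheriting visits
  domain_update(store, "telephone-visits", list(algorithm = "random_string"),
                propagate = TRUE)
  # ... and is then overwritten in visit 2 (consecutive numbers)
  domain_update(store, "visit-2", list(algorithm = "consecutive"))

  # PROMs subdomain and its pseudonym exist before the start-date change,
  # so the propagated value reaches both
  domain_create(store, "proms", parent = "visit-2")
  proms_rec <- pseudonym_create(store, "proms", "prom-subject-1")

  domain_update(store, "visit-1", list("validity.end" = t_end1))
  domain_update(store, "visit-2", list("validity.start" = t_start2),
                propagate = TRUE)

  # child of visit 1: both bounds overwritten; its pseudonym overwrites
  # only the start (reflecting its creation time)
  domain_create(store, "biosamples", parent = "visit-1",
                validity_start = t_start_q, validity_end = t_end_q)
  bio_rec <- pseudonym_create(store, "biosamples", "sample-0001",
                              validity_start = t_rec_start)

  list(t_end1 = t_end1, t_start2 = t_start2, t_start_q = t_start_q,
       t_end_q = t_end_q, t_rec_start = t_rec_start,
       proms_rec = proms_rec, bio_rec = bio_rec)
}

as_utc <- function(x) as.numeric(as.POSIXct(x, tz = "UTC"))

# Independently tabulated reference values for the sizing sweep: minimal
# pseudonym length by (q, a, m) at T = 0.99999998.
sizing_reference <- function() {
  ref <- rbind(
    #       a=10:m3 m5 m10  a=36:m3 m5 m10
    "1e1" = c(4, 3, 2,  3, 2, 2),
    "1e2" = c(6, 4, 3,  4, 3, 2),
    "1e3" = c(7, 5, 4,  5, 4, 3),
    "1e4" = c(8, 7, 6,  5, 4, 4),
    "1e5" = c(10, 8, 7, 6, 5, 4),
    "1e6" = c(11, 9, 8, 7, 6, 5),
    "1e7" = c(12, 10, 9, 8, 7, 6),
    "1e8" = c(14, 11, 10, 9, 8, 7),
    "1e9" = c(15, 13, 11, 10, 8, 7))
  grid <- expand.grid(q = 10^(1:9), a = c(10, 36), m = c(3, 5, 10),
                      KEEP.OUT.ATTRS = FALSE)
  cols <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("10", "36"), c("3", "5", "10")))
  grid$length <- mapply(function(q, a, m) {
    ref[paste0("1e", round(log10(q))), cols[as.character(a), as.character(m)]]
  }, grid$q, grid$a, grid$m)
  grid
}
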