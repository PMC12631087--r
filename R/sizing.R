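#' Namespace sizing by exact collision probability
#'
#' A domain generating random pseudonyms of length `l` over an alphabet of
#' size `a` has a namespace of `k = a^l` slots. Drawing uniformly with up
#' to `m` retries per pseudonym, the probability that `q` pseudonyms can
#' all be generated without ever exhausting the retries is
#'
#' \deqn{P_{successful}(q, k, m) = \prod_{n=0}^{q-1} \left[1 - (n/k)^m\right]}
#'
#' since after `n` distinct pseudonyms exist, a single draw is new with
#' probability `(k - n)/k` and all `m` draws fail with probability
#' `(n/k)^m`. Given a target success probability `T`, [min_capacity()]
#' finds the smallest `k >= q` with `P > T`, and [required_length()]
#' converts it to the smallest sufficient pseudonym length
#' `l = ceil(log_a k)`.
#'
#' `p_fill()` works in log space. For large `q` the product is evaluated
#' through exact Faulhaber power sums: `log P = -sum_j S_{jm}(q-1) /
#' (j k^{jm})` where `S_p(N) = sum_{n<=N} n^p`, truncated once the
#' series tail (bounded geometrically by `((q-1)/k)^m`) is negligible;
#' otherwise the direct chunked product is used. Both paths agree to
#' better than 1e-12 relative error where they overlap.
#'
#' @param n Number of pseudonyms already present (0 <= n <= k).
#' @param k Namespace capacity (number of possible pseudonyms).
#' @param m Retries per pseudonym (>= 1).
#' @param q Number of pseudonyms to generate (1 <= q <= k).
#' @param method `"auto"` (default), `"product"` (direct log1p sum), or
#'   `"powersum"` (Faulhaber series; errors if not safely convergent).
#' @return A probability.
#' @examples
#' p_fill(3, 4, 1)               # 0.375
#' min_capacity(2, 1, 0.5)       # 3
#' required_length(1e8, 3, 0.99999998, 26)  # 10
#' @export
p_new <- function(n, k) {
  if (k < 1) err_validation("capacity k must be >= 1")
  if (any(n < 0)) err_validation("n must be >= 0")
  if (any(n > k)) pt_abort("domain_overfull", "n exceeds capacity k")
  (k - n) / k
}

#' @rdname p_new
#' @export
p_attempts <- function(n, k, m) {
  if (m < 1) err_validation("retries m must be >= 1")
  if (any(n < 0) || any(n > k)) err_validation("need 0 <= n <= k")
  1 - (n / k)^m
}

#' @rdname p_new
#' @export
p_fill <- function(q, k, m, method = c("auto", "product", "powersum")) {
  exp(log_p_fill(q, k, m, match.arg(method)))
}

log_p_fill <- function(q, k, m, method = "auto") {
  if (q < 1) err_validation("q must be >= 1")
  if (m < 1) err_validation("m must be >= 1")
  if (q > k) pt_abort("capacity_too_small", "q exceeds capacity k")
  if (method == "product") return(log_p_fill_product(q, k, m))
  ps <- log_p_fill_powersum(q, k, m)
  if (!is.na(ps)) return(ps)
  if (method == "powersum") {
    err_validation("power-sum series does not converge safely for these arguments; use method = 'product'")
  }
  log_p_fill_product(q, k, m)
}

# Direct sum of log1p(-(n/k)^m) over n = 0..q-1, chunked to bound memory.
log_p_fill_product <- function(q, k, m, chunk = 1e6) {
  total <- 0
  n0 <- 0
  while (n0 < q) {
    n <- n0:min(n0 + chunk - 1, q - 1)
    x <- (n / k)^m
    if (any(x >= 1)) return(-Inf)      # only possible at n = k (q = k, m any)
    total <- total + sum(log1p(-x))
    n0 <- n0 + chunk
  }
  total
}

# Bernoulli numbers B_0..B_30 (B_1 = +1/2 convention; odd > 1 are zero).
.bernoulli <- local({
  b <- numeric(31)
  b[1] <- 1
  b[2] <- 1 / 2
  even <- c(1/6, -1/30, 1/42, -1/30, 5/66, -691/2730, 7/6, -3617/510,
            43867/798, -174611/330, 854513/138, -236364091/2730,
            8553103/6, -23749461029/870, 8615841276005/14322)
  b[seq(3, 31, by = 2)] <- even
  b
})

# S_p(N) / k^p via Faulhaber's formula, arranged so no intermediate
# overflows: S_p(N)/k^p = (1/(p+1)) sum_j C(p+1, j) B_j r^(p+1-j) k^(1-j),
# with r = N/k <= 1.
power_sum_ratio <- function(p, N, k) {
  if (N < 1) return(0)
  r <- N / k
  j <- 0:p
  terms <- choose(p + 1, j) * .bernoulli[j + 1] * r^(p + 1 - j) * k^(1 - j)
  sum(terms) / (p + 1)
}

# log P via -sum_{j>=1} S_{jm}(q-1) / (j k^{jm}); returns NA when the
# truncated tail cannot be certified negligible (caller falls back to the
# direct product).
log_p_fill_powersum <- function(q, k, m) {
  m <- as.integer(round(m))
  if (m < 1 || m != round(m)) return(NA_real_)
  N <- q - 1
  if (N < 1) return(0)
  xm <- (N / k)^m                       # largest single-term value
  if (xm >= 0.5) return(NA_real_)       # slow convergence; not worth it
  jmax <- 30L %/% m                     # Bernoulli table reaches B_30
  total <- 0
  term <- NA_real_
  for (j in seq_len(jmax)) {
    term <- power_sum_ratio(j * m, N, k) / j
    total <- total + term
    # geometric tail bound: following terms shrink at least by xm
    tail_bound <- term * xm / (1 - xm)
    if (tail_bound < 1e-16 * max(total, 1e-300) || tail_bound < 1e-20) {
      return(-total)
    }
  }
  tail_bound <- term * xm / (1 - xm)
  if (tail_bound < 1e-12 * max(total, 1e-300)) return(-total)
  NA_real_
}

#' @rdname p_new
#' @param T Minimum fill-success probability, in (0, 1).
#' @export
min_capacity <- function(q, m, T) {
  if (!(T > 0 && T < 1)) err_validation("T must be in (0, 1)")
  if (q < 1 || m < 1) err_validation("q and m must be >= 1")
  logT <- log(T)
  # log1p(-x) <= -x, so log P <= -S_m(q-1)/k^m: when that first-order
  # power sum already reaches -log T, the candidate k certainly fails and
  # the full (possibly slow) evaluation can be skipped.
  mi <- as.integer(round(m))
  ok <- function(k) {
    if (mi == m && mi <= 30L) {
      s1 <- power_sum_ratio(mi, q - 1, k)
      if (s1 >= -logT) return(FALSE)
    }
    log_p_fill(q, k, m) > logT
  }
  lo <- q
  if (ok(lo)) return(lo)
  hi <- 2 * lo
  while (!ok(hi)) {
    lo <- hi
    hi <- 2 * hi
    if (hi > 2^53) err_validation("required capacity exceeds exactly representable integers")
  }
  # invariant: !ok(lo), ok(hi); p_fill is nondecreasing in k
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' @rdname p_new
#' @param a Alphabet size (>= 2).
#' @export
required_length <- function(q, m, T, a) {
  if (a < 2) err_validation("alphabet size a must be >= 2")
  k <- min_capacity(q, m, T)
  a <- as.numeric(a)                    # avoid integer overflow in a^l
  l <- 1L
  pow <- a
  while (pow < k) {
    pow <- pow * a
    l <- l + 1L
  }
  l
}

#' Sizing table over a parameter grid
#'
#' Computes the minimal pseudonym length for every combination of the
#' supplied `q`, `a` and `m` values at a fixed success threshold.
#'
#' @param q,a,m Vectors of maximum pseudonym counts, alphabet sizes and
#'   retry counts.
#' @param T Success threshold.
#' @return A data frame with columns `q`, `a`, `m`, `length`.
#' @export
sizing_table <- function(q = 10^(1:9), a = c(10, 36), m = c(3, 5, 10),
                         T = 0.99999998) {
  grid <- expand.grid(q = q, a = a, m = m, KEEP.OUT.ATTRS = FALSE)
  grid$length <- mapply(function(qi, ai, mi) required_length(qi, mi, T, ai),
                        grid$q, grid$a, grid$m)
  grid[order(grid$a, grid$m, grid$q), , drop = FALSE]
}

#' Monte-Carlo fill simulation
#'
#' Simulates filling a namespace of `k` slots with `q` pseudonyms, each
#' drawn uniformly with up to `m` attempts; the empirical success
#' frequency over many runs validates the closed-form [p_fill()].
#'
#' @inheritParams p_new
#' @param rng Sampler as in [random_body()].
#' @return `TRUE` iff all `q` pseudonyms were placed.
#' @export
simulate_fill <- function(k, q, m, rng = prng_sampler()) {
  if (q > k) pt_abort("capacity_too_small", "q exceeds capacity k")
  draws <- rng(as.integer(q * m), as.integer(k))
  used <- logical(k)
  pos <- 1L
  for (i in seq_len(q)) {
    placed <- FALSE
    for (t in seq_len(m)) {
      s <- draws[pos]; pos <- pos + 1L
      if (!used[s]) {
        used[s] <- TRUE
        placed <- TRUE
        # skip the unused attempts for this pseudonym
        pos <- pos + (m - t)
        break
      }
    }
    if (!placed) return(FALSE)
  }
  TRUE
}
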