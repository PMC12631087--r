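#' Workload mixes
#'
#' The preset operation mixes used for stress-testing the service:
#' `mostly_read` (23% create / 75% read / 1% update / 1% delete),
#' `mostly_write` (75/23/1/1), `read_write` (49/49/1/1), and `ping`
#' (100% no-op baseline against the ping endpoint).
#'
#' @param name Preset name, or `NULL` for the full list.
#' @return A named numeric vector of proportions (or list of them).
#' @export
workload_mix <- function(name = NULL) {
  mixes <- list(
    mostly_read  = c(create = 0.23, read = 0.75, update = 0.01, delete = 0.01),
    mostly_write = c(create = 0.75, read = 0.23, update = 0.01, delete = 0.01),
    read_write   = c(create = 0.49, read = 0.49, update = 0.01, delete = 0.01),
    ping         = c(ping = 1))
  if (is.null(name)) return(mixes)
  if (!name %in% names(mixes)) err_validation(sprintf("unknown workload mix '%s'", name))
  mixes[[name]]
}

#' Run a mixed workload scenario
#'
#' Issues `n_ops` operations drawn i.i.d. from the mix against the
#' endpoint router ([handle()]), so every operation passes through
#' authorization and auditing like real traffic. Reads, updates and
#' deletes target pseudonyms sampled uniformly from the client-side set
#' of currently live pseudonyms; deletes are permanent, and operations
#' that find no live target count as failed requests. A transaction
#' counts toward throughput only when the request succeeded.
#'
#' @param store A [pseudonym_store()].
#' @param domain Target domain (created with defaults when absent; not
#'   used by the `ping` mix).
#' @param mix Preset name or named proportions summing to 1 over
#'   `create`, `read`, `update`, `delete` (and/or `ping`).
#' @param n_ops Number of operations to issue.
#' @param principal A [principal()] holding the needed record rights; a
#'   fully-authorized benchmark user is created by default.
#' @param window Sliding-window width in seconds for the TPS series.
#' @return A `workload_result`: list with `ledger` (one row per
#'   operation: `op`, `t`, `ok`, `status`), `series` (per-second
#'   successful-transaction counts plus `window_mean`), `n_ops` and
#'   `window`.
#' @export
run_scenario <- function(store, domain = "bench", mix = "mostly_read",
                         n_ops = 1000L, principal = NULL, window = 60) {
  if (n_ops < 1L) err_validation("n_ops must be >= 1")
  if (is.character(mix)) mix <- workload_mix(mix)
  if (abs(sum(mix) - 1) > 1e-9) err_validation("mix proportions must sum to 1")
  if (is.null(principal)) {
    principal <- principal("bench", paste0("/", c(
      "record-create", "record-read", "record-update", "record-delete"),
      "/", domain), actor_class = "technical")
  }
  needs_store <- !identical(names(mix), "ping")
  if (needs_store && !domain_exists(store, domain)) {
    domain_create(store, domain, actor = "bench")
  }

  ops <- sample(names(mix), n_ops, replace = TRUE, prob = mix)
  live <- character(0)                  # client-side live pseudonym set
  next_id <- 1L
  ledger <- data.frame(op = ops, t = NA_real_, ok = FALSE,
                       status = NA_integer_)
  base <- sprintf("/domains/%s/pseudonym", domain)

  for (i in seq_len(n_ops)) {
    op <- ops[[i]]
    target <- if (length(live)) live[[sample.int(length(live), 1L)]] else ""
    resp <- switch(op,
      ping   = handle(store, "GET", "/ping"),
      create = {
        id <- sprintf("subject-%06d", next_id)
        next_id <- next_id + 1L
        handle(store, "POST", base, list(identifier = id), principal)
      },
      read   = handle(store, "GET", base,
                      list(key = target, direction = "pseudonym"), principal),
      update = handle(store, "PUT", base,
                      list(pseudonym = target,
                           validity_end = Sys.time() + 86400), principal),
      delete = handle(store, "DELETE", base,
                      list(pseudonym = target), principal))
    ok <- resp$status == 200L
    if (ok && op == "create") live <- c(live, resp$data$pseudonym)
    if (ok && op == "delete") live <- setdiff(live, target)
    ledger$t[i] <- as.numeric(Sys.time())
    ledger$ok[i] <- ok
    ledger$status[i] <- resp$status
  }

  series <- tps_series(ledger, window)
  structure(list(ledger = ledger, series = series, n_ops = n_ops,
                 window = window),
            class = "workload_result")
}

tps_series <- function(ledger, window) {
  t_ok <- ledger$t[ledger$ok]
  if (!length(t_ok)) {
    return(data.frame(second = numeric(0), tps = numeric(0),
                      window_mean = numeric(0)))
  }
  sec <- floor(t_ok - min(ledger$t))
  counts <- table(factor(sec, levels = 0:max(sec)))
  tps <- as.numeric(counts)
  w <- max(1L, min(as.integer(window), length(tps)))
  # trailing sliding-window mean of the per-second counts
  cs <- cumsum(c(0, tps))
  wm <- vapply(seq_along(tps), function(i) {
    lo <- max(0L, i - w)
    (cs[i + 1L] - cs[lo + 1L]) / (i - lo)
  }, numeric(1))
  data.frame(second = as.numeric(names(counts)), tps = tps, window_mean = wm)
}

#' Summarise a throughput series
#'
#' Mean and standard deviation of the windowed transactions-per-second
#' values of a scenario run. Raw throughput depends entirely on the
#' executing hardware; report it, never compare it across machines.
#'
#' @param x A `workload_result` or the `series` data frame / numeric
#'   vector of windowed TPS values.
#' @return List with `mean`, `sd` and `n_windows`.
#' @export
summarize_throughput <- function(x) {
  v <- if (inherits(x, "workload_result")) x$series$window_mean
       else if (is.data.frame(x)) x$window_mean
       else as.numeric(x)
  if (!length(v)) pt_abort("empty_series", "throughput series is empty")
  list(mean = mean(v), sd = stats::sd(v), n_windows = length(v))
}

#' @export
print.workload_result <- function(x, ...) {
  s <- summarize_throughput(x)
  cat(sprintf("<workload_result> %d ops, %d successful; TPS mean %.1f (SD %.1f) over %d windowed seconds\n",
              x$n_ops, sum(x$ledger$ok), s$mean,
              if (is.na(s$sd)) 0 else s$sd, s$n_windows))
  invisible(x)
}
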