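# REST-style operation surface: an endpoint table, group-path
# authorization, content negotiation, and cross-domain linked-pseudonym
# traversal. Authentication is a pluggable contract: anything that can
# produce a principal (user id + group paths) can front this router; a
# static principal works for tests and scripting.

#' Principals and group-path authorization
#'
#' Rights are modelled as group paths of the form
#' `"/<action-class>/<domain>"`: a principal may perform an action class
#' on a domain iff that exact path is among its groups. Rights do not
#' inherit down the domain tree. Action classes: `record-create`,
#' `record-read`, `record-update`, `record-update-privileged`,
#' `record-delete`, `domain-create`, `domain-create-privileged`,
#' `domain-read`, `domain-update`, `domain-update-privileged`,
#' `domain-delete`, `domain-salt`.
#'
#' @param user User id.
#' @param groups Character vector of group paths.
#' @param actor_class `"human"` or `"technical"` (used by the audit
#'   policy).
#' @return A `principal` object.
#' @examples
#' p <- principal("foo", "/record-read/bar")
#' authorize(p, "record-read", "bar")   # TRUE
#' authorize(p, "record-read", "baz")   # FALSE
#' @export
principal <- function(user, groups = character(0), actor_class = "human") {
  structure(list(user = user, groups = as.character(groups),
                 actor_class = actor_class),
            class = "principal")
}

action_classes <- function() c(
  "record-create", "record-read", "record-update",
  "record-update-privileged", "record-delete",
  "domain-create", "domain-create-privileged", "domain-read",
  "domain-update", "domain-update-privileged", "domain-delete",
  "domain-salt")

#' @rdname principal
#' @param p A `principal`.
#' @param action_class One of the action classes above.
#' @param domain Domain name.
#' @export
authorize <- function(p, action_class, domain) {
  if (!inherits(p, "principal")) return(FALSE)
  paste0("/", action_class, "/", domain) %in% p$groups
}

#' The endpoint surface
#'
#' Every endpoint of the service with its HTTP method, required action
#' class and privilege level.
#'
#' @return Data frame describing the endpoint surface.
#' @export
endpoints <- function() {
  e <- rbind(
    c("POST",   "/domain",                                  "domain-create",            FALSE),
    c("GET",    "/domain",                                  "domain-read",              FALSE),
    c("PUT",    "/domain",                                  "domain-update",            FALSE),
    c("DELETE", "/domain",                                  "domain-delete",            FALSE),
    c("POST",   "/domain/privileged",                       "domain-create-privileged", TRUE),
    c("PUT",    "/domain/privileged",                       "domain-update-privileged", TRUE),
    c("GET",    "/domains/{domain}/{attribute}",            "domain-read",              FALSE),
    c("PUT",    "/domains/{domain}/salt",                   "domain-salt",              TRUE),
    c("POST",   "/domains/{domain}/pseudonym",              "record-create",            FALSE),
    c("GET",    "/domains/{domain}/pseudonym",              "record-read",              FALSE),
    c("PUT",    "/domains/{domain}/pseudonym",              "record-update",            FALSE),
    c("DELETE", "/domains/{domain}/pseudonym",              "record-delete",            FALSE),
    c("PUT",    "/domains/{domain}/pseudonym/privileged",   "record-update-privileged", TRUE),
    c("POST",   "/domains/{domain}/pseudonyms",             "record-create",            FALSE),
    c("GET",    "/domains/{domain}/pseudonyms",             "record-read",              FALSE),
    c("PUT",    "/domains/{domain}/pseudonyms",             "record-update",            FALSE),
    c("DELETE", "/domains/{domain}/pseudonyms",             "record-delete",            FALSE),
    c("GET",    "/domains/linked-pseudonyms",               "record-read",              FALSE),
    c("GET",    "/ping",                                    NA,                         FALSE))
  data.frame(method = e[, 1], path = e[, 2], action_class = e[, 3],
             privileged = as.logical(e[, 4]), stringsAsFactors = FALSE)
}

status_for_error <- function(code) {
  switch(code,
    not_found = 404L,
    unauthorized = 401L,
    privilege_violation = 403L,
    duplicate_name = 409L,
    uniqueness_violation = 409L,
    domain_not_empty = 409L,
    hash_collision = 409L,
    expired = 410L,
    exhausted_retries = 409L,
    400L)
}

#' Handle one request
#'
#' Dispatches a request against the endpoint surface: the ping endpoint
#' answers immediately without touching storage or authorization; every
#' other endpoint requires the principal to hold the exact group path for
#' its action class on the addressed domain. The response body is JSON by
#' default or plain text when `accept = "text"`; errors map to
#' distinguishable statuses (404 unknown, 401/403 unauthorized, 409
#' conflict, 410 expired, 400 invalid).
#'
#' @param store A [pseudonym_store()].
#' @param method HTTP method.
#' @param path Endpoint path with path variables filled in, e.g.
#'   `"/domains/study/pseudonym"`.
#' @param params Named list of request parameters / body fields.
#' @param principal The authenticated [principal()], or `NULL`.
#' @param accept `"json"` (default) or `"text"`.
#' @return List with `status`, `body` (serialised string) and `data` (the
#'   raw R value).
#' @export
handle <- function(store, method, path, params = list(), principal = NULL,
                   accept = c("json", "text")) {
  accept <- match.arg(accept)
  if (path == "/ping" && method == "GET") {
    return(respond(200L, "pong", accept))
  }
  route <- match_route(method, path)
  if (is.null(route)) {
    return(respond(404L, list(error = "unknown endpoint"), accept))
  }
  # the addressed domain: path variable, the domain name in the body
  # (/domain endpoints), or the source domain (linked-pseudonyms)
  domain <- route$vars$domain %||% params$name %||% params$source_domain
  if (is.null(principal) ||
      !authorize(principal, route$action_class, domain %||% "")) {
    return(respond(401L, list(error = "unauthorized"), accept))
  }
  if (route$path == "/domains/linked-pseudonyms" &&
      !authorize(principal, "record-read", params$target_domain %||% "")) {
    return(respond(401L, list(error = "unauthorized"), accept))
  }
  tryCatch({
    data <- dispatch(store, route, domain, params, principal)
    respond(200L, data, accept)
  }, pseudotree_error = function(e) {
    respond(status_for_error(e$code),
            list(error = e$code, message = conditionMessage(e)), accept)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

match_route <- function(method, path) {
  eps <- endpoints()
  segs <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1L]]
  best <- NULL
  best_nvar <- Inf
  for (i in seq_len(nrow(eps))) {
    if (eps$method[i] != method) next
    tsegs <- strsplit(sub("^/", "", eps$path[i]), "/", fixed = TRUE)[[1L]]
    if (length(tsegs) != length(segs)) next
    isvar <- grepl("^\\{", tsegs)
    if (!all(tsegs[!isvar] == segs[!isvar])) next
    if (sum(isvar) >= best_nvar) next   # prefer the most literal route
    vars <- as.list(segs[isvar])
    names(vars) <- gsub("[{}]", "", tsegs[isvar])
    best <- list(method = method, path = eps$path[i],
                 action_class = eps$action_class[i],
                 privileged = eps$privileged[i], vars = vars)
    best_nvar <- sum(isvar)
  }
  best
}

dispatch <- function(store, route, domain, params, p) {
  actor <- p$user
  acl <- p$actor_class
  at <- params$at %||% Sys.time()
  switch(route$path,
    "/domain" = switch(route$method,
      POST = do.call(domain_create,
        c(list(store), params, list(privileged = FALSE, actor = actor,
                                    actor_class = acl))),
      GET = domain_get(store, params$name, actor = actor, actor_class = acl),
      PUT = domain_update(store, params$name, params$changes,
                          propagate = isTRUE(params$propagate),
                          actor = actor, actor_class = acl),
      DELETE = domain_delete(store, params$name, actor = actor,
                             actor_class = acl)),
    "/domain/privileged" = switch(route$method,
      POST = do.call(domain_create,
        c(list(store), params, list(privileged = TRUE, actor = actor,
                                    actor_class = acl))),
      PUT = domain_update(store, params$name, params$changes,
                          propagate = isTRUE(params$propagate),
                          privileged = TRUE, actor = actor,
                          actor_class = acl)),
    "/domains/{domain}/{attribute}" = domain_attribute(
      store, domain, route$vars$attribute, actor = actor, actor_class = acl),
    "/domains/{domain}/salt" = domain_set_salt(
      store, domain, params$salt, actor = actor, actor_class = acl),
    "/domains/{domain}/pseudonym" = switch(route$method,
      POST = pseudonym_create(store, domain, params$identifier,
                              validity_start = params$validity_start,
                              validity_end = params$validity_end,
                              actor = actor, actor_class = acl),
      GET = pseudonym_resolve(store, domain, params$key,
                              direction = params$direction %||% "identifier",
                              at = at, actor = actor, actor_class = acl),
      PUT = pseudonym_update(store, domain, params$pseudonym,
                             validity_start = params$validity_start,
                             validity_end = params$validity_end,
                             actor = actor, actor_class = acl),
      DELETE = pseudonym_delete(store, domain, params$pseudonym,
                                actor = actor, actor_class = acl)),
    "/domains/{domain}/pseudonym/privileged" = pseudonym_update(
      store, domain, params$pseudonym,
      validity_start = params$validity_start,
      validity_end = params$validity_end,
      new_pseudonym = params$new_pseudonym, privileged = TRUE,
      actor = actor, actor_class = acl),
    "/domains/{domain}/pseudonyms" = pseudonym_batch(
      store, domain,
      operation = switch(route$method, POST = "create", GET = "read",
                         PUT = "update", DELETE = "delete"),
      items = params$items, direction = params$direction %||% "identifier",
      actor = actor, actor_class = acl),
    "/domains/linked-pseudonyms" = linked_pseudonyms(
      store, params$source_pseudonym, params$source_domain,
      params$target_domain, actor = actor, actor_class = acl),
    err_not_found("endpoint"))
}

respond <- function(status, data, accept) {
  body <- if (accept == "json") {
    as.character(jsonlite::toJSON(unclass_deep(data), auto_unbox = TRUE,
                                  na = "null", null = "null"))
  } else {
    to_plain_text(data)
  }
  list(status = status, body = body, data = data)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, unclass_deep)
  }
  x
}

to_plain_text <- function(data) {
  if (inherits(data, "pseudonym_record")) return(data$pseudonym)
  if (inherits(data, "domain_config")) return(data$name)
  if (is.character(data) && length(data) >= 1L) return(paste(data, collapse = "\n"))
  if (is.list(data) && !is.null(data$error)) return(as.character(data$error))
  paste(utils::capture.output(print(data)), collapse = "\n")
}

#' Linked pseudonyms across domains
#'
#' Starting from a pseudonym in a source domain, walks the domain
#' hierarchy under the deepest common ancestor of source and target
#' domain and returns every pseudonym in the target domain linked to the
#' source. Two records are linked when they share an identifier within
#' the common subtree, or when one record's identifier equals another
#' record's pseudonym along a parent-to-child chain (pseudonym chains);
#' the link relation is closed transitively. Domains in disjoint trees
#' yield a not-found error.
#'
#' @param store A [pseudonym_store()].
#' @param source_pseudonym Pseudonym in `source_domain` to start from.
#' @param source_domain,target_domain Domain names.
#' @param actor,actor_class Audit attribution.
#' @return Character vector of pseudonyms in `target_domain`.
#' @export
linked_pseudonyms <- function(store, source_pseudonym, source_domain,
                              target_domain, actor = "system",
                              actor_class = "technical") {
  audited(store, "linked_pseudonyms", "read", source_domain, actor,
          actor_class, {
    anc <- domain_common_ancestor(store, source_domain, target_domain)
    if (is.null(anc)) {
      pt_abort("not_found",
               "source and target domains have no common ancestor")
    }
    subtree <- domain_subtree(store, anc)
    recs <- DBI::dbGetQuery(store$con,
      sprintf("SELECT domain, identifier, pseudonym FROM pseudonym
               WHERE domain IN (%s)",
              paste(rep("?", length(subtree)), collapse = ",")),
      params = as.list(subtree))
    src <- which(recs$domain == source_domain &
                 recs$pseudonym == source_pseudonym)
    if (!length(src)) {
      pt_abort("not_found", "unknown source pseudonym",
               reason = "unknown_source_pseudonym")
    }
    comp <- link_component(store, recs, src)
    sort(unique(recs$pseudonym[comp][recs$domain[comp] == target_domain]))
  })
}

domain_subtree <- function(store, root) {
  out <- root
  queue <- root
  while (length(queue)) {
    kids <- DBI::dbGetQuery(store$con,
      sprintf("SELECT name FROM domain WHERE parent IN (%s)",
              paste(rep("?", length(queue)), collapse = ",")),
      params = as.list(queue))$name
    queue <- setdiff(kids, out)
    out <- c(out, queue)
  }
  out
}

# Indices of all records in `recs` linked (transitively) to the records
# at indices `seed`. Links: shared identifier, or identifier-of-child ==
# pseudonym-of-parent along a domain parent/child edge.
link_component <- function(store, recs, seed) {
  n <- nrow(recs)
  parent_of <- vapply(unique(recs$domain), function(d) {
    p <- domain_row(store, d)$parent
    if (is.na(p)) NA_character_ else p
  }, character(1))
  visited <- logical(n)
  queue <- seed
  visited[seed] <- TRUE
  while (length(queue)) {
    i <- queue[[1L]]
    queue <- queue[-1L]
    nbr <- which(
      (recs$identifier == recs$identifier[i]) |
      # this record's pseudonym used as identifier in a child domain
      (recs$identifier == recs$pseudonym[i] &
         !is.na(parent_of[recs$domain]) &
         parent_of[recs$domain] == recs$domain[i]) |
      # this record's identifier is a pseudonym in the parent domain
      (recs$pseudonym == recs$identifier[i] &
         !is.na(parent_of[recs$domain[i]]) &
         recs$domain == parent_of[recs$domain[i]])
    )
    new <- nbr[!visited[nbr]]
    visited[new] <- TRUE
    queue <- c(queue, new)
  }
  which(visited)
}
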