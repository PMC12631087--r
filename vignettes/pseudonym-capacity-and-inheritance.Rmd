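---
title: "Sizing pseudonym namespaces and inheriting domain configuration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sizing pseudonym namespaces and inheriting domain configuration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudotree)
```

## The problem

Medical research routinely separates a person's identity from their data
by replacing identifiers with pseudonyms, keeping the link in a guarded
mapping table. A real study needs many such mappings — one per study
arm, visit, sample type — and they are related: the same subject appears
in several of them, second-level pseudonyms are derived from first-level
ones, and most configuration is shared. `pseudotree` models this as a
tree of *domains*, each holding a full generation configuration
(algorithm, alphabet, length, padding, prefix, check digit, salt, retry
count, capacity target, success threshold, validity period) and one
pseudonym table.

Two questions dominate the design and get exact answers here:

1. **Inheritance.** Which configuration does a subdomain use, and what
   happens when a shared setting changes later?
2. **Capacity.** How long must a random pseudonym be so that a study of
   `q` subjects never fails to find a free pseudonym?

## Attribute inheritance

Every inheritable attribute of a domain carries a flag: *inherited* from
the parent or *overwritten* locally. Creation copies unspecified
attributes from the parent (flag inherited) and flags explicitly given
ones overwritten. Updates mark the changed attribute overwritten on the
target; with `propagate = TRUE` the new value also descends the tree,
but only into children whose flag for that attribute is still
inherited. An overwritten value shields its entire subtree: propagation
stops there and does not resume below. Validity periods extend this one
level further — the start and end date inherit *independently*, and
pseudonym records themselves carry the same flags, so a propagated end
date reaches every record that never overrode it while records keep
their individually set start dates.

```{r inheritance}
s <- pseudonym_store()
domain_create(s, "study")
domain_create(s, "visit-1", parent = "study")
domain_create(s, "visit-2", parent = "study")
domain_update(s, "visit-2", list(algorithm = "consecutive"))
domain_update(s, "study", list(retries = 5), propagate = TRUE)
domain_attribute(s, "visit-1", "retries")    # 5, inherited
domain_attribute(s, "visit-2", "algorithm")  # consecutive, overwritten
```

The invariant this maintains: after any sequence of always-propagated
updates, every attribute flagged inherited equals the value of the
nearest ancestor, and every overwritten attribute is exactly what some
caller explicitly set. The test suite checks this property on randomly
grown trees under random update workloads.

## Sizing the namespace

A domain generating random pseudonyms of length $l$ over an alphabet of
$a$ characters has $k = a^l$ possible values. Generation draws
uniformly and retries on collision, giving up after $m$ draws. With $n$
pseudonyms already assigned, a single draw is free with probability
$(k-n)/k$ and all $m$ draws collide with probability $(n/k)^m$, so $q$
pseudonyms can be generated without any failure with probability

$$P(q, k, m) \;=\; \prod_{n=0}^{q-1}\left[1 - \left(\frac{n}{k}\right)^{m}\right].$$

Given a target threshold $T$, `min_capacity(q, m, T)` returns the
smallest $k \ge q$ with $P > T$ — strictly greater, so a configuration
that only *meets* the threshold is rejected — and
`required_length(q, m, T, a)` converts it to the smallest $l$ with
$a^l \ge k$.

### Numerical strategy

The product has up to $10^9$ factors, each extremely close to 1, so
both speed and cancellation matter. `p_fill()` works in log space and
chooses between two exact evaluations:

* **Direct product**: $\sum_{n<q} \log(1 - (n/k)^m)$ via `log1p`,
  chunked to bound memory. Exact but $O(q)$.
* **Power-sum series**: expanding $\log(1-x) = -\sum_j x^j / j$ and
  exchanging sums gives
  $\log P = -\sum_{j \ge 1} S_{jm}(q-1) / (j\,k^{jm})$ where
  $S_p(N) = \sum_{n \le N} n^p$. Each $S_p$ is evaluated *exactly* by
  Faulhaber's formula with Bernoulli numbers up to $B_{30}$, arranged as
  $S_p(N)/k^p$ so no intermediate overflows. The series is truncated
  once its geometric tail bound (ratio at most $((q-1)/k)^m$) drops
  below $10^{-16}$ of the accumulated sum.

The series path answers the $q = 10^9$ problems in microseconds. It is
used only where it can *certify* its truncation error; when the tail
bound cannot be met (convergence ratio too close to 1, or more terms
needed than $B_{30}$ supports), it declines and the direct product is
used instead. Where both paths run they agree to better than
$10^{-12}$ relative error. The capacity search itself combines an
exponential bracket with binary search, using the first-order bound
$\log(1-x) \le -x$ to reject hopeless candidates without a full
evaluation.

```{r sizing}
required_length(1e8, 3, 0.99999998, 26)   # the default configuration: 10
sizing_table(q = c(1e6, 1e9), a = c(10, 36), m = c(3, 10))
```

The default success threshold, $T = 0.99999998$, makes a single failed
generation a 1-in-50-million event at full capacity. The full sweep
used in the tests covers $q = 10^1 \dots 10^9$, $a \in \{10, 36\}$,
$m \in \{3, 5, 10\}$; a Monte-Carlo simulation (`simulate_fill()`)
validates the closed form at small scale.

## Generators and their limits

Nine algorithms are supported: six salted hashes (`md5`, `sha1`,
`sha2`, `sha3`, `blake3`, `xxhash`), a per-domain counter
(`consecutive`), and two random generators (`random_string` over the
domain alphabet, `random_number` over digits). Practical notes, which
are also enforced or documented in code:

* **Hashes** are deterministic in (identifier, salt). They are meant
  for automated pipelines and stay raw hexadecimal unless a length or
  check digit is explicitly configured; truncating a digest narrows the
  namespace and re-introduces the collision analysis above. A digest
  that collides for a *different* identifier is reported as an error,
  not retried — determinism means retrying cannot help.
* **Counters** leak the order in which records entered the domain and
  overflow when the counter no longer fits the configured length; they
  render in decimal, so their check digit is computed over the digits
  alphabet regardless of the domain's display alphabet.
* **Random generators** default to rejection sampling over a
  cryptographic byte source; a seedable PRNG sampler exists for
  reproducible tests and simulations only.
* **Check digits** use the Luhn mod N scheme over the prefix-less body.
  They detect every single-character substitution and most adjacent
  transpositions; the tests enumerate all four-character digit payloads
  exhaustively against an independent oracle. A check digit is a
  transcription aid, not a security feature.

## Storage, audit, service

Mappings persist in SQLite in a star-like schema: a self-referencing
domain dimension, one pseudonym fact table with uniqueness constraints
on (domain, identifier) and (domain, pseudonym), and a stand-alone
audit-event table. Every operation runs in a transaction (savepoints
nest) and writes its audit event atomically with its effect — a failed
operation contributes a failure event and no other state. Audit policy
is configurable by operation and actor class, with retention-based
purging that itself leaves an audit event.

The service layer is a function-level router (`handle()`) over an
explicit endpoint table, with group-path authorization
(`"/<action-class>/<domain>"`, exact match, no inheritance down the
domain tree — rights on a parent deliberately do not imply rights on
its children), JSON or plain-text responses, and privileged endpoint
variants for the attributes that change the shape of the namespace
(salt, length, padding). Cross-domain linkage walks the tree under the
deepest common ancestor and closes transitively over shared identifiers
and pseudonym-derivation chains. Any HTTP front end can wrap `handle()`;
none is bundled, which keeps the package free of server dependencies
and the logic testable in-process.

`run_scenario()` drives this router with mixed CRUD workloads and
reports a sliding-window transactions-per-second series. Throughput is
hardware-bound; the suite asserts invariants (mix frequencies, audit
completeness, uniqueness) and never a TPS number.

## Limitations

* SQLite serialises writers; the concurrency claims tested here are
  about transactional atomicity, not parallel scaling.
* `min_capacity` searches $k \le 2^{53}$, the exactly representable
  integer range of doubles — ample for $q \le 10^9$ but a hard ceiling.
* The power-sum path requires integer $m$; non-integer retry counts
  fall back to the direct product.
* Authentication is out of scope by design: callers supply a verified
  principal, and anything from a static token check to a full identity
  provider can sit in front.
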