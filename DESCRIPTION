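Package: pseudotree
Title: Hierarchical Pseudonym Management with Audit Trail and
    Namespace Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pseudonymization engine for biomedical data protection.
    Generates pseudonyms with nine algorithms (salted cryptographic
    hashes, counters, and random strings over configurable alphabets),
    optionally protected by Luhn mod N check digits. Pseudonym spaces
    are organised as hierarchical domains whose configuration
    attributes are inherited, overwritten and propagated with explicit
    per-attribute flags. Identifier-pseudonym links are persisted in a
    transactional star-schema store with a complete audit trail and
    configurable retention. An exact collision-probability calculation
    sizes pseudonym namespaces (minimal capacity and length) for a
    target fill-success probability, validated by Monte-Carlo
    simulation. Includes a REST-style operation router with
    group-path authorization, batch processing, cross-domain linked
    pseudonym lookup, and a mixed-workload benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    digest,
    openssl,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
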