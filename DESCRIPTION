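Package: anonceil
Title: Utility-Preserving k-Anonymization with Generalization Ceilings and
    Counterfeit Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Anonymizes tabular health data by full-domain generalization under
    a ceiling on the generalization degree (h-ceiling), restoring k-anonymity in
    under-filled equivalence classes by inserting counterfeit records, and
    publishing a provably privacy-safe catalog of the counterfeits so that
    recipients can reconstruct a truthful dataset. Includes the generalization
    lattice search with monotonicity pruning, the loss metric (LM),
    discernibility metric (DM) and reconstruction-error (RCE) utility metrics,
    uniform-overlap range-query evaluation, and a seeded generator of synthetic
    EHR-like tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
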