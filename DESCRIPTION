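Package: epletmm
Title: Single-Molecule HLA-DR/DQ Eplet Mismatch Scoring and Alloimmune Risk
    Stratification
Version: 0.1.0
Authors@R: person("epletmm", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for molecule-level HLA-DR/DQ eplet mismatch analysis in
    kidney transplantation. Loads eplet registries and donor/recipient HLA
    typing tables, imputes two-field alleles from population haplotype
    frequencies, enumerates scorable HLA molecules (DR beta chains and
    DQ alpha1-beta1 heterodimers), computes per-molecule eplet mismatch
    counts and recipient-level single-molecule maxima, stratifies recipients
    into alloimmune risk categories under published or cohort-derived
    thresholds, derives cohort-specific thresholds by two-stage ROC analysis,
    and validates categories against de novo donor-specific antibody
    development with Kaplan-Meier, log-rank, and Cox proportional-hazards
    models. Includes a fully deterministic synthetic-cohort generator and a
    config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
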