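Package: basketpsm
Title: Weighted Multi-Site Partitioned Survival Models for Tumour-Agnostic Therapies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dynamic, modular cost-effectiveness framework for
    biomarker-defined ("tumour-agnostic") oncology therapies evaluated
    across multiple tumour sites. Each site is a three-state partitioned
    survival model (progression-free, progressed, dead) built from
    parametric extrapolations of overall and progression-free survival;
    sites are combined by epidemiological weights into pooled incremental
    costs and QALYs from which a single aggregated ICER is derived.
    Includes maximum-likelihood fitting of standard survival families to
    right-censored patient-level data, reconstruction of pseudo
    individual-patient data from digitised Kaplan-Meier curves and
    numbers at risk, background-mortality adjustment against a life
    table, break-out of tumour-site subgroups as evidence matures with a
    versioned re-analysis log, deterministic and probabilistic
    sensitivity analysis with shared versus site-specific parameter
    structure, and a seeded synthetic basket-trial generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
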