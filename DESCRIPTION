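Package: ramlhrs
Title: Mechanistic Modelling of Radiation-Induced AML Incidence in CBA/H
    Mice with Low-Dose Hyper-Radiosensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-mutation mechanistic model of radiation-induced
    acute myeloid leukemia (rAML) in male CBA/H mice. Normal haematopoietic
    cells acquire an Sfpi1-deleting interstitial deletion under irradiation,
    the resulting pre-leukemic clone expands, and a point mutation in the
    remaining Sfpi1 allele creates the first malignant cell; diagnosis follows
    after a fixed latency provided the mouse survives competing (non-rAML)
    mortality, modelled as a dose-shifted skew-normal time distribution.
    Cell killing and deletion induction follow linear-quadratic or
    induced-repair (low-dose hyper-radiosensitivity, HRS) survival models,
    giving three HRS scenarios for the dose-response curve. The package
    provides closed-form incidence computation, a per-mouse stochastic
    simulator used as an independent cross-check, weighted least-squares
    estimation of the proliferation and point-mutation rates from cohort
    data, a synthetic-cohort generator, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
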