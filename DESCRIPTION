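Package: umasurv
Title: Unified Multi-Activation Modelling of Cell Survival and Equivalent
    Dose in Fractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits clonogenic cell-survival curves with a two-parameter
    unified multi-activation (UMA) model, S = n / (exp(D/Do) + n - 1), over
    the entire dose range, and derives the analytic radiosensitivity
    quantities that follow from it: dose-dependent alpha and beta, the
    alpha/beta ratio, and the mean inactivation dose.  Computes equivalent
    dose in 2-Gy fractions (EQD2) and equivalent fraction numbers for
    arbitrary fractionation schemes, including mixed-radiation and
    mixed-cell-population rules, alongside the classical linear-quadratic
    EQD2 for comparison.  Includes linearized UMA, linear-quadratic and
    multitarget fitting with replicate-aware goodness statistics, a
    fractionation-scheme comparison grid over the (Do, n) plane, a
    synthetic clonogenic-assay curve generator, a curated table of
    published tumour cell-line parameters, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
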