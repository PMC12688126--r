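Package: gahacr
Title: Simulation of Gibberellin Signaling Feedback Rewired by a
    Hormone-Activated CAS9 Repressor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic ODE model of the gibberellin (GA) signaling
    and biosynthesis network in Arabidopsis, extended with a GA-regulated
    Hormone Activated CAS9-based Repressor (GAHACR) that rewires the
    DELLA-mediated transcriptional feedback on GA biosynthesis genes.
    Provides time-course integration, certified steady-state computation,
    two-parameter steady-state sweeps over repression strength,
    repressor degradation and expression level, comparison of the
    wildtype, no-degron repressor and GAHACR regulatory variants, a
    seeded log-normal parameter-ensemble robustness harness, a plain-text
    configuration dialect, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
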