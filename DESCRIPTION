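Package: mergenet
Title: Incoherent Merger Networks for Robust Ratiometric Gene Expression
Version: 0.1.0
Authors@R:
    person("mergenet", "developers", email = "mergenet@example.org",
           role = c("aut", "cre"))
Description: Models, analyses and fits the incoherent merger network, a
    bacterial gene circuit in which one inducer drives production of an
    output protein while a second inducer drives a protease that degrades
    it, so that the steady-state output tracks the ratio of the two inducer
    concentrations.  Provides mass-action ODE models (a minimal
    protease-output module and a full sensor/mRNA/ribosome-competition
    circuit), closed-form reduced steady-state laws, assumption checking,
    robustness and tunability analyses, nonlinear least-squares fitting of
    dose-response data, and a seeded synthetic-data generator emulating
    plate-reader and flow-cytometry readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
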