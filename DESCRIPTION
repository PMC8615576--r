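Package: cmcscan
Title: Ultrasensitivity Analysis of Covalent Modification Cycles with Protein Turnover
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic models of a protein phosphorylation-dephosphorylation
    cycle in which the modified and unmodified substrate forms are synthesized and
    degraded at their own rates, so that posttranslational modification can change
    protein stability. Implements a two-equation Michaelis-Menten variant and a
    four-equation mass-action variant with explicit enzyme-substrate complexes,
    a warm-started steady-state dose-response scan engine on geometric (percent
    increment) dose grids, and the two standard ultrasensitivity metrics: the
    Hill coefficient estimated from the 10-90% dose ratio and the local response
    coefficient (log-log slope) profile. Includes a declarative scenario runner
    with CSV/JSON output, a command-line interface, and ggplot2 plotting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
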