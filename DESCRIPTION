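Package: mitosim
Title: Hybrid Agent-Based and ODE Simulation of Mitochondrial Aging in C. elegans Cells
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multilevel stochastic simulator of mitochondrial function and
    dysfunction in aging, post-mitotic Caenorhabditis elegans cells. Each cell
    agent carries its own population of mitochondrion agents; an ordinary
    differential equation network (oxidative metabolism, reactive oxygen
    species pools, NAD+ and ATP, the ATFS-1/UPRmt axis, DAF-16 and SKN-1
    activities) is coupled to discrete stochastic events (mtDNA damage and
    clonally biased replication, stress-state transitions, selective
    mitophagy, biogenesis, compromise and death of cells). Includes
    pharmacological dosing schemes (rapamycin, bafilomycin, paraquat,
    pterostilbene), fractional genetic ablations (sod-2, daf-16, skn-1),
    endpoint observables with literature unit conversions, survival curves,
    and a one-at-a-time normalized-sensitivity-coefficient analysis. Results
    are returned as tidy tibbles with ggplot2 plotting methods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
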