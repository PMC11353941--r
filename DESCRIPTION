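Package: vdwsolv
Title: Solvation Thermodynamics from the van der Waals Model of Liquids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic solvation thermodynamics for monoatomic solutes in
    van der Waals liquids. From a solvent's effective hard-sphere diameter,
    molar volume and isobaric thermal expansion coefficient, computes the
    Ben-Naim solvation Gibbs free energy and its full decomposition into
    cavity-creation and attraction-switching contributions, each split into
    enthalpic and entropic parts (excluded-volume versus structural
    reorganization entropy). Includes a finite-composition van der Waals
    binary-mixture model with analytic chemical potentials and
    finite-difference oracles, a built-in reference dataset for eight common
    liquids at 25 degrees Celsius, temperature scans, liberation (molar
    volume transfer) free energies, validated delimited-table input and
    output, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
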