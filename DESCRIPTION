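Package: pfleach
Title: Soil Leaching and Plant Uptake of Perfluoroalkyl Acids with
    Non-Extractable Residue Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-dimensional daily soil-column model for the environmental
    fate of perfluoroalkyl acids (PFOA, PFOS) in agricultural soils: layered
    water balance with macropore bypass flow, Freundlich equilibrium sorption,
    reversible two-site kinetic sorption or irreversible formation of
    non-extractable residues (NER), advection-dispersion solute transport,
    and passive plant uptake via the transpiration stream. Includes a
    multi-target Kling-Gupta objective, a two-stage behavioural particle-swarm
    calibration with uncertainty envelopes and posterior parameter statistics,
    and a synthetic lysimeter-study generator (stochastic weather, crop
    rotation, noisy monthly and seasonal observations) for end-to-end testing
    and parameter-recovery experiments.
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
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
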