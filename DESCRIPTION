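Package: xylosim
Title: Spatially Explicit Simulation of Wood Formation in Conifers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily, cell-level simulation of xylogenesis (wood formation) along
    independent radial files of a conifer stem. Couples temperature-dependent
    cell enlargement (Boltzmann-Arrhenius kinetics), stochastic sizer-adder
    division-size control, primary and secondary wall deposition
    (Michaelis-Menten in cytoplasmic carbohydrate concentration), an
    equilibrium source-sink carbohydrate diffusion profile from the phloem
    solved by Brent's method, daylength-driven developmental zone widths, and
    chilling/degree-day dormancy phenology. Includes a synthetic boreal
    climate generator, scenario experiments (fixed temperature, frozen zone
    widths, sugar saturation, temperature anomalies and sweeps), and
    tree-ring anatomy metrics (density profiles, ring width, mass, maximum
    latewood density).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
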