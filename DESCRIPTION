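Package: syntrophr
Title: Simulation and Analysis of a Two-Strain Mutualistic Consortium with
    Reciprocal Disaccharide Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling an obligate mutualistic coculture of two
    engineered Pseudomonas putida strains that cross-feed by reciprocal
    hydrolysis of cellobiose and xylobiose.  Implements the coupled logistic
    growth equations with Monod-type cross-feeding factors and scenario
    scaling (substrate amounts, inoculation ratios, enzyme levels and
    expression burden), adaptive ODE simulation, bounded multistart
    least-squares parameter estimation from plate-reader growth curves,
    fluorescence-to-OD calibration with strain deconvolution, growth-curve
    metrics (maximum specific growth rate, lag time, substrate conversion
    rates), and seeded synthetic-data generators for plate-reader and HPLC
    time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
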