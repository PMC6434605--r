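Package: ethogramr
Title: Behavioral Classification of Seabird Biologger Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building time-activity budgets from tri-axial
    accelerometer, depth, and GPS biologger deployments on seabirds.
    Computes posture (pitch), dynamic body acceleration (ODBA), and
    wing-beat frequency from raw 25 Hz acceleration; segments tracks into
    bouts of consistent behavior; classifies colony, flying, swimming, and
    diving with six methods (histogram segregation, k-means, Gaussian
    mixtures, neural network, random forest, and a constrained hidden
    Markov model); validates classifications against GPS ground-speed
    rules; and converts activity budgets into daily energy expenditure.
    Includes a semi-Markov biologger simulator for murre- and
    kittiwake-like deployments used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    ranger,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    caret,
    jsonlite
Config/testthat/edition: 3
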