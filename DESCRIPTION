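Package: hvchan
Title: Voltage-Gated Proton Channel Biophysics and Cytosolic pH
    Homeostasis in Calcifying Phytoplankton
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of voltage-clamp recordings of voltage-gated H+
    conductances (leak subtraction, current-voltage extraction,
    tail-current reversal potentials, activation-kinetics fitting,
    recording quality control), closed-form electrochemistry (Nernst and
    Goldman-Hodgkin-Katz reversal potentials, inverse selectivity
    bounds, calcification acid-load arithmetic), a deterministic coupled
    membrane-potential/cytosolic-pH kinetic model of a calcifying
    coccolithophore cell with named experimental scenarios, and
    quantification of ratiometric BCECF pH imaging and
    birefringence-based calcification rates.  Ground-truth synthetic
    data generators make the entire analysis chain testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
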