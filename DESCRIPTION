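Package: csdtools
Title: Peptide Charge State Distribution Extraction and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and statistical analysis of peptide charge state
    distributions (CSDs) from positive-mode electrospray MS1 spectra.
    Implements isotope-envelope matching with presence/absence/chimera
    filtering and intensity-weighted aggregation into one CSD per peptide
    per run; total-variation error between CSD readings; a one-parameter
    multiplicative batch correction between run pairs; under/over-charging
    regime classification and mean-charge-versus-mass trends; and
    region-wise penalized logistic regression on amino acid composition
    yielding per-residue effective basicity scores with a robust (Huber)
    mass adjustment. A synthetic-data module generates peptides with
    planted ground-truth CSDs and renders MS1 runs with noise, chimeric
    interference, intensity thresholds and batch effects, so every stage
    can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mzR,
    jsonlite
Config/testthat/edition: 3
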