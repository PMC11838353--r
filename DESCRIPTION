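Package: ibdscan
Title: Genome-Wide Significance Thresholds for Identity-by-Descent Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selection scans based on excess identity-by-descent (IBD) segment
    sharing with family-wise error rate control. Computes IBD rates on a uniform
    centiMorgan grid from detected segment files and recombination maps, robustly
    standardizes them, estimates the exponential autocorrelation decay of the
    rate process under an Ornstein-Uhlenbeck model, and derives genome-wide
    significance thresholds by an analytical boundary-crossing approximation,
    by Monte Carlo simulation of the fitted process, and by the Bonferroni
    correction. Includes region calling for contiguous significant stretches,
    scan diagnostics, and a simulation harness that validates family-wise error
    rate calibration on Ornstein-Uhlenbeck null genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
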