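Package: telomap
Title: Single-Molecule Optical-Map Readouts for Telomeres and Chromosome Ends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses single-molecule two-color optical maps of
    human chromosome ends. Synthetic molecules carry genome-wide nick-label
    patterns plus telomere-channel labels whose fluorescence intensity is
    proportional to telomere length. A dynamic-programming aligner assigns
    molecule segments to chromosome arms by nick-label interval patterns
    (including split alignments for fusion molecules); each molecule is then
    classified as an end telomere, telomere-free end, fusion with or without
    an internal telomere-like sequence, or an extrachromosomal telomeric
    repeat. Per-arm and genome-wide readouts (mean lengths, coefficient of
    variation, fusion and telomere-free-end percentages, super-long telomere
    fractions) feed a five-readout vote that calls Alternative Lengthening of
    Telomeres (ALT) positivity. Includes readers and writers for simplified
    BNX/CMAP dialects, tabular reports, and packaged cell-line profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
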