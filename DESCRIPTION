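Package: dgmap
Title: Directed Graph Mapping of Cardiac Excitation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs cardiac excitation as a directed network from
    electrode local activation times (LATs) and diagnoses the arrhythmia
    mechanism automatically. Directed edges connect neighboring electrodes
    whose activation-time difference implies a physiological conduction
    velocity; rotational activity (functional or anatomical reentry) is
    found as directed cycles and localized by bundling cycle centers, and
    focal activity as regions with only outgoing edges. Includes
    network-derived features (region of influence, wave averaging), an
    LAT-based phase-mapping baseline with Sobel-kernel phase-singularity
    detection, synthetic activation-field generators (rotor, multi-rotor,
    anatomical reentry, focal, centrifugal target wave), forward
    computation of unipolar electrograms from transmembrane-potential
    fields with steepest-negative-slope LAT annotation, and a Monte-Carlo
    LAT-noise robustness benchmark with cluster-robust confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    deldir,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
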