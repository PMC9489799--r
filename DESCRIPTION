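Package: aggremorph
Title: Single-Molecule Localization Morphometry of Protein Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis chain for transient-binding
    single-molecule localization microscopy (PAINT/thioflavin-X) of
    soluble protein aggregates: simulation of localization data with
    ground truth, spot fitting and precision/intensity filtering,
    fiducial-based drift correction, density-based clustering (DBSCAN),
    per-aggregate length and eccentricity morphometry, two-sample
    distribution comparison (Kolmogorov-Smirnov, Mann-Whitney), and the
    companion diffraction-limited quantifications: per-liposome calcium
    influx from condition-matched TIRF fields and single-molecule
    pulldown spot counting with control-calibrated thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
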