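Package: tlsbench
Title: Simulation and Benchmarking of Terrestrial Laser Scanning for Forest Inventory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate terrestrial laser scans of calibration tubes and
    plantation stands with configurable device profiles (point rate, field of
    view, range noise, maximum range, detection censoring), and to benchmark the
    resulting point clouds for forest inventory: diameter at breast height (DBH)
    from the perimeter of a breast-height cross-section, tree height from
    DTM/DSM/nDSM rasters, a Fourier-residual noise-band quality statistic for
    stem cross-sections, and device comparison via RMSE, bias, detection rate,
    paired t-tests, one-way ANOVA and Tukey HSD.
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
    jsonlite,
    withr
Config/testthat/edition: 3
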