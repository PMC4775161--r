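Package: wpfx
Title: Whole-Pattern Fitting for Serial Femtosecond Nanocrystallography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extraction of structure-factor moduli from merged serial
    femtosecond crystallography (SFX) diffraction data by whole-pattern
    (Le Bail-style) fitting with extended pseudo-Voigt peak shapes.
    Includes a finite-lattice diffraction simulator for ensembles of
    log-normal-sized needle nanocrystals in the (hk0) plane, a
    P-matrix linear solver that untangles overlapping Bragg
    reflections, Wilson scaling, an integration-based extractor for
    benchmarking, radius-sweep accuracy comparisons, and an analysis
    of neighbouring-peak overlap contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
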