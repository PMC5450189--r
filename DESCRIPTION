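Package: vesicoat
Title: Radial Coat Profiling and Trafficking Kinetics for Fluorescent Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of fluorescent protein coats on intracellular
    vesicles from multi-channel microscopy. Decomposes a circumferential band
    around a vesicle into angular sectors and measures per-channel signal
    (radial "radar" profiles), estimates subpixel peak-to-peak diameters and
    cross-channel radial displacement in physical units, fits single-exponential
    fluorescence-recovery-after-photobleaching (FRAP) models with half-times and
    immobile fractions, and analyses exocytosis retention kinetics (time to 50%
    retention, area under the curve, ANOVA with Tukey HSD). Includes a synthetic
    data generator producing ring-shaped two-channel vesicle images, FRAP traces
    and retention curves with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
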