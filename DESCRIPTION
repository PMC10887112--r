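Package: flimox
Title: Single-Spheroid Oxygen Consumption from Frequency-Domain FLIM Microwell Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for oxygen-consumption measurements of
    single multicellular spheroids cultured in microwell arrays filled with an
    oxygen-sensitive ruthenium dye and imaged by homodyne frequency-domain
    fluorescence lifetime imaging microscopy (FD-FLIM). Provides a forward
    simulator for phase-step image stacks, brightfield and live/dead channels
    with known ground truth; per-pixel first-harmonic phasor demodulation and
    phase/modulation lifetime estimation; Stern-Volmer quenching calibration and
    lifetime-to-oxygen conversion with per-timepoint empty-chamber reference
    normalization; microwell ROI detection and occupancy classification;
    per-chamber oxygen-consumption kinetics with group comparisons; and
    brightfield morphometry plus live/dead viability quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
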