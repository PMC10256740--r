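Package: rnptrack
Title: Quantification of RNP Granule Transport, Anchoring, and mRNA Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the trafficking of ribonucleoprotein (RNP)
    granules and their mRNA cargo from fluorescence microscopy and
    compartment-fractionation data. Includes a synthetic-data generator
    (granule motion models, rendered movies, centrosome-recruitment images,
    neurite spot fields, two-compartment count tables, qPCR tables), a
    single-particle tracking pipeline (rolling-ball background correction,
    Laplacian-of-Gaussian spot detection, nearest-neighbour linking), track
    dynamics statistics (mean squared displacement, diffusion coefficients,
    maximum excursion, velocity), kymograph and co-transport analysis,
    centrosome-enrichment and masked colocalization scoring, and
    neurite/soma mRNA localization statistics with CLIP-density binning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
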