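Package: fiberflux
Title: Quantification of Autophagy Flux in Skeletal Muscle Fiber Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based quantification of autophagosome and lysosome
    dynamics in single skeletal muscle fibers. Provides a seeded synthetic
    generator for striated-fiber confocal images (LC3, mitochondrial and
    lysosomal channels with ground truth), fiber segmentation and Z-line
    localization from the paired mitochondrial rows, autophagosome puncta
    detection by an intensity-above-background threshold with a per-fiber
    area-ratio statistic, lysosome counting with a high-lysosome fiber
    classifier and LC3-lysosome contact analysis, immunoblot lane
    densitometry, and group statistics (mean, SEM, pooled two-sample
    t-tests with star annotations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
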