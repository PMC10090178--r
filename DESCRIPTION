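Package: nisslcount
Title: Automated Pyramidal-Neuron Counting in Nissl Histology with an
    In-Silico Optical Fractionator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A high-throughput pipeline for estimating pyramidal-neuron
    numbers in Nissl-stained histology partitions. Provides preprocessing
    (8-bit conversion, polygon cropping, inversion, auto-contrast), a
    pluggable instance-segmentation step with a deterministic classical
    watershed backend, moment-ellipse false-positive filtering (partition
    mean-intensity threshold and a lower minor-axis diameter threshold at
    mean minus 0.75 standard deviations), Dice-based mask agreement, and
    an in-silico optical fractionator with systematic uniform random
    sampling, disector counting and guard zones. A synthetic-tissue
    generator produces Nissl-like 2D partitions and 3D slabs with exact
    ground truth (somata, glia, partial neuron profiles, faint
    extracellular blobs, overlapping pairs, nucleolus points) so every
    stage is testable end-to-end against known counts. Nonparametric
    method-comparison statistics (paired Wilcoxon, Spearman,
    Kruskal-Wallis with Dunn/Holm post-hocs) relate automated estimates
    to stereology counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
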