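Package: mothcolr
Title: Assemblage-Level Colour Diversity of Moths Along Elevational Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how insect colour diversity changes along
    ecological gradients at the assemblage level. Provides a seeded
    generator of procedural moth specimen images with ground-truth part
    masks and planted thermal-melanism effects; classical two-cluster
    background segmentation with contour repair and mean-IoU scoring;
    deterministic colour-and-shape feature embeddings with cosine
    distances and classical multidimensional scaling; 100-m elevation
    binning with mean pairwise feature diversity, trend fitting, and
    pairwise and family-grouped bootstrap confidence intervals;
    T-statistic variance partitioning across population, assemblage and
    regional levels; HSV melanism indices (relative brightness and
    saturation of body and forewings); a standardized path analysis
    linking temperature, relative brightness and within-assemblage trait
    variation; and a colour-space constraint simulation relating darker
    HSV regions to reduced RGB variance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    utils,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
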