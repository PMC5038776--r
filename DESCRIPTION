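Package: SCMFusion
Title: Spiking Cortical Model Based Multimodal Medical Image Fusion
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pixel-level fusion of co-registered multimodal medical images
    (e.g. CT and MR slices) driven by a spiking cortical model (SCM). The
    binary pulse series emitted by the SCM yields firing-mapping images;
    patchwise Shannon entropy of the pulse trains and the Weber local
    descriptor differential excitation of the firing maps are combined into
    a per-pixel fusion weight, and a local-energy-gated weighted rule
    produces the fused image. Also implements six fusion-quality metrics
    (mutual information, edge preservation, SSIM-based index, fusion
    quality index, fusion similarity metric, standard deviation) and a
    deterministic synthetic phantom generator for complementary modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, png, tiff, yaml, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: ImageProcessing, Visualization
RoxygenNote: 7.3.3
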