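Package: epipolarity
Title: Planar Polarity, Topological Events, FRAP and Ablation Recoil
    Analysis for Segmented Epithelia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis pipeline for planar cell polarity in
    segmented epithelial tissues such as the Drosophila pupal wing.
    Provides PCA-based per-cell polarity scoring with shape
    normalization, nematic coarse-graining and magnitude-weighted
    circular histograms; extraction and orientation statistics of cell
    divisions and T1 neighbor exchanges from cell-tracking data;
    fluorescence recovery after photobleaching (FRAP) analysis with
    quality-control gates, acquisition-bleaching correction,
    normalization and one- or two-phase exponential recovery fits;
    laser-ablation recoil analysis via ellipse fitting and initial
    recoil velocimetry; axial circular statistics; and a fully seeded
    synthetic-data generator producing label-map, tracking, FRAP and
    ablation fixtures with known ground truth for end-to-end parameter
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    minpack.lm,
    jsonlite,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
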