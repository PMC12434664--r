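Package: foldscape
Title: Coarse-Grained RNA Folding Landscapes with Explicit Divalent Ions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis pipeline for RNA folding landscapes: a
    three-bead-per-nucleotide structure-based (Go-like) Langevin simulator with
    Debye-Hueckel electrostatics and explicit divalent point-charge ions;
    reaction coordinates (fraction of native contacts Q, RMSD, dRMSD);
    energy-landscape visualization by pairwise Q_w dissimilarity and a
    force-scheme 2D projection with Gaussian kernel density estimation and
    local conformational signatures; Mg-phosphate radial distribution,
    occupancy-along-Q heatmaps and ion-bridging contact maps; native base-pair
    and stacking frequency analysis; and free-energy profiles along Q from
    umbrella sampling reconstructed with the weighted histogram analysis
    method (WHAM).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
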