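Package: dentseg
Title: Multi-View Recurrent Segmentation of Teeth in 3D Dental Surface Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A projection-based detect-and-segment pipeline that labels every face of a
    3D dental arch mesh as one of sixteen tooth classes or gingiva. Given per-tooth
    mesial/distal surface landmarks, a scan is rigidly aligned to a canonical occlusion
    pose, each tooth is rendered from a spiral of orthographic viewpoints into depth and
    screen-space normal maps, a tooth-type-conditioned recurrent U-Net (bi-directional
    convolutional LSTM over the view sequence) predicts binary 2D masks, and the masks
    are unprojected back to mesh faces where multi-view-certainty region voting and
    connected-component cleanup resolve the final per-face labeling. Includes a
    parametric synthetic jaw generator with orthodontic anomalies (missing teeth,
    crowding, rotations), tessellation perturbations for robustness studies, and
    area-weighted IoU and 95th-percentile Hausdorff boundary metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
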