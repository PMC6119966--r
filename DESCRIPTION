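Package: decentnet
Title: Decentralized Multi-Site Analysis of Brain Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulated message-passing implementations of decentralized
    algorithms for multi-site neuroimaging analysis: single-shot,
    normal-equation and multi-shot (Adam) decentralized linear regression
    with decentralized R-squared and t/p inference, applied voxelwise to
    gray-matter concentration volumes (voxel-based morphometry);
    decentralized group spatial ICA (subject-level temporal PCA,
    peer-to-peer global spatial PCA, infomax ICA, spatio-temporal
    back-reconstruction); and a decentralized dynamic functional network
    connectivity pipeline (sliding-window covariances, exemplar selection,
    two-stage decentralized K-Means with centroid averaging). Every
    inter-site message is recorded so that communication costs can be
    audited against closed-form bandwidth predictions, and synthetic
    multi-site generators with known ground truth make all pipelines
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    RNifti,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
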