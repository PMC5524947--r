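Package: cryoval
Title: Per-Particle Alignment Quality Scoring for Cryo-EM Single Particle Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Soft-validation of cryo-EM single particle reconstructions by
    scoring, for every particle image, the precision and the accuracy of its
    3D alignment against the reconstructed density map. Precision is measured
    as the angular clusterability of the most similar map projections found in
    a global projection-matching search; accuracy as the geodesic consistency
    between those matches and the orientation assigned during refinement. Both
    statistics are calibrated between a Monte-Carlo random-orientation (noise)
    reference and a per-particle noise-free (perfect) reference, yielding
    linear quality scores, a global Q value (percentage of reliable
    particles), score-based particle pruning, and precision-only ranking of
    ab initio maps. Includes MRC volume/stack and STAR metadata readers and
    writers and a synthetic phantom data generator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, jsonlite, stats, utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
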