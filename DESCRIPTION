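Package: recess3d
Title: Digital Assessment of Gingival Recession Coverage from 3D Dental Cast Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying root-coverage outcomes of gingival
    recession therapy from pairs of digitized dental casts. Reads and
    validates STL surface meshes, superimposes the follow-up scan on the
    baseline scan by crown-masked point-to-plane iterative closest point
    registration, and computes per-tooth outcome metrics: recession depth
    relative to the cemento-enamel junction (CEJ), mean and complete root
    coverage, CEJ-independent recession reduction between gingival-margin
    landmarks, and gingival thickness change sampled on a mid-tooth
    sagittal profile. Includes a synthetic dental-arch generator with
    per-tooth ground truth for validation, and the statistical layer used
    in root-coverage studies: clustered factor comparisons with Scheffe
    correction, intraclass correlation coefficients, and non-inferiority
    sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    car,
    emmeans,
    jsonlite,
    nlme,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
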