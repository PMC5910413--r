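Package: craniocurv
Title: Curvature-Based Phenotyping of Metopic Head Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies orbitofrontal dysmorphology on head-surface triangle
    meshes to separate benign metopic ridge from metopic craniosynostosis.
    Reads and repairs STL surfaces, estimates signed per-vertex mean curvature
    with the cotangent Laplace-Beltrami operator (quadric-patch fitting as an
    independent estimator), segments a landmark-anchored mid-forehead strip
    and paired supraorbital bands, summarises region mean curvatures per
    subject, and clusters subjects into mild/severe phenotypes with seeded
    k-means, scoring agreement against clinician treatment labels. Synthetic
    generators (analytic fixtures, parametric heads with ridge and retrusion
    dials, feature-level cohorts) make the whole pipeline testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
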