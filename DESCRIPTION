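Package: circlehta
Title: Circle-Method Measurement of Humeral Torsion on Axial Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated geometry for measuring the humeral torsion angle
    (HTA) on digitised axial humeral-head sections. Implements the
    Circle-method (head axis through the centres of circles fitted to the
    humeral head and greater tubercle margins) and the Bernageau-Godefroy
    reference method (perpendicular to the anterior-posterior cartilage
    chord), with robust least-squares circle fitting that tolerates
    Hill-Sachs indentations. Includes a parametric phantom generator with
    known ground-truth torsion, lesion and rater-error models, a Monte
    Carlo method-comparison study, inter-rater reliability statistics
    (Cronbach's alpha ICC with Feldt interval, t-tests, chi-square), and
    n-weighted pooling of literature study records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
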