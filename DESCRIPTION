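Package: flowgrade
Title: Grading of Left Ventricular Diastolic Dysfunction from 4D Flow MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an echo-equivalent, multiparametric grading of left
    ventricular diastolic dysfunction from 4D flow MRI parameters, following
    the threshold-based 2016 ASE/EACVI decision algorithm, together with the
    method-comparison machinery needed to transfer echocardiographic grading
    cutoffs to a new modality: Bland-Altman bias-adjustment of volumetric
    cutoffs, a segmented (hockey-stick) linear model linking the peak
    tricuspid pressure gradient to the duration of vortical blood flow in the
    main pulmonary artery (yielding a surrogate cutoff for tricuspid
    regurgitant peak velocity), and ordinal agreement statistics
    (linear-weighted Cohen's kappa, Bowker symmetry test, exact binomial
    accuracies, absolute-agreement ICC). A synthetic paired-cohort generator
    reproduces the statistical structure such a validation study assumes, so
    the full pipeline is exercisable end to end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
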