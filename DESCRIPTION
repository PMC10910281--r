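Package: extmap
Title: Multivariate and Bayesian Lesion-Symptom Mapping of Visual Extinction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the neural substrate of visual extinction after
    right-hemisphere stroke from binary lesion masks and bedside behavioural
    assessments. Implements behavioural scoring (extinction score from
    confrontation testing, extinction index, Center of Cancellation, nuisance
    regression against spatial neglect), multivariate lesion-symptom mapping by
    epsilon-support-vector regression with direct total lesion volume control,
    pseudo-beta back-projection, cross-validated hyperparameter search,
    permutation inference and false-discovery-rate thresholding with cluster
    and atlas reporting, and voxel-wise Bayesian lesion-deficit inference
    (Bayes-factor maps with a covariate, evidence categorisation, and
    probabilistic-ROI summaries). A synthetic lesion-cohort simulator with
    known ground truth makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    kernlab,
    RNifti,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
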