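#' Run one full synthetic-study replicate
#'
#' Generates a cohort from `spec`, preprocesses the Raman batch (using the
#' generator's own response and interferent curves), extracts OCT texture
#' features, restricts spectra to the Welch-selected channels and runs the
#' combined leave-one-subject-out validation with Bayes fusion. This is the
#' workhorse behind the acceptance analysis and a convenient one-call
#' entry point for simulation studies.
#'
#' @param spec a [CohortSpec-class]; the seed inside it drives the run.
#' @param imageSide enface image side in pixels.
#' @param preprocess,texture configuration lists.
#' @param thresholds,prior,eps fusion settings, see
#'   [runCombinedValidation()].
#' @return list with `recordAuc` (rs, oct), `sampleAuc` (rs, oct, fused),
#'   `bands` (the band selection), `validation` (full
#'   [runCombinedValidation()] output) and `truth`.
#' @export
replicateStudy <- function(spec = cohortSpec(), imageSide = 500L,
                           preprocess = preprocessConfig(),
                           texture = textureConfig(),
                           thresholds = c(rs = 0.56, oct = 0.73),
                           prior = 0.5, eps = 1e-3) {
  cohort <- generateCohort(spec, imageSide = imageSide)
  pp <- preprocessBatch(cohort$raman, preprocess,
                        response = cohort$truth$response,
                        interferents = cohort$truth$interferents)
  sel <- pp$bands$mask
  if (!any(sel)) {
    message("no channel passed band selection; using all channels")
    sel <- rep(TRUE, length(sel))
  }
  rsFeat <- t(spectra(pp$processed))[, sel, drop = FALSE]
  fx <- octFeatureMatrix(cohort$oct, texture)
  res <- runCombinedValidation(
    rsFeat, as.data.frame(recordInfo(pp$processed)),
    fx$features, as.data.frame(recordInfo(cohort$oct)), fx$blocks,
    thresholds = thresholds, prior = prior, eps = eps)
  list(recordAuc = c(rs = rocAuc(res$records$rs$roc),
                     oct = rocAuc(res$records$oct$roc)),
       sampleAuc = vapply(res$sampleRoc, rocAuc, numeric(1)),
       bands = pp$bands,
       validation = res,
       truth = cohort$truth)
}
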