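#' Bayesian update of a disease probability from one diagnostic test
#'
#' Treats one binary test result with known true/false positive rates as
#' evidence: a positive result maps the prior through
#' `tpr * prior / (tpr * prior + fpr * (1 - prior))`, a negative result
#' through `1 - (1 - fpr)(1 - prior) / ((1 - fpr)(1 - prior) + (1 - tpr) * prior)`.
#' With `tpr = fpr` the likelihood ratio is 1 and the prior is returned
#' unchanged; priors of exactly 0 or 1 are absorbing.
#'
#' @param prior prior disease probability in \[0, 1\].
#' @param tpr,fpr test sensitivity and false positive rate, in (0, 1);
#'   callers clip degenerate rates (see [runCombinedValidation()]).
#' @param decision `"positive"` or `"negative"`.
#' @return posterior probability.
#' @export
updatePosterior <- function(prior, tpr, fpr,
                            decision = c("positive", "negative")) {
  decision <- match.arg(decision)
  if (prior < 0 || prior > 1) stop("prior must be in [0, 1]")
  if (tpr <= 0 || tpr >= 1 || fpr <= 0 || fpr >= 1)
    stop("tpr and fpr must be inside (0, 1); clip degenerate rates first")
  if (decision == "positive") {
    tpr * prior / (tpr * prior + fpr * (1 - prior))
  } else {
    1 - (1 - fpr) * (1 - prior) /
      ((1 - fpr) * (1 - prior) + (1 - tpr) * prior)
  }
}

#' Sequentially fuse per-record decisions into a sample posterior
#'
#' Folds [updatePosterior()] over an ordered list of decisions; an empty
#' list returns the prior. Because each update multiplies the prior odds by
#' the test's likelihood ratio, the final posterior is invariant to the
#' order of the decisions.
#'
#' @param decisions data.frame with columns `modality`, `decision`
#'   (`"positive"`/`"negative"`), `tpr`, `fpr` (one row per record), or an
#'   empty data.frame / `NULL`.
#' @param prior starting probability (default 0.5).
#' @return list of class `"SamplePosterior"`: `prior`, `posterior`, and
#'   `updateLog` (the input decisions with a `posterior` column appended in
#'   application order).
#' @export
fuseSample <- function(decisions = NULL, prior = 0.5) {
  if (is.null(decisions) || nrow(decisions) == 0L) {
    return(structure(list(prior = prior, posterior = prior,
                          updateLog = data.frame()),
                     class = "SamplePosterior"))
  }
  post <- prior
  n <- nrow(decisions)
  trace <- numeric(n)
  tpr <- decisions$tpr; fpr <- decisions$fpr; dec <- decisions$decision
  for (i in seq_len(n)) {
    post <- updatePosterior(post, tpr[i], fpr[i], dec[i])
    trace[i] <- post
  }
  log <- decisions
  log$posterior <- trace
  structure(list(prior = prior, posterior = post, updateLog = log),
            class = "SamplePosterior")
}

#' @export
print.SamplePosterior <- function(x, ...) {
  cat(sprintf("SamplePosterior: prior %.3f -> posterior %.4f after %d update(s)\n",
              x$prior, x$posterior, nrow(x$updateLog)))
  invisible(x)
}

## tpr/fpr of thresholded training probabilities, clipped away from {0, 1}
trainRatesAt <- function(prob, y, threshold, eps = 1e-3) {
  pos <- prob >= threshold
  tpr <- sum(pos & y) / sum(y)
  fpr <- sum(pos & !y) / sum(!y)
  c(tpr = clip(tpr, eps, 1 - eps), fpr = clip(fpr, eps, 1 - eps))
}

#' Combined leave-one-subject-out validation with Bayes fusion
#'
#' Runs the full two-modality validation: for every outer fold (held-out
#' subject) both modality models are trained on the remaining subjects with
#' the same standardize / PCA / nested-CV-tuned-LDA fitting used by
#' [validateModality()]; the fold's tpr/fpr at the fixed decision thresholds are read off
#' the thresholded training-set predictions (clipped into
#' `[eps, 1 - eps]`). Each held-out sample starts at the prior, its Raman
#' records update the posterior first, then its OCT records; the posterior
#' of each sample is computed exactly once. Samples without records in a
#' modality simply receive no updates from it (a sample with no records at
#' all keeps the prior, with a message).
#'
#' Three fusion modes are reported from the same record decisions:
#' `rs` (Raman updates only), `oct` (OCT only) and `fused` (both).
#'
#' @param rsFeatures,rsMeta Raman feature matrix (records x features, e.g.
#'   processed spectra restricted to selected bands) and metadata.
#' @param octFeatures,octMeta OCT texture features and metadata.
#' @param octBlocks block index list from [octFeatureMatrix()].
#' @param thresholds named vector: fixed decision thresholds per modality
#'   (defaults `c(rs = 0.56, oct = 0.73)`, the validated operating points).
#' @param prior starting probability per sample (default 0.5).
#' @param eps clipping bound for degenerate fold rates (default 1e-3).
#' @param rsComponents,octComponents PCA dimensions.
#' @param grid hyperparameter grid.
#' @return list with:
#'   `samples` (data.frame: sample_id, subject_id, label, nRs, nOct,
#'   posteriorRs, posteriorOct, posteriorFused),
#'   `sampleRoc` (list of [RocCurve-class] per mode),
#'   `records` (per-modality pooled record predictions and ROC),
#'   `folds` (per-fold chosen configs and clipped rates),
#'   `updateLogs` (per-sample decision logs, fused mode).
#' @export
runCombinedValidation <- function(rsFeatures, rsMeta, octFeatures, octMeta,
                                  octBlocks,
                                  thresholds = c(rs = 0.56, oct = 0.73),
                                  prior = 0.5, eps = 1e-3,
                                  rsComponents = 10L, octComponents = 10L,
                                  grid = ldaGrid()) {
  rsMeta <- as.data.frame(rsMeta); octMeta <- as.data.frame(octMeta)
  samples <- unique(rbind(rsMeta[c("sample_id", "subject_id", "label")],
                          octMeta[c("sample_id", "subject_id", "label")]))
  rownames(samples) <- NULL
  subjects <- unique(samples$subject_id)
  if (length(subjects) < 2L) stop("need at least 2 subjects")

  rsProb <- rep(NA_real_, nrow(rsMeta))
  octProb <- rep(NA_real_, nrow(octMeta))
  out <- samples
  out$nRs <- 0L; out$nOct <- 0L
  out$posteriorRs <- NA_real_; out$posteriorOct <- NA_real_
  out$posteriorFused <- NA_real_
  foldInfo <- list()
  updateLogs <- list()

  for (s in subjects) {
    rsTr <- which(rsMeta$subject_id != s); rsTe <- which(rsMeta$subject_id == s)
    octTr <- which(octMeta$subject_id != s); octTe <- which(octMeta$subject_id == s)

    rsFit <- fitModalityFold(rsFeatures[rsTr, , drop = FALSE], rsMeta[rsTr, ],
                             rsComponents, NULL, grid)
    octFit <- fitModalityFold(octFeatures[octTr, , drop = FALSE], octMeta[octTr, ],
                              octComponents, octBlocks, grid)
    rsRates <- trainRatesAt(rsFit$trainProb, rsFit$trainLabel,
                            thresholds["rs"], eps)
    octRates <- trainRatesAt(octFit$trainProb, octFit$trainLabel,
                             thresholds["oct"], eps)
    if (length(rsTe))
      rsProb[rsTe] <- ldaPredict(rsFit$tuned$model,
                                 rsFit$transform(rsFeatures[rsTe, , drop = FALSE]))
    if (length(octTe))
      octProb[octTe] <- ldaPredict(octFit$tuned$model,
                                   octFit$transform(octFeatures[octTe, , drop = FALSE]))
    foldInfo[[s]] <- list(subject = s,
                          rsConfig = rsFit$tuned$config,
                          octConfig = octFit$tuned$config,
                          rsRates = rsRates, octRates = octRates)

    for (i in which(out$subject_id == s)) {
      sid <- out$sample_id[i]
      ri <- rsTe[rsMeta$sample_id[rsTe] == sid]
      oi <- octTe[octMeta$sample_id[octTe] == sid]
      out$nRs[i] <- length(ri); out$nOct[i] <- length(oi)
      mkDecisions <- function(idx, probs, rates, modality, thr)
        if (!length(idx)) NULL else data.frame(
          modality = modality,
          record_id = if (modality == "RS") rsMeta$record_id[idx]
                      else octMeta$record_id[idx],
          decision = ifelse(probs[idx] >= thr, "positive", "negative"),
          tpr = rates["tpr"], fpr = rates["fpr"], threshold = thr,
          row.names = NULL)
      rsDec <- mkDecisions(ri, rsProb, rsRates, "RS", thresholds[["rs"]])
      octDec <- mkDecisions(oi, octProb, octRates, "OCT", thresholds[["oct"]])
      both <- rbind(rsDec, octDec)
      if (is.null(both) || nrow(both) == 0L)
        message("sample ", sid, " has no records in either modality; ",
                "posterior stays at the prior")
      out$posteriorRs[i] <- fuseSample(rsDec, prior)$posterior
      out$posteriorOct[i] <- fuseSample(octDec, prior)$posterior
      fused <- fuseSample(both, prior)
      out$posteriorFused[i] <- fused$posterior
      updateLogs[[sid]] <- fused$updateLog
    }
  }

  rsPred <- data.frame(rsMeta[c("record_id", "subject_id", "sample_id", "label")],
                       probability = rsProb)
  octPred <- data.frame(octMeta[c("record_id", "subject_id", "sample_id", "label")],
                        probability = octProb)
  list(samples = out,
       sampleRoc = list(rs = rocCurve(out$posteriorRs, out$label),
                        oct = rocCurve(out$posteriorOct, out$label),
                        fused = rocCurve(out$posteriorFused, out$label)),
       records = list(rs = list(predictions = rsPred,
                                roc = rocCurve(rsProb, rsMeta$label)),
                      oct = list(predictions = octPred,
                                 roc = rocCurve(octProb, octMeta$label))),
       folds = foldInfo,
       updateLogs = updateLogs,
       thresholds = thresholds, prior = prior, eps = eps)
}

#' Operating-point report for sample posteriors
#'
#' For each mode, the sample-level ROC with three operating points: the
#' Youden optimum, the confirmatory test (fixed FPR = 0.1, high
#' specificity) and the screening test (fixed TPR = 0.9, high sensitivity),
#' each with its threshold, confusion counts and the five derived
#' statistics at 2 decimals.
#'
#' @param samples `samples` data.frame from [runCombinedValidation()] (or
#'   any data.frame with a `label` column and posterior columns).
#' @param modes named character vector mapping mode name to posterior
#'   column.
#' @param fixedFpr,fixedTpr requested rates for the C- and S-test points.
#' @return nested list: per mode, `auc`, `roc` and per operating point the
#'   `threshold`, `point` and `"ConfusionMatrix"`.
#' @export
operatingPointReport <- function(samples,
                                 modes = c(rs = "posteriorRs",
                                           oct = "posteriorOct",
                                           fused = "posteriorFused"),
                                 fixedFpr = 0.1, fixedTpr = 0.9) {
  lab <- samples$label
  if (length(unique(asTumorLogical(lab))) < 2L)
    stop("both classes must be present")
  out <- list()
  for (m in names(modes)) {
    post <- samples[[modes[[m]]]]
    roc <- rocCurve(post, lab)
    pts <- list(youden = youdenPoint(roc),
                ctest = pointAtFpr(roc, fixedFpr),
                stest = pointAtTpr(roc, fixedTpr))
    out[[m]] <- list(auc = rocAuc(roc), roc = roc,
                     points = lapply(pts, function(p)
                       list(kind = p$kind, threshold = p$threshold,
                            fpr = p$fpr, tpr = p$tpr,
                            confusion = confusionAt(post, lab, p$threshold))))
  }
  out
}
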