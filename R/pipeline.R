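#' Default run configuration
#'
#' A run configuration is a plain nested list (round-trippable through
#' YAML): a synthetic cohort block (or input paths), the preprocessing,
#' texture and validation settings, the fusion thresholds and the output
#' directory. [runPipeline()] writes the fully resolved configuration next
#' to its outputs so a run directory is self-describing.
#'
#' @param outputDir output directory.
#' @param seed top-level seed; all randomness of a run flows from it.
#' @param imageSide synthetic image side in pixels.
#' @return configuration list.
#' @export
runConfig <- function(outputDir = tempfile("probefusion_run_"),
                      seed = 1L, imageSide = 500L) {
  list(
    cohort = list(synthetic = TRUE, inputDir = NULL,
                  nSubjects = 27L, nHealthySamples = 21L, nTumorSamples = 40L,
                  meanRsRecordsPerSample = 303 / 61,
                  meanOctRecordsPerSample = 346 / 61,
                  tumorPurityRange = c(0.1, 1),
                  rsEffectSize = 5, octEffectSize = 1,
                  imageSide = as.integer(imageSide)),
    preprocess = preprocessConfig(),
    texture = textureConfig(),
    validation = list(rsComponents = 10L, octComponents = 10L),
    fusion = list(rsThreshold = 0.56, octThreshold = 0.73,
                  prior = 0.5, eps = 1e-3),
    outputDir = outputDir,
    seed = as.integer(seed),
    plots = FALSE)
}

#' Validate a record metadata table
#'
#' Checks the invariants the pipeline relies on: required columns present,
#' every sample belongs to exactly one subject, labels constant within a
#' sample and valid, no duplicated record ids. Errors name the offending
#' record or sample.
#'
#' @param meta data.frame with columns `subject_id`, `sample_id`,
#'   `record_id`, `modality`, `label`.
#' @return the checked table, unchanged.
#' @export
validateMetadata <- function(meta) {
  need <- c("subject_id", "sample_id", "record_id", "modality", "label")
  miss <- setdiff(need, colnames(meta))
  if (length(miss))
    stop("metadata misses column(s): ", paste(miss, collapse = ", "))
  dup <- meta$record_id[duplicated(meta$record_id)]
  if (length(dup))
    stop("duplicated record id(s): ", paste(unique(dup), collapse = ", "))
  if (!all(meta$label %in% c("healthy", "tumor"))) {
    bad <- meta$record_id[!meta$label %in% c("healthy", "tumor")]
    stop("invalid label for record(s): ", paste(bad, collapse = ", "))
  }
  bySample <- split(meta, meta$sample_id)
  for (s in names(bySample)) {
    if (length(unique(bySample[[s]]$subject_id)) > 1L)
      stop("sample ", s, " is assigned to more than one subject (records ",
           paste(bySample[[s]]$record_id, collapse = ", "), ")")
    if (length(unique(bySample[[s]]$label)) > 1L)
      stop("sample ", s, " carries more than one label")
  }
  if (!all(meta$modality %in% c("RS", "OCT")))
    stop("modality must be 'RS' or 'OCT'")
  meta
}

## fuse one modality's validated predictions into per-sample posteriors,
## using each fold's training rates at the fixed threshold
fuseBySample <- function(validated, threshold, prior = 0.5, eps = 1e-3) {
  pred <- validated$predictions
  samples <- unique(pred[c("sample_id", "subject_id", "label")])
  rownames(samples) <- NULL
  samples$posterior <- NA_real_
  samples$n <- 0L
  for (i in seq_len(nrow(samples))) {
    rows <- pred[pred$sample_id == samples$sample_id[i], ]
    fit <- validated$models[[samples$subject_id[i]]]
    rates <- trainRatesAt(fit$trainProb, fit$trainLabel, threshold, eps)
    dec <- data.frame(
      modality = "single", record_id = rows$record_id,
      decision = ifelse(rows$probability >= threshold, "positive", "negative"),
      tpr = rates["tpr"], fpr = rates["fpr"], threshold = threshold,
      row.names = NULL)
    samples$posterior[i] <- fuseSample(dec, prior)$posterior
    samples$n[i] <- nrow(rows)
  }
  samples
}

#' Run the full analysis pipeline
#'
#' Orchestrates generate (or load), preprocess, texture extraction,
#' leave-one-subject-out validation, Bayes fusion and reporting, writing
#' all artifacts under `config$outputDir`: the resolved configuration,
#' metadata, record predictions, sample posteriors, ROC curves, the
#' operating-point report and a machine-readable `summary.json`. With only
#' one modality available the other modes are skipped with a notice.
#'
#' @param config list from [runConfig()] (possibly edited) or the path of a
#'   YAML file holding one.
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config = runConfig()) {
  if (is.character(config)) config <- resolveConfig(yaml::read_yaml(config))
  else config <- resolveConfig(config)
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(config$outputDir, "resolved_config.yaml"))

  ## data
  truth <- NULL
  if (isTRUE(config$cohort$synthetic)) {
    co <- config$cohort
    spec <- cohortSpec(co$nSubjects, co$nHealthySamples, co$nTumorSamples,
                       co$meanRsRecordsPerSample, co$meanOctRecordsPerSample,
                       co$tumorPurityRange, co$rsEffectSize, co$octEffectSize,
                       seed = config$seed)
    cohort <- generateCohort(spec, imageSide = co$imageSide)
    truth <- cohort$truth
  } else {
    if (is.null(config$cohort$inputDir))
      stop("non-synthetic runs need cohort$inputDir")
    cohort <- readCohort(config$cohort$inputDir)
  }
  raman <- cohort$raman; oct <- cohort$oct
  if (is.null(raman) && is.null(oct)) stop("no modality data available")

  rsFeat <- NULL; rsMeta <- NULL; bands <- NULL
  if (!is.null(raman)) {
    pp <- preprocessBatch(raman, config$preprocess,
                          response = truth$response,
                          interferents = truth$interferents)
    bands <- pp$bands
    sel <- bands$mask
    if (!any(sel)) {
      message("no channel passed band selection; using all channels")
      sel <- rep(TRUE, length(bands$mask))
    }
    rsFeat <- t(spectra(pp$processed))[, sel, drop = FALSE]
    rsMeta <- as.data.frame(recordInfo(pp$processed))
  }
  octFeat <- NULL; octMeta <- NULL; octBlocks <- NULL
  if (!is.null(oct)) {
    fx <- octFeatureMatrix(oct, config$texture)
    octFeat <- fx$features; octBlocks <- fx$blocks
    octMeta <- as.data.frame(recordInfo(oct))
  }

  ## validation + fusion
  out <- config$outputDir
  summary <- list(seed = config$seed,
                  nRsRecords = if (is.null(rsMeta)) 0L else nrow(rsMeta),
                  nOctRecords = if (is.null(octMeta)) 0L else nrow(octMeta))
  if (!is.null(rsFeat) && !is.null(octFeat)) {
    res <- runCombinedValidation(
      rsFeat, rsMeta, octFeat, octMeta, octBlocks,
      thresholds = c(rs = config$fusion$rsThreshold,
                     oct = config$fusion$octThreshold),
      prior = config$fusion$prior, eps = config$fusion$eps,
      rsComponents = config$validation$rsComponents,
      octComponents = config$validation$octComponents)
    report <- operatingPointReport(res$samples)
    write.csv(res$samples, file.path(out, "sample_posteriors.csv"),
              row.names = FALSE)
    write.csv(res$records$rs$predictions,
              file.path(out, "rs_record_predictions.csv"), row.names = FALSE)
    write.csv(res$records$oct$predictions,
              file.path(out, "oct_record_predictions.csv"), row.names = FALSE)
    for (m in names(res$sampleRoc))
      writeRoc(res$sampleRoc[[m]], file.path(out, paste0("roc_sample_", m, ".csv")))
    writeRoc(res$records$rs$roc, file.path(out, "roc_record_rs.csv"))
    writeRoc(res$records$oct$roc, file.path(out, "roc_record_oct.csv"))
    summary$recordAuc <- list(rs = rocAuc(res$records$rs$roc),
                              oct = rocAuc(res$records$oct$roc))
    summary$sampleAuc <- lapply(res$sampleRoc, rocAuc)
    summary$operatingPoints <- reportToList(report)
    summary$folds <- lapply(res$folds, function(f)
      list(subject = f$subject,
           rsSolver = f$rsConfig$solver, rsTol = f$rsConfig$tol,
           octSolver = f$octConfig$solver, octTol = f$octConfig$tol,
           rsTpr = unname(f$rsRates["tpr"]), rsFpr = unname(f$rsRates["fpr"]),
           octTpr = unname(f$octRates["tpr"]), octFpr = unname(f$octRates["fpr"])))
    if (isTRUE(config$plots)) {
      plotRocOverlay(res$sampleRoc, file.path(out, "roc_overlay.png"))
      plotPosteriors(res$samples, file.path(out, "posteriors.png"),
                     report = report)
    }
  } else {
    mode <- if (is.null(octFeat)) "rs" else "oct"
    message("only the ", toupper(mode),
            " modality is available; other modes skipped")
    if (mode == "rs") {
      v <- validateModality(rsFeat, rsMeta,
                            nComponents = config$validation$rsComponents)
      thr <- config$fusion$rsThreshold
    } else {
      v <- validateModality(octFeat, octMeta,
                            nComponents = config$validation$octComponents,
                            blocks = octBlocks)
      thr <- config$fusion$octThreshold
    }
    fused <- fuseBySample(v, thr, config$fusion$prior, config$fusion$eps)
    write.csv(v$predictions,
              file.path(out, paste0(mode, "_record_predictions.csv")),
              row.names = FALSE)
    write.csv(fused, file.path(out, "sample_posteriors.csv"), row.names = FALSE)
    writeRoc(v$roc, file.path(out, paste0("roc_record_", mode, ".csv")))
    summary$recordAuc <- setNames(list(rocAuc(v$roc)), mode)
    summary$sampleAuc <- setNames(
      list(rocAuc(rocCurve(fused$posterior, fused$label))), mode)
    report <- operatingPointReport(fused, modes = setNames("posterior", mode))
    summary$operatingPoints <- reportToList(report)
  }
  if (!is.null(bands)) {
    writeBandSelection(bands, file.path(out, "selected_bands.csv"))
    summary$nSelectedChannels <- sum(bands$mask)
    summary$nSelectedRegions <- nrow(bands$regions)
  }
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

reportToList <- function(report) {
  lapply(report, function(m)
    list(auc = m$auc,
         points = lapply(m$points, function(p)
           list(kind = p$kind, threshold = p$threshold, fpr = p$fpr,
                tpr = p$tpr,
                counts = as.list(p$confusion$counts),
                stats = as.list(p$confusion$rounded)))))
}

## deep-merge user config over defaults so partial YAML files work
resolveConfig <- function(config) {
  merge2 <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge2(base[[nm]], upd[[nm]])
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  merge2(runConfig(), config)
}

#' Diagnostic plots
#'
#' `plotRocOverlay` draws the per-mode sample-level ROC curves on one
#' canvas; `plotPosteriors` draws the per-sample posterior strip chart with
#' the operating-point thresholds as dashed lines.
#'
#' @param rocs named list of [RocCurve-class] objects.
#' @param file PNG path (`NULL` draws on the active device).
#' @export
plotRocOverlay <- function(rocs, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, 600, 600)
    on.exit(grDevices::dev.off())
  }
  cols <- c("goldenrod", "steelblue", "gray30")[seq_along(rocs)]
  graphics::plot(0:1, 0:1, type = "l", lty = 3, col = "gray",
                 xlab = "False positive rate", ylab = "True positive rate")
  for (i in seq_along(rocs))
    graphics::lines(rocs[[i]]@fpr, rocs[[i]]@tpr, col = cols[i], lwd = 2)
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.2f)", names(rocs),
                                    vapply(rocs, rocAuc, numeric(1))),
                   col = cols, lwd = 2, bty = "n")
  invisible(NULL)
}

#' @rdname plotRocOverlay
#' @param samples sample posterior data.frame from [runCombinedValidation()].
#' @param report optional [operatingPointReport()] output supplying
#'   threshold lines.
#' @export
plotPosteriors <- function(samples, file = NULL, report = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, 800, 500)
    on.exit(grDevices::dev.off())
  }
  y <- samples$posteriorFused %||% samples$posterior
  tum <- asTumorLogical(samples$label)
  graphics::plot(seq_along(y), y, pch = ifelse(tum, 19, 17),
                 col = ifelse(tum, "firebrick", "steelblue"),
                 ylim = c(0, 1), xlab = "Sample", ylab = "Tumor posterior")
  if (!is.null(report) && !is.null(report$fused))
    for (p in report$fused$points)
      graphics::abline(h = p$threshold, lty = 2, col = "gray40")
  graphics::legend("right", legend = c("tumor", "healthy"),
                   pch = c(19, 17), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(NULL)
}
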