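#' Write a cohort to disk
#'
#' Spectra go to `raman_spectra.csv` (first column `wavenumber`, one column
#' per record), images to 16-bit grayscale TIFFs under `images/`, the
#' record metadata of both modalities to `metadata.csv` (columns
#' `subject_id`, `sample_id`, `record_id`, `modality`, `label`, `path`) and
#' the generator ground truth, when present, to `ground_truth.json`.
#'
#' @param cohort list with `raman`, `oct` and optionally `truth`, as
#'   returned by [generateCohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rs <- cohort$raman; oc <- cohort$oct
  df <- data.frame(wavenumber = wavenumbers(rs), spectra(rs),
                   check.names = FALSE)
  colnames(df) <- c("wavenumber", recordInfo(rs)$record_id)
  write.csv(df, file.path(dir, "raman_spectra.csv"), row.names = FALSE)

  oinfo <- as.data.frame(recordInfo(oc))
  paths <- file.path("images", paste0(oinfo$record_id, ".tiff"))
  for (i in seq_along(images(oc)))
    tiff::writeTIFF(images(oc)[[i]], file.path(dir, paths[i]),
                    bits.per.sample = 16)

  rinfo <- as.data.frame(recordInfo(rs))
  meta <- rbind(
    data.frame(subject_id = rinfo$subject_id, sample_id = rinfo$sample_id,
               record_id = rinfo$record_id, modality = "RS",
               label = rinfo$label, path = "raman_spectra.csv"),
    data.frame(subject_id = oinfo$subject_id, sample_id = oinfo$sample_id,
               record_id = oinfo$record_id, modality = "OCT",
               label = oinfo$label, path = paths))
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)

  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(samples = tr$samples, rsRecords = tr$rsRecords,
           octRecords = tr$octRecords, bands = tr$bands,
           shiftedBands = tr$shiftedBands),
      file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory holding `metadata.csv`, `raman_spectra.csv` and
#'   `images/`.
#' @param pixelSize micrometres per pixel of the stored images.
#' @return list with `raman` ([RamanExperiment-class]) and `oct`
#'   ([EnfaceImageSet-class]); either may be `NULL` when that modality is
#'   absent.
#' @export
readCohort <- function(dir, pixelSize = 4) {
  meta <- validateMetadata(read.csv(file.path(dir, "metadata.csv")))
  raman <- NULL; oct <- NULL
  rsMeta <- meta[meta$modality == "RS", ]
  if (nrow(rsMeta)) {
    df <- read.csv(file.path(dir, "raman_spectra.csv"), check.names = FALSE)
    missing <- setdiff(rsMeta$record_id, colnames(df))
    if (length(missing))
      stop("spectra missing for record(s): ", paste(missing, collapse = ", "))
    raman <- RamanExperiment(as.matrix(df[, rsMeta$record_id, drop = FALSE]),
                             df$wavenumber,
                             rsMeta[c("record_id", "subject_id",
                                      "sample_id", "label")])
  }
  octMeta <- meta[meta$modality == "OCT", ]
  if (nrow(octMeta)) {
    imgs <- lapply(seq_len(nrow(octMeta)), function(i) {
      f <- file.path(dir, octMeta$path[i])
      if (!file.exists(f))
        stop("image missing for record ", octMeta$record_id[i], ": ", f)
      img <- tiff::readTIFF(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    })
    oct <- EnfaceImageSet(imgs,
                          octMeta[c("record_id", "subject_id",
                                    "sample_id", "label")],
                          pixelSize = pixelSize)
  }
  list(raman = raman, oct = oct)
}

#' Export a band selection as a CSV of regions
#'
#' @param bands a `"BandSelection"` from [welchBandSelect()].
#' @param file output path.
#' @export
writeBandSelection <- function(bands, file) {
  write.csv(bands$regions[c("startWavenumber", "endWavenumber")], file,
            row.names = FALSE)
  invisible(file)
}

#' Export a ROC curve as CSV (threshold, fpr, tpr)
#'
#' @param roc a [RocCurve-class].
#' @param file output path.
#' @export
writeRoc <- function(roc, file) {
  write.csv(data.frame(threshold = roc@thresholds, fpr = roc@fpr,
                       tpr = roc@tpr), file, row.names = FALSE)
  invisible(file)
}
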