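#' @describeIn RamanExperiment-class wavenumber axis (cm^-1).
#' @export
setMethod("wavenumbers", "RamanExperiment",
          function(x) rowData(x)$wavenumber)

#' @describeIn RamanExperiment-class intensity matrix (channels x records).
#' @export
setMethod("spectra", "RamanExperiment",
          function(x) assay(x, "intensities"))

#' @describeIn RamanExperiment-class record metadata.
#' @export
setMethod("recordInfo", "RamanExperiment", function(x) colData(x))

#' @describeIn EnfaceImageSet-class list of image matrices.
#' @export
setMethod("images", "EnfaceImageSet", function(x) x@images)

#' @describeIn EnfaceImageSet-class micrometres per pixel.
#' @export
setMethod("pixelSize", "EnfaceImageSet", function(x) x@pixelSize)

#' @describeIn EnfaceImageSet-class field of view in millimetres.
#' @export
setMethod("fieldOfView", "EnfaceImageSet", function(x) x@fieldOfView)

#' @describeIn EnfaceImageSet-class record metadata.
#' @export
setMethod("recordInfo", "EnfaceImageSet", function(x) x@recordInfo)

#' @describeIn EnfaceImageSet-class number of images.
#' @export
setMethod("length", "EnfaceImageSet", function(x) length(x@images))

#' @describeIn EnfaceImageSet-class subset records.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "EnfaceImageSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, images = x@images[i], recordInfo = x@recordInfo[i, , drop = FALSE])
})

#' @describeIn RocCurve-class area under the curve.
#' @export
setMethod("rocAuc", "RocCurve", function(x) x@auc)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec\n")
  cat(sprintf("  subjects: %d | samples: %d healthy + %d tumor\n",
              object@nSubjects, object@nHealthySamples, object@nTumorSamples))
  cat(sprintf("  mean records/sample: RS %.2f, OCT %.2f\n",
              object@meanRsRecordsPerSample, object@meanOctRecordsPerSample))
  cat(sprintf("  tumor purity: [%.2f, %.2f] | effect sizes: RS %.2f, OCT %.2f\n",
              object@tumorPurityRange[1], object@tumorPurityRange[2],
              object@rsEffectSize, object@octEffectSize))
  cat(sprintf("  seed: %d\n", object@seed))
})

setMethod("show", "EnfaceImageSet", function(object) {
  side <- if (length(object@images)) nrow(object@images[[1]]) else 0L
  cat(sprintf("EnfaceImageSet with %d images (%d x %d px, %.1f um/px, %.1f mm FOV)\n",
              length(object@images), side, side, object@pixelSize,
              object@fieldOfView))
  tab <- table(object@recordInfo$label)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve with %d points, AUC = %.3f\n",
              length(object@thresholds), object@auc))
})
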