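#' Specification of a synthetic measurement cohort
#'
#' A `CohortSpec` holds the parameters of the hierarchical synthetic cohort
#' generator: subjects contain tissue samples, samples contain Raman and OCT
#' measurement records. The defaults reproduce the scale of the clinical
#' dataset the package emulates: 27 subjects, 21 healthy + 40 tumor samples,
#' and on average about 303 Raman and 346 OCT records in total.
#'
#' @slot nSubjects number of subjects.
#' @slot nHealthySamples,nTumorSamples sample counts per class.
#' @slot meanRsRecordsPerSample,meanOctRecordsPerSample mean records per
#'   sample; actual counts are drawn as 1 + Poisson(mean - 1).
#' @slot tumorPurityRange range of the per-sample tumor purity fraction;
#'   each record of a tumor sample is tumor-like with probability equal to
#'   the sample's purity, so tumor samples can contain healthy-like records.
#' @slot rsEffectSize class-dependent Raman peak-amplitude shift in units of
#'   the nominal per-channel noise sd.
#' @slot octEffectSize amplitude of the oriented fibrous component added to
#'   tumor-like enface images, in units of the mean speckle level.
#' @slot seed integer seed driving the whole cohort realization.
#'
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(
    nSubjects = "integer",
    nHealthySamples = "integer",
    nTumorSamples = "integer",
    meanRsRecordsPerSample = "numeric",
    meanOctRecordsPerSample = "numeric",
    tumorPurityRange = "numeric",
    rsEffectSize = "numeric",
    octEffectSize = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@nHealthySamples < 1L || object@nTumorSamples < 1L)
    msg <- c(msg, "both classes need at least one sample")
  if (object@meanRsRecordsPerSample < 1 || object@meanOctRecordsPerSample < 1)
    msg <- c(msg, "mean records per sample must be >= 1")
  pr <- object@tumorPurityRange
  if (length(pr) != 2L || any(!is.finite(pr)) || pr[1] > pr[2] ||
      pr[1] < 0 || pr[2] > 1)
    msg <- c(msg, "tumorPurityRange must be an ordered pair within [0, 1]")
  if (object@rsEffectSize < 0 || object@octEffectSize < 0)
    msg <- c(msg, "effect sizes must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Container for a batch of Raman spectra
#'
#' `RamanExperiment` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]:
#' rows are wavenumber channels (with the axis in `rowData(x)$wavenumber`,
#' cm^-1, strictly increasing), columns are measurement records, and
#' `colData` carries `record_id`, `subject_id`, `sample_id` and `label`
#' (`"healthy"` or `"tumor"`). The single assay `"intensities"` holds the
#' spectra in arbitrary counts units.
#'
#' @seealso [RamanExperiment()] constructor, [preprocessBatch()]
#' @export
setClass("RamanExperiment", contains = "SummarizedExperiment")

setValidity("RamanExperiment", function(object) {
  msg <- character()
  wn <- rowData(object)$wavenumber
  if (is.null(wn)) return("rowData must contain a 'wavenumber' column")
  if (any(!is.finite(wn)) || any(diff(wn) <= 0))
    msg <- c(msg, "wavenumber axis must be finite and strictly increasing")
  if (!"intensities" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensities' is required")
  else if (!all(is.finite(assay(object, "intensities"))))
    msg <- c(msg, "intensities must be finite")
  cd <- colData(object)
  need <- c("record_id", "subject_id", "sample_id", "label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData misses column(s):", paste(miss, collapse = ", ")))
  else if (!all(cd$label %in% c("healthy", "tumor")))
    msg <- c(msg, "label must be 'healthy' or 'tumor'")
  if (length(msg)) msg else TRUE
})

#' Container for OCT enface images
#'
#' Holds one grayscale enface image per OCT measurement, together with the
#' record metadata, the pixel size (micrometres per pixel) and the field of
#' view (millimetres). Images are square numeric matrices with finite,
#' non-negative values; the side length times the pixel size must equal the
#' field of view.
#'
#' @slot images list of square numeric matrices.
#' @slot recordInfo [S4Vectors::DataFrame] with `record_id`, `subject_id`,
#'   `sample_id`, `label`.
#' @slot pixelSize micrometres per pixel (default 4).
#' @slot fieldOfView millimetres (default 2).
#' @seealso [EnfaceImageSet()] constructor, [extractTextureBlocks()]
#' @export
setClass("EnfaceImageSet",
  representation(
    images = "list",
    recordInfo = "DataFrame",
    pixelSize = "numeric",
    fieldOfView = "numeric"
  )
)

setValidity("EnfaceImageSet", function(object) {
  msg <- character()
  if (length(object@images) != nrow(object@recordInfo))
    msg <- c(msg, "one metadata row per image is required")
  need <- c("record_id", "subject_id", "sample_id", "label")
  miss <- setdiff(need, colnames(object@recordInfo))
  if (length(miss))
    msg <- c(msg, paste("recordInfo misses column(s):", paste(miss, collapse = ", ")))
  for (img in object@images) {
    if (!is.matrix(img) || nrow(img) != ncol(img)) {
      msg <- c(msg, "images must be square matrices"); break
    }
    if (!cpp_all_finite(img) || min(img) < 0) {
      msg <- c(msg, "image intensities must be finite and non-negative"); break
    }
    fovPx <- nrow(img) * object@pixelSize / 1000
    if (abs(fovPx - object@fieldOfView) > 0.05 * object@fieldOfView) {
      msg <- c(msg, "image side x pixel size must match the field of view"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve
#'
#' Thresholds are decreasing; `fpr` and `tpr` are non-decreasing, start at
#' (0, 0) and end at (1, 1); `auc` is the trapezoidal area under the curve.
#' A score is called positive when it is greater than or equal to the
#' threshold.
#'
#' @slot thresholds decreasing numeric vector (first element `Inf`).
#' @slot fpr,tpr false/true positive rates per threshold.
#' @slot auc trapezoidal area under the curve.
#' @seealso [rocCurve()], [youdenPoint()]
#' @export
setClass("RocCurve",
  representation(
    thresholds = "numeric",
    fpr = "numeric",
    tpr = "numeric",
    auc = "numeric"
  )
)

setValidity("RocCurve", function(object) {
  msg <- character()
  n <- length(object@thresholds)
  if (length(object@fpr) != n || length(object@tpr) != n)
    msg <- c(msg, "thresholds, fpr and tpr must have equal length")
  if (any(diff(object@thresholds) > 0))
    msg <- c(msg, "thresholds must be non-increasing")
  for (nm in c("fpr", "tpr")) {
    v <- slot(object, nm)
    if (any(v < -1e-12) || any(v > 1 + 1e-12) || any(diff(v) < -1e-12))
      msg <- c(msg, sprintf("%s must be non-decreasing within [0, 1]", nm))
  }
  if (n > 0 && (object@fpr[1] != 0 || object@tpr[1] != 0 ||
                abs(object@fpr[n] - 1) > 1e-12 || abs(object@tpr[n] - 1) > 1e-12))
    msg <- c(msg, "curve must start at (0,0) and end at (1,1)")
  a <- trapz(object@fpr, object@tpr)
  if (abs(a - object@auc) > 1e-8)
    msg <- c(msg, "auc must equal the trapezoidal area of the curve")
  if (length(msg)) msg else TRUE
})
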