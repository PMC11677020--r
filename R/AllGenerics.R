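#' @rdname RamanExperiment-class
#' @param x a `RamanExperiment` or `EnfaceImageSet`.
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname RamanExperiment-class
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname EnfaceImageSet-class
#' @param x object.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname EnfaceImageSet-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname EnfaceImageSet-class
#' @export
setGeneric("fieldOfView", function(x) standardGeneric("fieldOfView"))

#' @rdname EnfaceImageSet-class
#' @export
setGeneric("recordInfo", function(x) standardGeneric("recordInfo"))

#' @rdname RocCurve-class
#' @param x a `RocCurve`.
#' @export
setGeneric("rocAuc", function(x) standardGeneric("rocAuc"))
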