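#' Preprocessing configuration for Raman batches
#'
#' Defaults follow the published processing chain: SVD rank 30, ALS with
#' lambda = 1e3, p = 1e-5 and 10 iterations, and Welch band selection at
#' alpha = 1e-10.
#'
#' @param svdRank number of singular components retained in denoising.
#' @param alsLambda,alsP,alsIterations ALS baseline parameters.
#' @param welchAlpha per-channel significance threshold for band selection.
#' @param spikeThreshold robust z-score threshold on first differences for
#'   cosmic-spike detection.
#' @param spikeMaxWidth maximal spike width in channels.
#' @param emscPolyOrder polynomial order of the EMSC model.
#' @param welchPerFold if `TRUE`, band selection is meant to be recomputed
#'   per cross-validation fold by the caller; the default (global selection
#'   on the full batch) mirrors the single-batch processing of the study
#'   design.
#' @return configuration list.
#' @export
preprocessConfig <- function(svdRank = 30L, alsLambda = 1e3, alsP = 1e-5,
                             alsIterations = 10L, welchAlpha = 1e-10,
                             spikeThreshold = 8, spikeMaxWidth = 3L,
                             emscPolyOrder = 2L, welchPerFold = FALSE) {
  stopifnot(svdRank >= 1L, alsP > 0, alsP < 1, welchAlpha > 0, welchAlpha < 1)
  list(svdRank = as.integer(svdRank), alsLambda = alsLambda, alsP = alsP,
       alsIterations = as.integer(alsIterations), welchAlpha = welchAlpha,
       spikeThreshold = spikeThreshold, spikeMaxWidth = as.integer(spikeMaxWidth),
       emscPolyOrder = as.integer(emscPolyOrder), welchPerFold = welchPerFold)
}

#' Remove cosmic spikes from a spectrum
#'
#' Spikes are sharp 1-3 channel positive excursions. Detection uses the
#' robust z-score (median/MAD) of the first differences: an up-jump above
#' the threshold followed within `spikeMaxWidth` channels by a matching
#' down-jump flags the enclosed channels, which are replaced by linear
#' interpolation between the nearest unflagged neighbours. All other
#' channels are returned bit-identical.
#'
#' @param intensities numeric vector.
#' @param config see [preprocessConfig()].
#' @return corrected vector with attribute `"flagged"` (indices repaired).
#' @export
removeCosmicSpikes <- function(intensities, config = preprocessConfig()) {
  stopifnotFinite(intensities, "intensities")
  n <- length(intensities)
  d <- diff(intensities)
  s <- mad(d)
  if (s == 0) s <- max(abs(d - median(d)), .Machine$double.eps)
  z <- (d - median(d)) / s
  flagged <- logical(n)
  up <- which(z > config$spikeThreshold)
  for (i in up) {
    # spike occupying channels (i+1) ... (i+j), closed by the last strong
    # down-jump within the admissible width
    jmax <- min(i + config$spikeMaxWidth, n - 1L)
    down <- which(z[(i + 1):jmax] < -config$spikeThreshold)
    if (length(down)) flagged[(i + 1):(i + max(down))] <- TRUE
  }
  if (!any(flagged)) return(structure(intensities, flagged = integer()))
  if (all(flagged)) stop("all channels flagged as spikes; degenerate input")
  idx <- which(!flagged)
  repaired <- intensities
  repaired[flagged] <- approx(idx, intensities[idx], xout = which(flagged),
                              rule = 2)$y
  structure(repaired, flagged = which(flagged))
}

#' Fit a wavenumber calibration polynomial
#'
#' Least-squares degree-5 polynomial mapping detector channel to wavenumber,
#' fitted on matched peak pairs from a reference material (classically
#' polystyrene).
#'
#' @param measuredChannels channel indices of detected reference peaks.
#' @param referenceWavenumbers their certified positions (cm^-1).
#' @param channelRange channel range over which monotonicity is enforced.
#' @return list with `coefficients` (degree 0..5), `residuals`, and
#'   `predict(channel)`.
#' @export
calibrateWavenumber <- function(measuredChannels, referenceWavenumbers,
                                channelRange = range(measuredChannels)) {
  if (length(measuredChannels) != length(referenceWavenumbers))
    stop("peak vectors must have equal length")
  if (length(measuredChannels) < 6L)
    stop("a degree-5 calibration needs at least 6 matched peak pairs")
  X <- outer(as.numeric(measuredChannels), 0:5, `^`)
  fit <- lm.fit(X, as.numeric(referenceWavenumbers))
  cf <- fit$coefficients
  predictFn <- function(channel) drop(outer(as.numeric(channel), 0:5, `^`) %*% cf)
  grid <- seq(channelRange[1], channelRange[2], length.out = 512)
  if (any(diff(predictFn(grid)) <= 0))
    stop("calibration polynomial is not monotone over the used channel range")
  list(coefficients = cf, residuals = fit$residuals, predict = predictFn)
}

#' Correct the instrument intensity response
#'
#' Channel-wise division by a calibrated response curve (in practice derived
#' from a NIST SRM-2241-style fluorescence standard; the synthetic generator
#' supplies its own curve).
#'
#' @param intensities spectrum (vector) or channels x records matrix.
#' @param response strictly positive response curve, one value per channel.
#' @return corrected spectrum or matrix.
#' @export
correctIntensityResponse <- function(intensities, response) {
  nCh <- if (is.matrix(intensities)) nrow(intensities) else length(intensities)
  if (length(response) != nCh)
    stop("response curve length must match the number of channels")
  if (any(!is.finite(response)) || any(response <= 0))
    stop("response curve must be strictly positive")
  intensities / response
}

#' SVD denoising of a spectra batch
#'
#' Best rank-`rank` least-squares approximation of the records x channels
#' matrix; `rank` is clamped to `min(rank, n, m)`.
#'
#' @param spectraMatrix records x channels matrix (n >= 2).
#' @param rank retained components (default 30).
#' @return denoised matrix of the same shape.
#' @export
svdDenoise <- function(spectraMatrix, rank = 30L) {
  if (!is.matrix(spectraMatrix) || nrow(spectraMatrix) < 2L)
    stop("a matrix with at least 2 spectra is required")
  k <- min(rank, nrow(spectraMatrix), ncol(spectraMatrix))
  s <- svd(spectraMatrix, nu = k, nv = k)
  s$u %*% (s$d[seq_len(k)] * t(s$v))
}

#' Asymmetric least squares baseline
#'
#' Estimates a smooth autofluorescence baseline under the Raman peaks by
#' minimizing `sum w_i (y_i - z_i)^2 + lambda * sum (d2 z)^2` with
#' asymmetric weights `w_i = p` where `y_i > z_i` and `1 - p` otherwise,
#' re-estimated for `iterations` rounds.
#'
#' @param intensities numeric vector.
#' @param lambda smoothness penalty (default 1e3).
#' @param p asymmetry (default 1e-5).
#' @param iterations weight re-estimation rounds (default 10).
#' @return list with `baseline` and `corrected` (= intensities - baseline).
#' @export
alsBaseline <- function(intensities, lambda = 1e3, p = 1e-5, iterations = 10L) {
  stopifnotFinite(intensities, "intensities")
  z <- cpp_als_baseline(as.numeric(intensities), lambda, p,
                        as.integer(iterations))
  list(baseline = z, corrected = intensities - z)
}

#' Extended multiplicative signal correction
#'
#' Models the spectrum as `b * reference + sum_k c_k * interferent_k +
#' polynomial` and returns the corrected spectrum
#' `(spectrum - interferents - polynomial) / b`. Used to strip known
#' constituents such as holder material and room light after baseline
#' removal. With an empty interferent library this reduces to multiplicative
#' scatter correction against the reference.
#'
#' @param intensities spectrum to correct.
#' @param reference reference spectrum on the same axis (typically the batch
#'   mean).
#' @param interferents optional channels x k matrix of interferent spectra.
#' @param polyOrder polynomial order of the smooth background term.
#' @param wavenumbers axis used to scale the polynomial basis.
#' @return list with `corrected` and `coefficients`
#'   (`b`, `c` per interferent, `poly` of length polyOrder + 1).
#' @export
emscCorrect <- function(intensities, reference, interferents = NULL,
                        polyOrder = 2L, wavenumbers = seq_along(intensities)) {
  n <- length(intensities)
  if (length(reference) != n) stop("reference must share the spectrum axis")
  if (!is.null(interferents)) {
    interferents <- as.matrix(interferents)
    if (nrow(interferents) != n)
      stop("interferent spectra must share the spectrum axis")
  }
  t <- 2 * (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers)) - 1
  P <- outer(t, 0:polyOrder, `^`)
  X <- cbind(reference, interferents, P)
  fit <- lm.fit(X, as.numeric(intensities))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  b <- cf[1]
  if (abs(b) < 1e-6) stop("reference scaling coefficient is ~0; EMSC not invertible")
  k <- if (is.null(interferents)) 0L else ncol(interferents)
  interfPart <- if (k > 0) drop(interferents %*% cf[2:(1 + k)]) else 0
  polyPart <- drop(P %*% cf[(2 + k):length(cf)])
  list(corrected = (intensities - interfPart - polyPart) / b,
       coefficients = list(b = unname(b),
                           c = if (k > 0) unname(cf[2:(1 + k)]) else numeric(),
                           poly = unname(cf[(2 + k):length(cf)])))
}

#' Area-normalize a spectrum
#'
#' Scales the spectrum so its trapezoidal integral over the wavenumber axis
#' equals 1.
#'
#' @param intensities numeric vector.
#' @param wavenumbers axis (cm^-1).
#' @return normalized vector.
#' @export
areaNormalize <- function(intensities, wavenumbers = seq_along(intensities)) {
  a <- trapz(wavenumbers, intensities)
  if (!is.finite(a) || abs(a) < 1e-12 * max(1, max(abs(intensities))))
    stop("zero-area spectrum cannot be normalized")
  intensities / a
}

#' Welch t-test band selection
#'
#' Per-channel unequal-variance t-statistic
#' `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with Welch-Satterthwaite
#' degrees of freedom and two-sided p-values. Channels with `p < alpha` form
#' the selection mask; maximal contiguous runs of selected channels are the
#' reported regions.
#'
#' @param healthySpectra,tumorSpectra records x channels matrices (>= 2
#'   records each).
#' @param wavenumbers channel axis (cm^-1).
#' @param alpha significance threshold (default 1e-10).
#' @return object of class `"BandSelection"`: list with `pvalues`, `mask`,
#'   `regions` (data.frame `start`, `end`, `startWavenumber`,
#'   `endWavenumber`), `alpha`, `wavenumbers`.
#' @export
welchBandSelect <- function(healthySpectra, tumorSpectra,
                            wavenumbers = seq_len(ncol(healthySpectra)),
                            alpha = 1e-10) {
  healthySpectra <- as.matrix(healthySpectra)
  tumorSpectra <- as.matrix(tumorSpectra)
  if (nrow(healthySpectra) < 2L || nrow(tumorSpectra) < 2L)
    stop("each class needs at least 2 spectra (variance undefined otherwise)")
  if (ncol(healthySpectra) != ncol(tumorSpectra))
    stop("spectra must share one channel grid")
  n1 <- nrow(healthySpectra); n2 <- nrow(tumorSpectra)
  m1 <- colMeans(healthySpectra); m2 <- colMeans(tumorSpectra)
  v1 <- apply(healthySpectra, 2, var); v2 <- apply(tumorSpectra, 2, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), ifelse(m1 == m2, 0, Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)), 1)
  p <- ifelse(is.finite(tstat), 2 * pt(abs(tstat), df, lower.tail = FALSE),
              0)
  p[tstat == 0] <- 1
  mask <- p < alpha
  regions <- maskToRegions(mask, wavenumbers)
  structure(list(pvalues = p, mask = mask, regions = regions,
                 alpha = alpha, wavenumbers = wavenumbers),
            class = "BandSelection")
}

maskToRegions <- function(mask, wavenumbers) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             startWavenumber = wavenumbers[starts[keep]],
             endWavenumber = wavenumbers[ends[keep]])
}

#' @export
print.BandSelection <- function(x, ...) {
  cat(sprintf("BandSelection: %d of %d channels in %d regions (alpha = %g)\n",
              sum(x$mask), length(x$mask), nrow(x$regions), x$alpha))
  invisible(x)
}

#' Preprocess a Raman batch
#'
#' Applies the fixed-order chain: cosmic-spike removal, wavenumber
#' calibration, intensity-response correction, batch SVD denoising, ALS
#' baseline removal, EMSC against the batch mean, area normalization, and
#' Welch band selection (healthy vs tumor labels, on the full batch). The
#' stage order is part of the contract and cannot be permuted.
#'
#' @param x a [RamanExperiment-class] of raw spectra.
#' @param config see [preprocessConfig()].
#' @param calibration optional [calibrateWavenumber()] model remapping the
#'   axis (channel index -> wavenumber); `NULL` keeps the recorded axis
#'   (synthetic data are generated on a calibrated axis).
#' @param response optional positive response curve; `NULL` skips the
#'   response stage.
#' @param interferents optional channels x k interferent matrix for EMSC.
#' @return list with `processed` (a [RamanExperiment-class], unit-area
#'   spectra) and `bands` (a `"BandSelection"`).
#' @export
preprocessBatch <- function(x, config = preprocessConfig(),
                            calibration = NULL, response = NULL,
                            interferents = NULL) {
  stopifnot(is(x, "RamanExperiment"))
  mat <- spectra(x) # channels x records
  wn <- wavenumbers(x)

  mat <- apply(mat, 2, removeCosmicSpikes, config = config)
  if (!is.null(calibration)) {
    wn <- calibration$predict(seq_len(nrow(mat)))
    if (any(diff(wn) <= 0)) stop("calibrated axis is not strictly increasing")
  }
  if (!is.null(response)) mat <- correctIntensityResponse(mat, response)
  mat <- t(svdDenoise(t(mat), rank = config$svdRank))
  for (j in seq_len(ncol(mat)))
    mat[, j] <- alsBaseline(mat[, j], config$alsLambda, config$alsP,
                            config$alsIterations)$corrected
  ref <- rowMeans(mat)
  for (j in seq_len(ncol(mat)))
    mat[, j] <- emscCorrect(mat[, j], ref, interferents,
                            config$emscPolyOrder, wn)$corrected
  for (j in seq_len(ncol(mat)))
    mat[, j] <- areaNormalize(mat[, j], wn)

  lab <- colData(x)$label
  bands <- welchBandSelect(t(mat[, lab == "healthy", drop = FALSE]),
                           t(mat[, lab == "tumor", drop = FALSE]),
                           wavenumbers = wn, alpha = config$welchAlpha)
  processed <- RamanExperiment(mat, wn, colData(x))
  list(processed = processed, bands = bands)
}
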