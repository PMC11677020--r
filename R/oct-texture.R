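#' Texture extraction configuration
#'
#' Defaults follow the descriptor settings used for the enface analysis:
#' a Gabor bank at spatial frequency magnitude 0.4 (cycles/pixel) with 4
#' one-octave bands, 30-degree angular bandwidth and orientations 0, 33, 66,
#' 99, 132, 165 degrees; multi-scale LBP at radii 1/2/3 with 8/16/24
#' neighbours; LPQ with a 7-pixel window; and GLCMs at distance 5 for angles
#' 0/90/180/270 degrees on 256 gray levels with properties contrast,
#' dissimilarity, homogeneity, energy, correlation and angular second
#' moment.
#'
#' @param gaborFrequency highest band centre frequency (cycles/pixel).
#' @param gaborBands number of one-octave-spaced radial bands.
#' @param gaborOrientations filter orientations in degrees (wave-vector
#'   angle).
#' @param gaborBandwidthDeg full angular bandwidth in degrees (half-response
#'   half-width = bandwidth/2).
#' @param lbpRadii,lbpNeighbors paired LBP scales.
#' @param lpqWindow LPQ window side in pixels.
#' @param glcmDistance,glcmAngles,glcmLevels GLCM offset length (pixels),
#'   angles (degrees) and quantization levels.
#' @return configuration list.
#' @export
textureConfig <- function(gaborFrequency = 0.4, gaborBands = 4L,
                          gaborOrientations = c(0, 33, 66, 99, 132, 165),
                          gaborBandwidthDeg = 30,
                          lbpRadii = c(1, 2, 3), lbpNeighbors = c(8L, 16L, 24L),
                          lpqWindow = 7L,
                          glcmDistance = 5L,
                          glcmAngles = c(0, 90, 180, 270),
                          glcmLevels = 256L) {
  stopifnot(length(lbpRadii) == length(lbpNeighbors), lpqWindow >= 3,
            glcmDistance >= 1, glcmLevels >= 2)
  list(gaborFrequency = gaborFrequency, gaborBands = as.integer(gaborBands),
       gaborOrientations = gaborOrientations,
       gaborBandwidthDeg = gaborBandwidthDeg,
       lbpRadii = lbpRadii, lbpNeighbors = as.integer(lbpNeighbors),
       lpqWindow = as.integer(lpqWindow),
       glcmDistance = as.integer(glcmDistance), glcmAngles = glcmAngles,
       glcmLevels = as.integer(glcmLevels))
}

checkImage <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix")
  if (!cpp_all_finite(image)) stop("image must be finite")
  image
}

#' Gabor filter-bank features
#'
#' Mean and standard deviation of the complex response magnitude for each
#' filter of a polar frequency-domain Gabor bank: radial Gaussians centred
#' at `f0 / 2^(b-1)` for band `b` with sd `0.352 * f0` (half-response width
#' of one octave), angular Gaussians with half-response half-width equal to
#' half the angular bandwidth, one-sided (analytic) with the DC bin zeroed,
#' so features are invariant to intensity offsets. Filtering is periodic
#' (FFT-based).
#'
#' @param image 2-D numeric matrix.
#' @param config see [textureConfig()].
#' @return object of class `"TextureFeatureBlock"`: list with `method`,
#'   `vector`, `names`.
#' @export
gaborFeatures <- function(image, config = textureConfig()) {
  checkImage(image)
  freqs <- config$gaborFrequency / 2^(seq_len(config$gaborBands) - 1)
  if (min(dim(image)) < ceiling(1 / min(freqs)))
    stop("image smaller than the largest Gabor filter support")
  # half-response half-widths -> Gaussian sds
  radialSigmaFactor <- (sqrt(2) - 1) / sqrt(2 * log(2))
  angularSigma <- (config$gaborBandwidthDeg / 2) * pi / 180 / sqrt(2 * log(2))
  st <- cpp_gabor_stats(image, freqs, config$gaborOrientations,
                        radialSigmaFactor, angularSigma)
  nm <- as.vector(outer(config$gaborOrientations, freqs,
                        function(th, f) sprintf("f%.3g_th%g", f, th)))
  vec <- as.vector(rbind(st[1, ], st[2, ]))
  names(vec) <- as.vector(rbind(paste0("gabor_mean_", nm),
                                paste0("gabor_sd_", nm)))
  structure(list(method = "gabor", vector = vec, names = names(vec)),
            class = "TextureFeatureBlock")
}

#' Multi-scale local binary pattern features
#'
#' For each (radius, P) scale: the normalized rotation-invariant uniform
#' pattern histogram (P + 2 bins) plus the mean and sd of the local
#' neighbour variance, concatenated over scales.
#'
#' @inheritParams gaborFeatures
#' @return `"TextureFeatureBlock"`.
#' @export
lbpFeatures <- function(image, config = textureConfig()) {
  checkImage(image)
  out <- numeric(); nm <- character()
  for (s in seq_along(config$lbpRadii)) {
    R <- config$lbpRadii[s]; P <- config$lbpNeighbors[s]
    if (min(dim(image)) < 2 * ceiling(R) + 1)
      stop("image smaller than the LBP neighbourhood")
    r <- cpp_lbp(image, P, R)
    out <- c(out, r$hist, r$varMean, r$varSd)
    nm <- c(nm, sprintf("lbp_r%g_p%d_bin%d", R, P, seq_len(P + 2) - 1L),
            sprintf("lbp_r%g_p%d_varmean", R, P),
            sprintf("lbp_r%g_p%d_varsd", R, P))
  }
  names(out) <- nm
  structure(list(method = "lbp", vector = out, names = nm),
            class = "TextureFeatureBlock")
}

#' Local phase quantization features
#'
#' 256-bin normalized histogram of 8-bit codes built from the signs of the
#' real and imaginary parts of four low-frequency short-term Fourier
#' coefficients computed in a square local window (blur-insensitive phase
#' information).
#'
#' @inheritParams gaborFeatures
#' @return `"TextureFeatureBlock"`.
#' @export
lpqFeatures <- function(image, config = textureConfig()) {
  checkImage(image)
  if (min(dim(image)) < config$lpqWindow)
    stop("image side smaller than the LPQ window")
  h <- cpp_lpq(image, config$lpqWindow)
  names(h) <- sprintf("lpq_code%03d", 0:255)
  structure(list(method = "lpq", vector = h, names = names(h)),
            class = "TextureFeatureBlock")
}

glcmProps <- function(P) {
  i <- row(P) - 1; j <- col(P) - 1
  asm <- sum(P^2)
  mi <- sum(i * P); mj <- sum(j * P)
  si <- sqrt(sum((i - mi)^2 * P)); sj <- sqrt(sum((j - mj)^2 * P))
  corr <- if (si > 0 && sj > 0) sum((i - mi) * (j - mj) * P) / (si * sj) else 1
  c(contrast = sum(P * (i - j)^2),
    dissimilarity = sum(P * abs(i - j)),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sqrt(asm),
    correlation = corr,
    asm = asm)
}

#' Gray-level co-occurrence matrix features
#'
#' The image is linearly rescaled to `glcmLevels` gray levels; one
#' normalized (asymmetric) co-occurrence matrix is tallied per angle at the
#' configured pixel distance, and six scalar properties are computed per
#' angle: contrast, dissimilarity, homogeneity, energy, correlation and
#' angular second moment.
#'
#' @inheritParams gaborFeatures
#' @param quantized set `TRUE` when `image` already holds integer levels in
#'   `0 .. glcmLevels - 1` (skips rescaling; used by toy oracles).
#' @return `"TextureFeatureBlock"`.
#' @export
glcmFeatures <- function(image, config = textureConfig(), quantized = FALSE) {
  checkImage(image)
  if (max(dim(image)) <= config$glcmDistance)
    stop("image too small for the co-occurrence distance")
  q <- if (quantized) matrix(as.integer(image), nrow(image))
       else cpp_quantize(image, config$glcmLevels)
  out <- numeric(); nm <- character()
  for (ang in config$glcmAngles) {
    # angle convention: 0 deg = offset to the next column (+x), angles grow
    # counter-clockwise with +y pointing up the image (towards lower rows)
    dr <- -round(config$glcmDistance * sin(ang * pi / 180))
    dc <- round(config$glcmDistance * cos(ang * pi / 180))
    M <- cpp_glcm(q, config$glcmLevels, dr, dc)
    tot <- sum(M)
    if (tot == 0) stop("empty co-occurrence tally; image too small")
    pr <- glcmProps(M / tot)
    out <- c(out, pr)
    nm <- c(nm, sprintf("glcm_a%g_%s", ang, names(pr)))
  }
  names(out) <- nm
  structure(list(method = "glcm", vector = out, names = nm),
            class = "TextureFeatureBlock")
}

#' @export
print.TextureFeatureBlock <- function(x, ...) {
  cat(sprintf("TextureFeatureBlock '%s' with %d features\n",
              x$method, length(x$vector)))
  invisible(x)
}

#' Extract all four texture blocks from one image
#'
#' Fixed block order: gabor, lbp, lpq, glcm. Extraction is deterministic.
#'
#' @inheritParams gaborFeatures
#' @return list of four `"TextureFeatureBlock"` objects.
#' @export
extractTextureBlocks <- function(image, config = textureConfig()) {
  list(gabor = gaborFeatures(image, config),
       lbp = lbpFeatures(image, config),
       lpq = lpqFeatures(image, config),
       glcm = glcmFeatures(image, config))
}

#' Texture feature matrix for an image set
#'
#' Runs [extractTextureBlocks()] over every image of an
#' [EnfaceImageSet-class] and returns a records x features matrix plus the
#' block column index, the layout consumed by [validateModality()] and
#' [runCombinedValidation()].
#'
#' @param imageSet an [EnfaceImageSet-class].
#' @param config see [textureConfig()].
#' @return list with `features` (matrix, rownames = record ids) and
#'   `blocks` (named list of column indices per block).
#' @export
octFeatureMatrix <- function(imageSet, config = textureConfig()) {
  stopifnot(is(imageSet, "EnfaceImageSet"))
  n <- length(imageSet)
  rows <- vector("list", n)
  lens <- NULL; nm <- NULL
  for (i in seq_len(n)) {
    bl <- extractTextureBlocks(images(imageSet)[[i]], config)
    rows[[i]] <- unlist(lapply(bl, `[[`, "vector"), use.names = FALSE)
    if (i == 1L) {
      lens <- vapply(bl, function(b) length(b$vector), integer(1))
      nm <- unlist(lapply(bl, function(b) b$names), use.names = FALSE)
    }
  }
  feat <- do.call(rbind, rows)
  colnames(feat) <- nm
  rownames(feat) <- recordInfo(imageSet)$record_id
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  blocks <- Map(function(s, e) s:e, starts, ends)
  names(blocks) <- names(lens)
  list(features = feat, blocks = blocks)
}
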