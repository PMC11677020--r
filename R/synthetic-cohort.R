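#' Create a synthetic cohort specification
#'
#' The defaults reproduce the scale of the clinical dataset the package
#' emulates: 27 subjects contributing 61 samples (21 healthy, 40 tumor) with
#' on average 303/61 Raman and 346/61 OCT records per sample, so default
#' totals land near 303 Raman records and 346 enface images. Tumor samples
#' are heterogeneous: each carries a tumor-purity fraction drawn uniformly
#' from `tumorPurityRange`, and each of its records is tumor-like with that
#' probability, so tumor samples may contain healthy-like records.
#'
#' @param nSubjects,nHealthySamples,nTumorSamples cohort dimensions.
#' @param meanRsRecordsPerSample,meanOctRecordsPerSample mean records per
#'   sample; per-sample counts are 1 + Poisson(mean - 1), so never zero.
#' @param tumorPurityRange ordered pair in \[0, 1\].
#' @param rsEffectSize,octEffectSize class-contrast magnitudes; 0 makes the
#'   two classes statistically identical in that modality.
#' @param seed integer seed for [generateCohort()].
#' @return A [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nSubjects = 4, nHealthySamples = 4, nTumorSamples = 4,
#'                    meanRsRecordsPerSample = 4.5, seed = 1)
#' spec
#' @export
cohortSpec <- function(nSubjects = 27L,
                       nHealthySamples = 21L,
                       nTumorSamples = 40L,
                       meanRsRecordsPerSample = 303 / 61,
                       meanOctRecordsPerSample = 346 / 61,
                       tumorPurityRange = c(0.1, 1),
                       rsEffectSize = 5,
                       octEffectSize = 1,
                       seed = 1L) {
  new("CohortSpec",
      nSubjects = as.integer(nSubjects),
      nHealthySamples = as.integer(nHealthySamples),
      nTumorSamples = as.integer(nTumorSamples),
      meanRsRecordsPerSample = meanRsRecordsPerSample,
      meanOctRecordsPerSample = meanOctRecordsPerSample,
      tumorPurityRange = as.numeric(tumorPurityRange),
      rsEffectSize = rsEffectSize,
      octEffectSize = octEffectSize,
      seed = as.integer(seed))
}

#' Raman band model of the synthetic generator
#'
#' Twelve vibrational bands at the positions commonly reported for colon
#' tissue (proline/hydroxyproline/tyrosine at 853, C-C proline stretch at
#' 935, lipid C-C at 1078, Amide III at 1265, CH2 twist at 1302, CH2/CH3
#' deformation at 1451, Amide I at 1661, and the high-wavenumber CH/OH
#' stretches at 2860-3210 cm^-1). `deltaDir` encodes the direction of the
#' tumor-vs-healthy amplitude shift (collagen/protein bands up, lipid bands
#' down); bands with `deltaDir = 0` carry no class contrast, which gives the
#' generator a known ground-truth set of discriminative bands.
#'
#' @return data.frame with columns `position` (cm^-1), `fwhm` (cm^-1),
#'   `ampHealthy` and `deltaDir`.
#' @export
defaultRamanBands <- function() {
  data.frame(
    position   = c(853, 935, 1078, 1265, 1302, 1451,
                   1661, 2860, 2890, 2935, 3010, 3210),
    fwhm       = c(18, 16, 20, 24, 16, 22, 26, 40, 30, 35, 20, 80),
    ampHealthy = c(0.8, 0.6, 0.9, 0.7, 1.0, 1.2, 1.5, 1.1, 0.9, 2.0, 0.5, 1.3),
    deltaDir   = c(0.9, 0.8, -0.7, 0.6, 0, 0.4, 0.8, -0.8, 0, -0.6, -0.5, 0)
  )
}

## pseudo-Voigt line shape, unit height
pseudoVoigt <- function(x, position, fwhm, eta = 0.3) {
  hw <- fwhm / 2
  g <- exp(-log(2) * ((x - position) / hw)^2)
  l <- 1 / (1 + ((x - position) / hw)^2)
  eta * l + (1 - eta) * g
}

#' Parameters of the synthetic Raman spectrum generator
#'
#' The raw spectrum model is
#' `(peaks + autofluorescence baseline + interferents) * response + noise`,
#' with heteroscedastic (shot-like) noise and occasional 1-3 channel cosmic
#' spikes of amplitude at least 20x the local noise sd. The wavenumber axis
#' has 1024 evenly spaced channels over 600-3300 cm^-1. Tumor-like and
#' healthy-like spectra differ only through band-amplitude shifts of size
#' `effectSize * deltaDir * noiseRef`.
#'
#' @param effectSize class amplitude shift in units of `noiseRef`.
#' @param nChannels,wavenumberRange axis definition.
#' @param bands band table, see [defaultRamanBands()].
#' @param noiseScale scale of the shot-noise model
#'   (`sd = noiseScale * sqrt(signal + 0.5)`).
#' @param noiseRef nominal per-channel noise sd defining the effect-size unit.
#' @param spikeProb per-record probability of a cosmic spike.
#' @param recordJitterSd,bandJitterSd,subjectJitterSd lognormal sds of the
#'   per-record, per-record-per-band and per-subject-per-band amplitude
#'   variability (biological and measurement variation).
#' @param eta pseudo-Voigt mixing fraction.
#' @return list of generator parameters with precomputed axis, band
#'   profiles, instrument response and interferent curves.
#' @export
ramanGenParams <- function(effectSize = 1,
                           nChannels = 1024L,
                           wavenumberRange = c(600, 3300),
                           bands = defaultRamanBands(),
                           noiseScale = 0.05,
                           noiseRef = 0.1,
                           spikeProb = 0.1,
                           recordJitterSd = 0.15,
                           bandJitterSd = 0.08,
                           subjectJitterSd = 0.05,
                           eta = 0.3) {
  wn <- seq(wavenumberRange[1], wavenumberRange[2], length.out = nChannels)
  if (any(diff(wn) <= 0)) stop("wavenumber axis must be strictly increasing")
  profiles <- sapply(seq_len(nrow(bands)), function(k)
    pseudoVoigt(wn, bands$position[k], bands$fwhm[k], eta))
  t <- (wn - wn[1]) / (wn[nChannels] - wn[1])
  list(
    effectSize = effectSize,
    wavenumbers = wn,
    t = t,
    bands = bands,
    profiles = profiles,
    response = 0.6 + 0.4 * exp(-((wn - 1800) / 900)^2 / 2),
    holder = 0.6 * exp(-((wn - 1100) / 250)^2 / 2) +
             0.4 * exp(-((wn - 2900) / 350)^2 / 2),
    roomLight = 0.5 * exp(-((wn - 2200) / 600)^2 / 2),
    noiseScale = noiseScale,
    noiseRef = noiseRef,
    spikeProb = spikeProb,
    recordJitterSd = recordJitterSd,
    bandJitterSd = bandJitterSd,
    subjectJitterSd = subjectJitterSd
  )
}

#' Generate one synthetic Raman record
#'
#' Draws from the global RNG stream (seed it with [withSeed()] or via
#' [generateCohort()]).
#'
#' @param latentClass `"healthy"` or `"tumor"`: the latent class of this
#'   record (a record of a heterogeneous tumor sample can be healthy-like).
#' @param params see [ramanGenParams()].
#' @param subjectFactor optional per-band multiplicative subject effect.
#' @param noise,baseline logical switches, mainly for tests.
#' @return list with `wavenumbers`, `intensities` and `truth` (amplitudes,
#'   baseline coefficients, spike channels).
#' @export
generateRamanSpectrum <- function(latentClass = c("healthy", "tumor"),
                                  params = ramanGenParams(),
                                  subjectFactor = NULL,
                                  noise = TRUE, baseline = TRUE) {
  latentClass <- match.arg(latentClass)
  bands <- params$bands
  amps <- bands$ampHealthy
  if (latentClass == "tumor")
    amps <- amps + params$effectSize * bands$deltaDir * params$noiseRef
  jit <- exp(rnorm(1, 0, params$recordJitterSd)) *
         exp(rnorm(nrow(bands), 0, params$bandJitterSd))
  if (!is.null(subjectFactor)) jit <- jit * subjectFactor
  amps <- amps * jit
  clean <- drop(params$profiles %*% amps)

  blCoef <- c(b0 = 0, b1 = 0, b2 = 0, bg = 0, holder = 0, room = 0)
  if (baseline) {
    blCoef <- c(b0 = runif(1, 2, 4), b1 = runif(1, -1, 1),
                b2 = runif(1, -0.5, 0.5), bg = runif(1, 1, 3),
                holder = runif(1, 0, 0.3), room = runif(1, 0, 0.3))
    bl <- blCoef["b0"] + blCoef["b1"] * params$t + blCoef["b2"] * params$t^2 +
      blCoef["bg"] * exp(-((params$wavenumbers - 1400) / 700)^2 / 2)
    clean <- clean + bl + blCoef["holder"] * params$holder +
      blCoef["room"] * params$roomLight
  }
  clean <- clean * params$response

  y <- clean
  spikeChannels <- integer()
  if (noise) {
    sdv <- params$noiseScale * sqrt(pmax(clean, 0) + 0.5)
    y <- clean + rnorm(length(clean)) * sdv
    if (runif(1) < params$spikeProb) {
      pos <- sample.int(length(y) - 3L, 1L)
      width <- sample.int(3L, 1L)
      spikeChannels <- pos:(pos + width - 1L)
      y[spikeChannels] <- y[spikeChannels] +
        (20 + rexp(1, 1 / 30)) * sdv[spikeChannels]
    }
  }
  list(wavenumbers = params$wavenumbers, intensities = y,
       truth = list(latent = latentClass, amps = amps, baseline = blCoef,
                    spikeChannels = spikeChannels))
}

#' Parameters of the synthetic enface image generator
#'
#' Healthy-like images are isotropic speckle (the amplitude of a complex
#' Gaussian random field with isotropic correlation). Tumor-like images add
#' a band-limited fibrous component: white noise smoothed strongly along one
#' spatial axis, giving oriented streaks that emulate the desmoplastic
#' collagen patterns of tumor stroma. The `orientation` of a fibrous texture
#' is quoted as the dominant angle of its 2-D spectral energy (the fiber
#' streaks themselves run perpendicular to it). Values are min-max scaled to
#' \[0, 1\].
#'
#' @param side image side in pixels (default 500 px = 2 mm at 4 um/px).
#' @param pixelSizeUm micrometres per pixel.
#' @param speckleSigma correlation length (px) of the speckle field.
#' @param fiberSigmaAlong,fiberSigmaAcross smoothing sds (px) along/across
#'   the fiber axis.
#' @param fiberWeight fibrous-component amplitude per unit effect size, in
#'   units of the mean speckle amplitude.
#' @param effectSize multiplies `fiberWeight`; 0 removes the class contrast.
#' @return parameter list.
#' @export
octGenParams <- function(side = 500L, pixelSizeUm = 4,
                         speckleSigma = 1.5,
                         fiberSigmaAlong = 18, fiberSigmaAcross = 1.5,
                         fiberWeight = 0.45, effectSize = 1,
                         speckleJitterSd = 0.1, fiberJitterSd = 0.3,
                         subjectJitterSd = 0.08) {
  if (side <= 0) stop("image side must be positive")
  list(side = as.integer(side), pixelSizeUm = pixelSizeUm,
       speckleSigma = speckleSigma,
       fiberSigmaAlong = fiberSigmaAlong,
       fiberSigmaAcross = fiberSigmaAcross,
       fiberWeight = fiberWeight, effectSize = effectSize,
       speckleJitterSd = speckleJitterSd, fiberJitterSd = fiberJitterSd,
       subjectJitterSd = subjectJitterSd)
}

#' Generate one synthetic OCT enface image
#'
#' Draws from the global RNG stream.
#'
#' @param latentClass `"healthy"` or `"tumor"`.
#' @param params see [octGenParams()].
#' @param orientation dominant spectral angle in degrees (tumor-like only);
#'   drawn uniformly from \[0, 180) when `NULL`.
#' @return list with `pixels` (side x side matrix in \[0, 1\]) and
#'   `orientation` (`NA` for healthy-like images).
#' @export
generateEnfaceImage <- function(latentClass = c("healthy", "tumor"),
                                params = octGenParams(),
                                orientation = NULL, subjectFactor = 1) {
  latentClass <- match.arg(latentClass)
  n <- params$side
  if (n <= 0) stop("image side must be positive")
  # per-image measurement variability: speckle grain and fiber prominence
  spkSigma <- params$speckleSigma * subjectFactor *
    exp(rnorm(1, 0, params$speckleJitterSd))
  z1 <- matrix(rnorm(n * n), n, n)
  z2 <- matrix(rnorm(n * n), n, n)
  theta <- NA_real_
  zf <- NULL
  weight <- 0
  sigAlong <- params$fiberSigmaAlong
  if (latentClass == "tumor") {
    theta <- if (is.null(orientation)) runif(1, 0, 180) else orientation
    weight <- params$effectSize * params$fiberWeight *
      exp(rnorm(1, 0, params$fiberJitterSd))
    sigAlong <- sigAlong * exp(rnorm(1, 0, params$fiberJitterSd / 2))
    # effectSize 0: tumor-like images come from the healthy distribution
    if (weight > 0) zf <- matrix(rnorm(n * n), n, n)
  }
  img <- cpp_enface_texture(z1, z2, spkSigma, zf,
                            sigAlong, params$fiberSigmaAcross,
                            if (is.na(theta)) 0 else theta + 90, # along fibers
                            weight)
  list(pixels = img, orientation = theta)
}

#' Generate a hierarchical synthetic cohort
#'
#' Builds subjects, samples and per-sample Raman/OCT records with the
#' hierarchy the validation assumes (records nested in samples nested in
#' subjects), deterministic for a fixed `spec@seed`. Healthy samples contain
#' only healthy-like records; each tumor sample draws a purity fraction and
#' its records are independently tumor-like with that probability.
#'
#' @param spec a [CohortSpec-class].
#' @param ramanParams,octParams generator parameter lists; their
#'   `effectSize` entries are overridden by the spec's effect sizes.
#' @param imageSide image side in pixels, forwarded to [octGenParams()].
#' @return list with elements `raman` ([RamanExperiment-class]), `oct`
#'   ([EnfaceImageSet-class]) and `truth` (generator ground truth: sample
#'   purities, record latent classes, band table, response and interferent
#'   curves, spike channels, fiber orientations).
#' @examples
#' cohort <- generateCohort(cohortSpec(nSubjects = 3, nHealthySamples = 3,
#'   nTumorSamples = 3, meanRsRecordsPerSample = 2,
#'   meanOctRecordsPerSample = 2, seed = 7), imageSide = 64)
#' cohort$raman
#' cohort$oct
#' @export
generateCohort <- function(spec = cohortSpec(),
                           ramanParams = NULL, octParams = NULL,
                           imageSide = 500L) {
  validObject(spec)
  if (spec@nHealthySamples < 1L || spec@nTumorSamples < 1L)
    stop("both classes need at least one sample")
  if (is.null(ramanParams)) ramanParams <- ramanGenParams()
  if (is.null(octParams)) octParams <- octGenParams(side = imageSide)
  ramanParams$effectSize <- spec@rsEffectSize
  octParams$effectSize <- spec@octEffectSize

  withSeed(spec@seed, {
    nSamp <- spec@nHealthySamples + spec@nTumorSamples
    subjects <- sprintf("S%02d", seq_len(spec@nSubjects))
    sampleSubject <- subjects[sample(rep_len(seq_len(spec@nSubjects), nSamp))]
    labels <- sample(c(rep("healthy", spec@nHealthySamples),
                       rep("tumor", spec@nTumorSamples)))
    sampleIds <- sprintf("SA%03d", seq_len(nSamp))
    purity <- ifelse(labels == "tumor",
                     runif(nSamp, spec@tumorPurityRange[1],
                           spec@tumorPurityRange[2]), 0)
    nRs <- 1L + rpois(nSamp, spec@meanRsRecordsPerSample - 1)
    nOct <- 1L + rpois(nSamp, spec@meanOctRecordsPerSample - 1)

    # per-subject, per-band multiplicative effects (shared by both classes)
    subjFac <- matrix(exp(rnorm(spec@nSubjects * nrow(ramanParams$bands),
                                0, ramanParams$subjectJitterSd)),
                      nrow = spec@nSubjects,
                      dimnames = list(subjects, NULL))

    drawLatent <- function(n, lab, pur)
      ifelse(lab == "tumor" & runif(n) < pur, "tumor", "healthy")

    ## Raman records
    rsMeta <- data.frame(sampleIdx = rep(seq_len(nSamp), nRs))
    rsMeta$record_id <- sprintf("RS%04d", seq_len(nrow(rsMeta)))
    rsMeta$sample_id <- sampleIds[rsMeta$sampleIdx]
    rsMeta$subject_id <- sampleSubject[rsMeta$sampleIdx]
    rsMeta$label <- labels[rsMeta$sampleIdx]
    rsMeta$latent <- drawLatent(nrow(rsMeta), rsMeta$label,
                                purity[rsMeta$sampleIdx])
    nCh <- length(ramanParams$wavenumbers)
    intens <- matrix(NA_real_, nCh, nrow(rsMeta))
    spikes <- vector("list", nrow(rsMeta))
    for (i in seq_len(nrow(rsMeta))) {
      rec <- generateRamanSpectrum(rsMeta$latent[i], ramanParams,
                                   subjectFactor = subjFac[rsMeta$subject_id[i], ])
      intens[, i] <- rec$intensities
      spikes[[i]] <- rec$truth$spikeChannels
    }

    ## OCT records
    octMeta <- data.frame(sampleIdx = rep(seq_len(nSamp), nOct))
    octMeta$record_id <- sprintf("OCT%04d", seq_len(nrow(octMeta)))
    octMeta$sample_id <- sampleIds[octMeta$sampleIdx]
    octMeta$subject_id <- sampleSubject[octMeta$sampleIdx]
    octMeta$label <- labels[octMeta$sampleIdx]
    octMeta$latent <- drawLatent(nrow(octMeta), octMeta$label,
                                 purity[octMeta$sampleIdx])
    octSubjFac <- setNames(exp(rnorm(spec@nSubjects, 0,
                                     octParams$subjectJitterSd)), subjects)
    imgs <- vector("list", nrow(octMeta))
    orient <- rep(NA_real_, nrow(octMeta))
    for (i in seq_len(nrow(octMeta))) {
      im <- generateEnfaceImage(octMeta$latent[i], octParams,
                                subjectFactor = octSubjFac[[octMeta$subject_id[i]]])
      imgs[[i]] <- im$pixels
      orient[i] <- im$orientation
    }
    octMeta$orientation <- orient

    raman <- RamanExperiment(
      intensities = intens,
      wavenumbers = ramanParams$wavenumbers,
      recordInfo = DataFrame(rsMeta[c("record_id", "subject_id",
                                      "sample_id", "label")]))
    oct <- EnfaceImageSet(
      images = imgs,
      recordInfo = DataFrame(octMeta[c("record_id", "subject_id",
                                       "sample_id", "label")]),
      pixelSize = octParams$pixelSizeUm,
      fieldOfView = octParams$side * octParams$pixelSizeUm / 1000)

    truth <- list(
      samples = data.frame(sample_id = sampleIds, subject_id = sampleSubject,
                           label = labels, purity = purity,
                           nRs = nRs, nOct = nOct),
      rsRecords = rsMeta[c("record_id", "sample_id", "subject_id",
                           "label", "latent")],
      octRecords = octMeta[c("record_id", "sample_id", "subject_id",
                             "label", "latent", "orientation")],
      bands = ramanParams$bands,
      shiftedBands = ramanParams$bands$position[ramanParams$bands$deltaDir != 0],
      response = ramanParams$response,
      interferents = cbind(holder = ramanParams$holder,
                           roomLight = ramanParams$roomLight),
      rsSpikes = spikes,
      ramanParams = ramanParams,
      octParams = octParams)
    list(raman = raman, oct = oct, truth = truth)
  })
}

#' Construct a RamanExperiment
#'
#' @param intensities numeric matrix, channels x records.
#' @param wavenumbers strictly increasing axis (cm^-1), one per row.
#' @param recordInfo [S4Vectors::DataFrame] (or data.frame) with columns
#'   `record_id`, `subject_id`, `sample_id`, `label`.
#' @return A [RamanExperiment-class].
#' @export
RamanExperiment <- function(intensities, wavenumbers, recordInfo) {
  recordInfo <- DataFrame(recordInfo)
  se <- SummarizedExperiment(
    assays = list(intensities = intensities),
    rowData = DataFrame(wavenumber = wavenumbers),
    colData = recordInfo)
  colnames(se) <- recordInfo$record_id
  new("RamanExperiment", se)
}

#' Construct an EnfaceImageSet
#'
#' @param images list of square numeric matrices.
#' @param recordInfo metadata with `record_id`, `subject_id`, `sample_id`,
#'   `label`.
#' @param pixelSize micrometres per pixel.
#' @param fieldOfView millimetres.
#' @return An [EnfaceImageSet-class].
#' @export
EnfaceImageSet <- function(images, recordInfo, pixelSize = 4,
                           fieldOfView = NULL) {
  recordInfo <- DataFrame(recordInfo)
  if (is.null(fieldOfView) && length(images))
    fieldOfView <- nrow(images[[1]]) * pixelSize / 1000
  new("EnfaceImageSet", images = images, recordInfo = recordInfo,
      pixelSize = pixelSize, fieldOfView = fieldOfView)
}
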