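test_that("cohort spec validates its invariants", {
  expect_s4_class(cohortSpec(), "CohortSpec")
  expect_error(cohortSpec(nHealthySamples = 0), "both classes")
  expect_error(cohortSpec(tumorPurityRange = c(0.8, 0.2)), "ordered pair")
  expect_error(cohortSpec(rsEffectSize = -1), "non-negative")
})

test_that("generated hierarchy matches the requested shape", {
  co <- generateCohort(cohortSpec(nSubjects = 4, nHealthySamples = 4,
                                  nTumorSamples = 4,
                                  meanRsRecordsPerSample = 4.5,
                                  meanOctRecordsPerSample = 4.5, seed = 5),
                       imageSide = 32)
  tr <- co$truth
  expect_equal(length(unique(tr$samples$subject_id)), 4L)
  expect_equal(nrow(tr$samples), 8L)
  expect_equal(sum(tr$samples$label == "healthy"), 4L)
  # every sample belongs to exactly one subject
  expect_equal(anyDuplicated(tr$samples$sample_id), 0L)
  m <- as.data.frame(recordInfo(co$raman))
  expect_true(all(table(m$sample_id) >= 1))
  link <- unique(m[c("sample_id", "subject_id")])
  expect_equal(anyDuplicated(link$sample_id), 0L)
  # Poisson totals around 8 * 4.5 = 36 records per modality
  expect_gt(ncol(spectra(co$raman)), 36 * 0.6)
  expect_lt(ncol(spectra(co$raman)), 36 * 1.5)
})

test_that("generation is deterministic for a fixed seed and varies across seeds", {
  a <- generateCohort(smallSpec(seed = 3), imageSide = 32)
  b <- generateCohort(smallSpec(seed = 3), imageSide = 32)
  d <- generateCohort(smallSpec(seed = 4), imageSide = 32)
  expect_identical(spectra(a$raman), spectra(b$raman))
  expect_identical(images(a$oct), images(b$oct))
  expect_identical(a$truth$samples, b$truth$samples)
  expect_false(identical(spectra(a$raman), spectra(d$raman)))
  expect_false(identical(images(a$oct)[[1]], images(d$oct)[[1]]))
})

test_that("default cohort reproduces the study scale", {
  co <- withSeed(11, {
    spec <- cohortSpec(seed = 20)
    nSamp <- spec@nHealthySamples + spec@nTumorSamples
    expect_equal(nSamp, 61L)
    expect_equal(spec@nSubjects, 27L)
    generateCohort(spec, imageSide = 32)
  })
  expect_equal(nrow(co$truth$samples), 61L)
  expect_equal(sum(co$truth$samples$label == "healthy"), 21L)
  expect_equal(sum(co$truth$samples$label == "tumor"), 40L)
  # totals within +/- 15% of the specified means
  expect_lt(abs(ncol(spectra(co$raman)) - 303) / 303, 0.15)
  expect_lt(abs(length(co$oct) - 346) / 346, 0.15)
})

test_that("healthy samples never contain tumor-like records", {
  for (seed in 1:3) {
    co <- smallCohort(seed = seed, imageSide = 32)
    tr <- co$truth
    healthy <- tr$samples$sample_id[tr$samples$label == "healthy"]
    expect_true(all(tr$rsRecords$latent[tr$rsRecords$sample_id %in% healthy] ==
                      "healthy"))
    expect_true(all(tr$octRecords$latent[tr$octRecords$sample_id %in% healthy] ==
                      "healthy"))
    expect_true(all(tr$samples$purity[tr$samples$label == "healthy"] == 0))
    expect_true(all(tr$samples$purity[tr$samples$label == "tumor"] > 0))
  }
})

test_that("noiseless single-peak spectrum is a symmetric peak at the band", {
  wn <- seq(600, 3300, length.out = 1024)
  pos <- wn[228] # on-grid centre so symmetry is exact channel-wise
  bands <- data.frame(position = pos, fwhm = 20, ampHealthy = 1, deltaDir = 0)
  p <- ramanGenParams(bands = bands)
  p$response <- rep(1, length(p$wavenumbers))
  rec <- withSeed(1, generateRamanSpectrum("healthy", p, noise = FALSE,
                                           baseline = FALSE))
  i <- which.max(rec$intensities)
  expect_lt(abs(rec$wavenumbers[i] - pos), 2)
  # symmetry around the peak
  lhs <- rec$intensities[i - (1:20)]
  rhs <- rec$intensities[i + (1:20)]
  expect_lt(max(abs(lhs - rhs)) / max(rec$intensities), 0.02)
})

test_that("noiseless class means differ exactly at the shifted bands", {
  p <- ramanGenParams(effectSize = 5, recordJitterSd = 0, bandJitterSd = 0)
  p$response <- rep(1, length(p$wavenumbers))
  h <- withSeed(1, generateRamanSpectrum("healthy", p, noise = FALSE,
                                         baseline = FALSE))$intensities
  t <- withSeed(1, generateRamanSpectrum("tumor", p, noise = FALSE,
                                         baseline = FALSE))$intensities
  d <- t - h
  # oracle: direct subtraction of the generator band models
  shifted <- p$bands$deltaDir != 0
  expected <- drop(p$profiles %*% (5 * p$bands$deltaDir * p$noiseRef))
  expect_equal(d, expected, tolerance = 1e-12)
  wn <- p$wavenumbers
  nearShifted <- rowSums(sapply(p$bands$position[shifted],
                                function(b) abs(wn - b) < 5)) > 0
  farFromShifted <- rowSums(sapply(p$bands$position[shifted],
                                   function(b) abs(wn - b) < 150)) == 0
  expect_gt(max(abs(d[nearShifted])), 0)
  # away from the shifted bands only line-shape tails remain
  expect_lt(max(abs(d[farFromShifted])), 0.05 * max(abs(d[nearShifted])))
})

test_that("zero RS effect gives exchangeable classes", {
  p <- ramanGenParams(effectSize = 0)
  set.seed(42)
  h <- replicate(150, sum(generateRamanSpectrum("healthy", p)$intensities))
  t <- replicate(150, sum(generateRamanSpectrum("tumor", p)$intensities))
  expect_gt(t.test(h, t)$p.value, 0.01)
})

test_that("enface images have the documented geometry and range", {
  im <- withSeed(2, generateEnfaceImage("healthy", octGenParams(side = 100)))
  expect_equal(dim(im$pixels), c(100L, 100L))
  expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  expect_true(is.na(im$orientation))
  # default geometry: 500 px at 4 um/px covers 2 mm
  p <- octGenParams()
  expect_equal(p$side * p$pixelSizeUm / 1000, 2)
  expect_error(octGenParams(side = 0), "positive")
})

test_that("tumor fiber orientation dominates the image spectrum", {
  # oracle: 2-D Fourier energy by angle
  for (theta in c(33, 120)) {
    im <- withSeed(7, generateEnfaceImage(
      "tumor", octGenParams(side = 200, effectSize = 3, fiberJitterSd = 0),
      orientation = theta))
    e <- ProbeFusion:::cpp_angular_energy(im$pixels - mean(im$pixels), 36L)
    peak <- (which.max(e) - 1) * 5 + 2.5
    delta <- abs(peak - theta)
    expect_lt(min(delta, 180 - delta), 10)
  }
})

test_that("zero OCT effect makes tumor-like images healthy-like", {
  p <- octGenParams(side = 64, effectSize = 0)
  set.seed(8)
  h <- replicate(80, sd(generateEnfaceImage("healthy", p)$pixels))
  t <- replicate(80, sd(generateEnfaceImage("tumor", p)$pixels))
  expect_gt(t.test(h, t)$p.value, 0.01)
})

test_that("validated AUC is monotone in the effect size (majority over seeds)", {
  ## 3 effect levels x 5 seeds per modality, small cohorts for speed
  levs <- c(0, 2.5, 8)
  seeds <- 1:5
  rsAuc <- matrix(NA_real_, length(seeds), length(levs))
  octAuc <- matrix(NA_real_, length(seeds), length(levs))
  for (si in seq_along(seeds)) {
    for (li in seq_along(levs)) {
      co <- generateCohort(
        cohortSpec(nSubjects = 8, nHealthySamples = 8, nTumorSamples = 8,
                   meanRsRecordsPerSample = 4, meanOctRecordsPerSample = 3,
                   tumorPurityRange = c(0.6, 1),
                   rsEffectSize = levs[li], octEffectSize = levs[li] / 4,
                   seed = 100 * seeds[si] + li),
        imageSide = 64)
      pp <- preprocessBatch(co$raman, preprocessConfig(welchAlpha = 1e-4),
                            response = co$truth$response,
                            interferents = co$truth$interferents)
      sel <- if (any(pp$bands$mask)) pp$bands$mask else rep(TRUE, 1024)
      v <- suppressMessages(suppressWarnings(validateModality(
        t(spectra(pp$processed))[, sel, drop = FALSE],
        as.data.frame(recordInfo(pp$processed)))))
      rsAuc[si, li] <- rocAuc(v$roc)
      fx <- octFeatureMatrix(co$oct)
      v2 <- suppressMessages(suppressWarnings(validateModality(
        fx$features, as.data.frame(recordInfo(co$oct)), blocks = fx$blocks)))
      octAuc[si, li] <- rocAuc(v2$roc)
    }
  }
  rsMed <- apply(rsAuc, 2, median)
  octMed <- apply(octAuc, 2, median)
  expect_true(all(diff(rsMed) >= -0.02))
  expect_true(all(diff(octMed) >= -0.02))
  expect_gt(rsMed[3], rsMed[1])
  expect_gt(octMed[3], octMed[1])
})
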