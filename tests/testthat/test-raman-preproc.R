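test_that("spike removal repairs spikes and touches nothing else", {
  wn <- seq(600, 3300, length.out = 512)
  smooth <- 2 + sin(wn / 300) + exp(-((wn - 1500) / 120)^2)
  expect_identical(removeCosmicSpikes(smooth), structure(smooth, flagged = integer()))
  cst <- rep(3, 512)
  expect_identical(as.numeric(removeCosmicSpikes(cst)), cst)

  y <- smooth
  y[200] <- y[200] + 50 * sd(diff(smooth))
  rep1 <- removeCosmicSpikes(y)
  expect_equal(attr(rep1, "flagged"), 200L)
  # oracle: linear interpolation of the immediate neighbours
  expect_equal(rep1[200], (y[199] + y[201]) / 2, tolerance = 1e-12)
  expect_identical(rep1[-200], y[-200]) # bitwise elsewhere

  # 3-channel spike
  y2 <- smooth
  y2[300:302] <- y2[300:302] + c(40, 55, 45)
  rep2 <- removeCosmicSpikes(y2)
  expect_true(all(300:302 %in% attr(rep2, "flagged")))
  expect_lt(max(abs(rep2 - smooth)), 0.2)
  expect_error(removeCosmicSpikes(c(1, NA, 3)), "finite")
})

test_that("wavenumber calibration recovers a generating polynomial", {
  channels <- seq(10, 500, length.out = 12)
  # identity-like: linear axis
  lin <- 600 + 2.5 * channels
  fit <- calibrateWavenumber(channels, lin)
  expect_equal(unname(fit$coefficients[1:2]), c(600, 2.5), tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients[3:6])), 1e-8)

  genCoef <- c(580, 2.2, 1e-3, -4e-6, 6e-9, -3e-12)
  ref <- drop(outer(channels, 0:5, `^`) %*% genCoef)
  fit2 <- calibrateWavenumber(channels, ref)
  expect_equal(unname(fit2$coefficients), genCoef,
               tolerance = 1e-6) # relative oracle: generating coefficients
  expect_lt(max(abs(fit2$residuals)), 1e-8)
  expect_error(calibrateWavenumber(channels[1:5], lin[1:5]), "at least 6")
  # non-monotone mapping refused
  expect_error(calibrateWavenumber(seq_len(7), c(1, 5, 2, 8, 3, 9, 4)),
               "not monotone")
})

test_that("intensity response correction divides channel-wise", {
  true <- c(1, 2, 3, 4)
  resp <- c(0.5, 1, 2, 4)
  expect_equal(correctIntensityResponse(true * resp, resp), true)
  expect_identical(correctIntensityResponse(true, rep(1, 4)), true)
  expect_error(correctIntensityResponse(true, c(1, 0, 1, 1)), "positive")
  expect_error(correctIntensityResponse(true, rep(1, 3)), "length")
})

test_that("SVD denoising is the best low-rank approximation", {
  set.seed(1)
  # exact-rank case: rank <= 30 input is reproduced
  u <- matrix(rnorm(100 * 5), 100); v <- matrix(rnorm(5 * 64), 5)
  lowRank <- u %*% v
  expect_equal(svdDenoise(lowRank, 30), lowRank, tolerance = 1e-8)
  # rank-2 signal + noise: reconstruction at rank 2 is closer than the data
  sig <- matrix(rnorm(100 * 2), 100) %*% matrix(rnorm(2 * 64), 2)
  noisy <- sig + 0.1 * matrix(rnorm(100 * 64), 100)
  den <- svdDenoise(noisy, 2)
  expect_lt(norm(den - sig, "F"), norm(noisy - sig, "F"))
  # oracle: equals the truncated full decomposition
  s <- svd(noisy)
  recon <- s$u[, 1:2] %*% diag(s$d[1:2]) %*% t(s$v[, 1:2])
  expect_equal(den, recon, tolerance = 1e-10)
  # rank clamping
  expect_equal(svdDenoise(noisy[1:10, ], 30), noisy[1:10, ], tolerance = 1e-8)
  expect_error(svdDenoise(noisy[1, , drop = FALSE]), "at least 2")
})

test_that("ALS baseline recovers a smooth background under peaks", {
  expect_equal(alsBaseline(rep(0, 200))$baseline, rep(0, 200),
               tolerance = 1e-12)
  x <- seq(0, 1, length.out = 1024)
  gentle <- 3 + 2 * x + 1.5 * exp(-((x - 0.4) / 0.8)^2)
  fitS <- alsBaseline(gentle)
  expect_lt(max(abs(fitS$corrected)), 0.01 * diff(range(gentle)))

  smooth <- 3 + 2 * x + 1.5 * exp(-((x - 0.4) / 0.35)^2)
  peaks <-2 * exp(-((x - 0.25) / 0.008)^2) + 3 * exp(-((x - 0.6) / 0.01)^2) +
    1.5 * exp(-((x - 0.8) / 0.006)^2)
  fit <- alsBaseline(smooth + peaks)
  offPeak <- peaks < 1e-3
  rmsErr <- sqrt(mean((fit$baseline - smooth)[offPeak]^2))
  expect_lt(rmsErr / sqrt(mean(smooth^2)), 0.05)
  # smoothness: second-difference energy no larger than the input's
  d2 <- function(v) sum(diff(diff(v))^2)
  expect_lte(d2(fit$baseline), d2(smooth + peaks))
  expect_error(alsBaseline(c(1, Inf, 3)), "finite")
})

test_that("EMSC recovers known mixing coefficients", {
  wn <- seq(600, 3300, length.out = 800)
  ref <- exp(-((wn - 1450) / 40)^2) + 0.8 * exp(-((wn - 2930) / 50)^2)
  intf <- exp(-((wn - 1100) / 150)^2)

  idFit <- emscCorrect(ref, ref, polyOrder = 2, wavenumbers = wn)
  expect_equal(idFit$coefficients$b, 1, tolerance = 1e-10)
  expect_lt(max(abs(idFit$coefficients$poly)), 1e-10)
  expect_equal(idFit$corrected, ref, tolerance = 1e-8)

  y <- 2 * ref + 0.5 * intf + 3
  fit <- emscCorrect(y, ref, cbind(intf), polyOrder = 2, wavenumbers = wn)
  expect_equal(fit$coefficients$b, 2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$c), 0.5, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients$poly[1]), 3, tolerance = 1e-6)
  expect_equal(fit$corrected, ref, tolerance = 1e-6)

  # degenerate library reduces to multiplicative scatter correction
  msc <- emscCorrect(3 * ref + 1, ref, NULL, polyOrder = 0, wavenumbers = wn)
  expect_equal(msc$coefficients$b, 3, tolerance = 1e-8)
  expect_equal(msc$corrected, ref, tolerance = 1e-8)
  expect_error(emscCorrect(intf, ref * 1e9, NULL, 0, wn), "not invertible")
})

test_that("area normalization yields unit trapezoidal integral", {
  wn <- seq(600, 3300, length.out = 256)
  y <- 1 + exp(-((wn - 1600) / 100)^2)
  n1 <- areaNormalize(y, wn)
  tz <- function(x, f) sum((f[-1] + f[-length(f)]) * diff(x)) / 2
  expect_equal(tz(wn, n1), 1, tolerance = 1e-10)
  # scale invariance
  expect_equal(areaNormalize(7.3 * y, wn), n1, tolerance = 1e-12)
  # closed form: constant 1 over axis of length L -> 1/L
  expect_equal(areaNormalize(rep(1, 256), wn), rep(1 / 2700, 256),
               tolerance = 1e-12)
  expect_error(areaNormalize(rep(0, 256), wn), "zero-area")
})

test_that("Welch band selection matches the textbook statistic", {
  set.seed(2)
  n <- 50; p <- 40
  h <- matrix(rnorm(n * p), n)
  t <- matrix(rnorm(n * p), n)
  t[, 7] <- t[, 7] + 5 # 5-pooled-sd shift in one channel
  sel <- welchBandSelect(h, t, alpha = 1e-10)
  expect_true(sel$mask[7])
  expect_equal(which(sel$mask), 7L)
  expect_equal(nrow(sel$regions), 1L)
  # oracle: stats::t.test per channel
  for (ch in c(1, 7, 20)) {
    ref <- t.test(h[, ch], t[, ch], var.equal = FALSE)$p.value
    expect_equal(sel$pvalues[ch], ref, tolerance = 1e-12)
  }
  # identical groups: p = 1 everywhere, empty selection
  same <- welchBandSelect(h, h, alpha = 0.05)
  expect_true(all(same$pvalues == 1))
  expect_false(any(same$mask))
  expect_equal(nrow(same$regions), 0L)
  expect_error(welchBandSelect(h[1, , drop = FALSE], t), "at least 2")
  # monotone in alpha
  sLoose <- welchBandSelect(h, t, alpha = 0.1)
  expect_true(all(sel$mask <= sLoose$mask))
  expect_true(all(sel$pvalues >= 0 & sel$pvalues <= 1))
})

test_that("selected regions are maximal contiguous runs", {
  mask <- c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE)
  wn <- 100 + seq_len(10)
  reg <- ProbeFusion:::maskToRegions(mask, wn)
  expect_equal(reg$start, c(2L, 5L, 8L))
  expect_equal(reg$end, c(3L, 5L, 10L))
  expect_equal(reg$startWavenumber, c(102, 105, 108))
})

test_that("batch preprocessing is deterministic, unit-area and label-blind in order", {
  co <- smallCohort(seed = 6, imageSide = 32)
  pp1 <- preprocessBatch(co$raman, response = co$truth$response,
                         interferents = co$truth$interferents)
  pp2 <- preprocessBatch(co$raman, response = co$truth$response,
                         interferents = co$truth$interferents)
  expect_identical(spectra(pp1$processed), spectra(pp2$processed))
  wn <- wavenumbers(pp1$processed)
  areas <- apply(spectra(pp1$processed), 2, function(y)
    sum((y[-1] + y[-length(y)]) * diff(wn)) / 2)
  expect_equal(areas, setNames(rep(1, length(areas)), names(areas)),
               tolerance = 1e-10)
  expect_identical(colnames(pp1$processed), recordInfo(co$raman)$record_id)
})

test_that("selection on an effectful cohort intersects the true shifted bands", {
  co <- generateCohort(cohortSpec(nSubjects = 8, nHealthySamples = 8,
                                  nTumorSamples = 8,
                                  meanRsRecordsPerSample = 5,
                                  meanOctRecordsPerSample = 1,
                                  tumorPurityRange = c(0.7, 1),
                                  rsEffectSize = 8, seed = 13),
                      imageSide = 32)
  pp <- preprocessBatch(co$raman, preprocessConfig(welchAlpha = 1e-6),
                        response = co$truth$response,
                        interferents = co$truth$interferents)
  expect_gt(sum(pp$bands$mask), 0)
  selWn <- wavenumbers(pp$processed)[pp$bands$mask]
  hits <- vapply(co$truth$shiftedBands,
                 function(b) any(abs(selWn - b) < 30), logical(1))
  expect_gt(mean(hits), 0.5)
})
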