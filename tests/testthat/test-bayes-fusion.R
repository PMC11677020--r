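test_that("single-test posterior updates follow the predictive-value formulas", {
  # hand arithmetic: 0.87 * 0.5 / (0.87 * 0.5 + 0.33 * 0.5) = 0.435 / 0.6
  expect_equal(updatePosterior(0.5, 0.87, 0.33, "positive"), 0.725,
               tolerance = 1e-12)
  # uninformative test leaves any prior unchanged
  for (pr in c(0, 0.2, 0.5, 0.9, 1)) {
    expect_equal(updatePosterior(pr, 0.4, 0.4, "positive"), pr,
                 tolerance = 1e-12)
    expect_equal(updatePosterior(pr, 0.4, 0.4, "negative"), pr,
                 tolerance = 1e-12)
  }
  # absorbing priors
  expect_equal(updatePosterior(0, 0.9, 0.1, "positive"), 0)
  expect_equal(updatePosterior(1, 0.9, 0.1, "negative"), 1)
  expect_error(updatePosterior(0.5, 1, 0.1, "positive"), "inside")
  expect_error(updatePosterior(1.2, 0.9, 0.1, "positive"), "prior")
  # monotone in prior; monotone in positives when tpr > fpr
  p1 <- updatePosterior(0.3, 0.8, 0.2, "positive")
  p2 <- updatePosterior(0.4, 0.8, 0.2, "positive")
  expect_gt(p2, p1)
  expect_gt(updatePosterior(0.5, 0.8, 0.2, "positive"), 0.5)
  expect_lt(updatePosterior(0.5, 0.8, 0.2, "negative"), 0.5)
})

test_that("sequential fusion equals the closed-form odds product", {
  expect_equal(fuseSample(NULL, prior = 0.5)$posterior, 0.5)
  expect_equal(fuseSample(data.frame(), prior = 0.31)$posterior, 0.31)

  oddsOracle <- function(prior, tpr, fpr, nPos, nNeg) {
    odds <- prior / (1 - prior) * (tpr / fpr)^nPos *
      ((1 - tpr) / (1 - fpr))^nNeg
    odds / (1 + odds)
  }
  set.seed(12)
  for (r in 1:50) {
    tpr <- runif(1, 0.05, 0.95); fpr <- runif(1, 0.05, 0.95)
    nPos <- sample(0:6, 1); nNeg <- sample(0:6, 1)
    decs <- sample(c(rep("positive", nPos), rep("negative", nNeg)))
    dec <- data.frame(modality = rep("RS", nPos + nNeg), decision = decs,
                      tpr = rep(tpr, nPos + nNeg), fpr = rep(fpr, nPos + nNeg))
    got <- fuseSample(dec, prior = 0.5)
    expect_equal(got$posterior, oddsOracle(0.5, tpr, fpr, nPos, nNeg),
                 tolerance = 1e-12)
    if (nrow(dec)) {
      expect_equal(nrow(got$updateLog), nrow(dec))
      expect_equal(got$updateLog$posterior[nrow(dec)], got$posterior)
    }
  }
})

test_that("fusion is invariant to the decision order", {
  set.seed(13)
  dec <- data.frame(
    modality = sample(c("RS", "OCT"), 9, replace = TRUE),
    decision = sample(c("positive", "negative"), 9, replace = TRUE),
    tpr = runif(9, 0.1, 0.9), fpr = runif(9, 0.1, 0.9))
  base <- fuseSample(dec, 0.5)$posterior
  for (r in 1:30) {
    perm <- sample(nrow(dec))
    expect_equal(fuseSample(dec[perm, ], 0.5)$posterior, base,
                 tolerance = 1e-12)
  }
})

test_that("replaying an update log reproduces the posterior", {
  dec <- data.frame(modality = "OCT",
                    decision = c("positive", "negative", "positive"),
                    tpr = 0.8, fpr = 0.25)
  f <- fuseSample(dec, 0.5)
  p <- f$prior
  for (i in seq_len(nrow(f$updateLog))) {
    p <- updatePosterior(p, f$updateLog$tpr[i], f$updateLog$fpr[i],
                         f$updateLog$decision[i])
    expect_equal(p, f$updateLog$posterior[i], tolerance = 1e-15)
  }
  expect_equal(p, f$posterior)
})

test_that("combined validation yields one posterior per sample with full logs", {
  co <- smallCohort(seed = 21, imageSide = 48, nSubjects = 5,
                    nHealthy = 4, nTumor = 6, meanRs = 3, meanOct = 2)
  pp <- preprocessBatch(co$raman, preprocessConfig(welchAlpha = 1e-4),
                        response = co$truth$response,
                        interferents = co$truth$interferents)
  sel <- if (any(pp$bands$mask)) pp$bands$mask else rep(TRUE, 1024)
  fx <- octFeatureMatrix(co$oct)
  res <- suppressMessages(suppressWarnings(runCombinedValidation(
    t(spectra(pp$processed))[, sel, drop = FALSE],
    as.data.frame(recordInfo(pp$processed)),
    fx$features, as.data.frame(recordInfo(co$oct)), fx$blocks)))

  expect_equal(sort(res$samples$sample_id),
               sort(co$truth$samples$sample_id)) # each sample exactly once
  expect_equal(anyDuplicated(res$samples$sample_id), 0L)
  expect_true(all(res$samples$posteriorFused >= 0 &
                  res$samples$posteriorFused <= 1))
  expect_equal(res$samples$nRs + res$samples$nOct,
               co$truth$samples$nRs[match(res$samples$sample_id,
                                          co$truth$samples$sample_id)] +
               co$truth$samples$nOct[match(res$samples$sample_id,
                                           co$truth$samples$sample_id)])

  # thresholds recorded in every update-log entry
  for (lg in res$updateLogs) {
    if (!nrow(lg)) next
    expect_true(all(lg$threshold[lg$modality == "RS"] == 0.56))
    expect_true(all(lg$threshold[lg$modality == "OCT"] == 0.73))
  }

  # single-modality modes equal refusing the filtered update logs
  for (i in seq_len(nrow(res$samples))) {
    lg <- res$updateLogs[[res$samples$sample_id[i]]]
    rsOnly <- lg[lg$modality == "RS", , drop = FALSE]
    octOnly <- lg[lg$modality == "OCT", , drop = FALSE]
    expect_equal(res$samples$posteriorRs[i],
                 fuseSample(rsOnly, 0.5)$posterior, tolerance = 1e-12)
    expect_equal(res$samples$posteriorOct[i],
                 fuseSample(octOnly, 0.5)$posterior, tolerance = 1e-12)
  }

  # fold rates are clipped and derived from training data only
  for (f in res$folds) {
    expect_true(all(c(f$rsRates, f$octRates) >= 1e-3))
    expect_true(all(c(f$rsRates, f$octRates) <= 1 - 1e-3))
  }
})

test_that("operating-point report covers the three conventions per mode", {
  set.seed(22)
  samples <- data.frame(
    label = rep(c("healthy", "tumor"), each = 20),
    posteriorRs = c(runif(20, 0, 0.7), runif(20, 0.3, 1)),
    posteriorOct = c(runif(20, 0, 0.6), runif(20, 0.4, 1)),
    posteriorFused = c(runif(20, 0, 0.5), runif(20, 0.5, 1)))
  rep_ <- operatingPointReport(samples)
  expect_equal(names(rep_), c("rs", "oct", "fused"))
  for (m in rep_) {
    expect_equal(names(m$points), c("youden", "ctest", "stest"))
    expect_gte(m$points$stest$tpr, 0.9)
    for (p in m$points) {
      expect_equal(sum(p$confusion$counts), 40)
      expect_true(all(p$confusion$rounded >= 0 & p$confusion$rounded <= 1,
                      na.rm = TRUE))
    }
  }
  # perfectly separated posteriors: all operating points perfect
  sep <- data.frame(label = rep(c("healthy", "tumor"), each = 10),
                    posterior = rep(c(0.1, 0.9), each = 10))
  r2 <- operatingPointReport(sep, modes = c(all = "posterior"))
  for (p in r2$all$points)
    expect_equal(unname(p$confusion$stats["accuracy"]), 1)
  expect_error(operatingPointReport(data.frame(label = "tumor",
                                               posterior = 1),
                                    modes = c(a = "posterior")),
               "both classes")
})
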