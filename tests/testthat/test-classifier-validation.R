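test_that("leave-one-subject-out folds partition records by subject", {
  # toy hierarchy: 4 subjects, 8 samples, a few records each
  tf <- toyFeatures(1, nSubjects = 4, recsPerSubject = 8)
  folds <- losoSplit(tf$meta)
  expect_length(folds, 4L)
  testIdx <- sort(unlist(lapply(folds, `[[`, "testIdx")))
  expect_equal(testIdx, seq_len(nrow(tf$meta))) # each record tested once
  for (f in folds) {
    expect_length(intersect(tf$meta$subject_id[f$trainIdx],
                            tf$meta$subject_id[f$testIdx]), 0L)
    expect_equal(sort(c(f$trainIdx, f$testIdx)), seq_len(nrow(tf$meta)))
  }
  one <- tf$meta[tf$meta$subject_id == "S01", ]
  expect_error(losoSplit(one), "at least 2 subjects")
})

test_that("standardizer centres and scales with training parameters only", {
  set.seed(5)
  x <- matrix(rnorm(40 * 6, mean = 3, sd = 2), 40)
  st <- fitStandardizer(x)
  z <- applyStandardizer(x, st)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 6), tolerance = 1e-10)
  expect_equal(applyStandardizer(x, st), z) # idempotent refit application
  # a test row equal to the training mean maps to zero
  expect_equal(unname(applyStandardizer(rbind(st$center), st))[1, ],
               rep(0, 6))
  xc <- cbind(x, 7) # constant feature passes through centred
  expect_message(stc <- fitStandardizer(xc), "constant")
  expect_equal(unname(applyStandardizer(xc, stc)[, 7]), rep(0, 40))
})

test_that("PCA basis is orthonormal, ordered and training-derived", {
  set.seed(6)
  x <- matrix(rnorm(50 * 8), 50)
  pc <- fitPca(x, 4)
  expect_equal(crossprod(pc$rotation), diag(4), tolerance = 1e-8)
  expect_true(all(diff(pc$sdev) <= 1e-12))
  expect_equal(applyPca(x, pc), pc$scores, tolerance = 1e-8)
  # data in an exact 2-D plane are reconstructed by 2 components
  basis <- qr.Q(qr(matrix(rnorm(8 * 2), 8)))
  planar <- matrix(rnorm(50 * 2), 50) %*% t(basis)
  pc2 <- fitPca(planar, 2)
  recon <- sweep(applyPca(planar, pc2) %*% t(pc2$rotation), 2,
                 pc2$center, `+`)
  expect_equal(recon, planar, tolerance = 1e-8)
  expect_warning(fitPca(x[1:5, ], 10), "clamped")
})

test_that("composite OCT features equal their isolated block pipelines", {
  set.seed(7)
  x <- matrix(rnorm(30 * 20), 30)
  blocks <- list(a = 1:8, b = 9:14, c = 15:20)
  comp <- buildOctComposite(x, blocks, perBlockComponents = 3,
                           test = x[1:5, , drop = FALSE])
  expect_equal(ncol(comp$train), 9L) # 3 blocks x 3 components
  for (b in names(blocks)) {
    xb <- x[, blocks[[b]]]
    st <- fitStandardizer(xb)
    pc <- fitPca(applyStandardizer(xb, st), 3)
    iso <- applyPca(applyStandardizer(xb, st), pc)
    expect_equal(comp$train[, (match(b, names(blocks)) - 1) * 3 + 1:3], iso,
                 tolerance = 1e-10)
  }
  # permuting records permutes rows only
  perm <- sample(30)
  comp2 <- buildOctComposite(x[perm, ], blocks, perBlockComponents = 3)
  expect_equal(comp2$train, comp$train[perm, ], tolerance = 1e-8)
  expect_error(buildOctComposite(x, list(1:3)), "named list")
})

test_that("the LDA grid has the documented 21 configurations in fixed order", {
  g <- ldaGrid()
  expect_equal(nrow(g), 21L)
  expect_equal(unique(g$solver), c("svd", "lsqr", "eigen"))
  expect_equal(g$tol[1:7], 10^-seq(2, 14, by = 2))
})

test_that("LDA posteriors match MASS::lda on well-conditioned data", {
  skip_if_not_installed("MASS")
  set.seed(8)
  x <- matrix(rnorm(120 * 5), 120)
  y <- rep(c(FALSE, TRUE), each = 60)
  x[y, 1:2] <- x[y, 1:2] + 1
  prep <- ProbeFusion:::ldaPrep(x, y)
  ref <- predict(MASS::lda(x, grouping = y), x)$posterior[, "TRUE"]
  for (sv in c("svd", "lsqr", "eigen")) {
    m <- ProbeFusion:::ldaModel(prep, sv, 1e-10)
    expect_equal(unname(ldaPredict(m, x)), unname(ref), tolerance = 1e-8)
  }
})

test_that("nested tuning picks the exhaustive-argmax configuration", {
  tf <- toyFeatures(9, nSubjects = 6, recsPerSubject = 10, shift = 1.2)
  tuned <- suppressMessages(tuneLda(tf$x, tf$meta$label, tf$meta$subject_id))
  # independent exhaustive re-evaluation of the inner score table
  grid <- ldaGrid()
  subjects <- unique(tf$meta$subject_id)
  y <- tf$meta$label == "tumor"
  scores <- sapply(seq_len(nrow(grid)), function(g) {
    av <- c()
    for (s in subjects) {
      te <- tf$meta$subject_id == s
      if (length(unique(y[te])) < 2) next
      prep <- ProbeFusion:::ldaPrep(tf$x[!te, ], y[!te])
      m <- ProbeFusion:::ldaModel(prep, grid$solver[g], grid$tol[g])
      p <- ldaPredict(m, tf$x[te, , drop = FALSE])
      av <- c(av, uStatAuc(p, y[te]))
    }
    mean(av)
  })
  expect_equal(unname(tuned$scores), unname(scores), tolerance = 1e-12)
  expect_equal(which.max(scores),
               which(grid$solver == tuned$config$solver &
                     grid$tol == tuned$config$tol))
  # separable toy data: training AUC 1 for the selected model
  p <- ldaPredict(tuned$model, tf$x)
  sepX <- tf$x; sepX[y, ] <- sepX[y, ] + 50
  sepTuned <- suppressMessages(tuneLda(sepX, y, tf$meta$subject_id))
  expect_equal(uStatAuc(ldaPredict(sepTuned$model, sepX), y), 1)
})

test_that("modality validation pools held-out predictions subject-wise", {
  tf <- toyFeatures(10, nSubjects = 6, recsPerSubject = 10, shift = 1.5)
  v <- suppressMessages(validateModality(tf$x, tf$meta, nComponents = 5))
  expect_true(all(v$predictions$probability >= 0 &
                  v$predictions$probability <= 1))
  expect_false(any(is.na(v$predictions$probability)))
  expect_equal(v$predictions$fold, v$predictions$subject_id)
  expect_gt(rocAuc(v$roc), 0.8)
  # pooled ROC invariant to record order
  perm <- withSeed(1, sample(nrow(tf$meta)))
  v2 <- suppressMessages(validateModality(tf$x[perm, ], tf$meta[perm, ],
                                          nComponents = 5))
  expect_equal(rocAuc(v2$roc), rocAuc(v$roc), tolerance = 1e-10)
})

test_that("null cohorts (no class contrast) validate at chance level", {
  aucs <- vapply(1:5, function(seed) {
    tf <- toyFeatures(100 + seed, nSubjects = 6, recsPerSubject = 10,
                      shift = 0)
    v <- suppressMessages(validateModality(tf$x, tf$meta, nComponents = 5))
    rocAuc(v$roc)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("no information flows from held-out records into fold parameters", {
  tf <- toyFeatures(11, nSubjects = 5, recsPerSubject = 8, shift = 1)
  v1 <- suppressMessages(validateModality(tf$x, tf$meta, nComponents = 4))
  x2 <- tf$x
  heldOut <- tf$meta$subject_id == "S03"
  x2[heldOut, ] <- x2[heldOut, ] + 100 # perturb only held-out records
  v2 <- suppressMessages(validateModality(x2, tf$meta, nComponents = 4))
  f1 <- v1$models[["S03"]]; f2 <- v2$models[["S03"]]
  expect_identical(f1$transforms$standardizer, f2$transforms$standardizer)
  expect_identical(f1$transforms$pca$rotation, f2$transforms$pca$rotation)
  expect_identical(f1$tuned$model$weights, f2$tuned$model$weights)
  expect_identical(f1$tuned$config, f2$tuned$config)
  expect_identical(f1$trainProb, f2$trainProb)
  # predictions for the perturbed subject do change (sanity of the probe)
  expect_false(isTRUE(all.equal(v1$predictions$probability[heldOut],
                                v2$predictions$probability[heldOut])))
})
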