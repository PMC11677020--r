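#' Leave-one-subject-out folds
#'
#' One fold per subject: all records of the held-out subject form the test
#' partition. Splitting at the highest hierarchical level (the subject)
#' removes identity confounding between train and test.
#'
#' @param meta data.frame / DataFrame with columns `subject_id` and
#'   `record_id`.
#' @return list of folds, each `list(subject, trainIdx, testIdx)`.
#' @export
losoSplit <- function(meta) {
  meta <- as.data.frame(meta)
  subjects <- unique(meta$subject_id)
  if (length(subjects) < 2L)
    stop("leave-one-subject-out needs at least 2 subjects")
  lapply(subjects, function(s) {
    test <- which(meta$subject_id == s)
    list(subject = s, trainIdx = setdiff(seq_len(nrow(meta)), test),
         testIdx = test)
  })
}

#' Z-score standardizer
#'
#' `fitStandardizer` learns per-feature means and sds from the training
#' rows; `applyStandardizer` reuses them on any data, so test records are
#' transformed with training-derived parameters only. Zero-variance features
#' are centred but scaled by 1 (with a message).
#'
#' @param x numeric matrix, rows = records.
#' @return `fitStandardizer`: list with `center`, `scale`;
#'   `applyStandardizer`: transformed matrix.
#' @export
fitStandardizer <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L) stop("need at least 2 training rows")
  ctr <- colMeans(x)
  sc <- apply(x, 2, sd)
  bad <- !is.finite(sc) | sc == 0
  if (any(bad)) {
    message(sum(bad), " constant feature(s): sd treated as 1")
    sc[bad] <- 1
  }
  list(center = ctr, scale = sc)
}

#' @rdname fitStandardizer
#' @param standardizer a fitted standardizer.
#' @export
applyStandardizer <- function(x, standardizer) {
  sweep(sweep(x, 2, standardizer$center), 2, standardizer$scale, `/`)
}

#' Principal component analysis for classifier inputs
#'
#' `fitPca` learns the centring vector and the leading orthonormal
#' directions from the training rows (via the SVD of the centred matrix);
#' `applyPca` projects any data onto the training basis. `nComponents` is
#' clamped to `min(rows - 1, cols)` with a warning.
#'
#' @param x numeric matrix, rows = records.
#' @param nComponents number of leading components.
#' @return `fitPca`: list with `center`, `rotation` (cols = components),
#'   `sdev`, `scores`; `applyPca`: score matrix.
#' @export
fitPca <- function(x, nComponents = 10L) {
  kmax <- min(nrow(x) - 1L, ncol(x))
  if (nComponents > kmax) {
    warning(sprintf("nComponents clamped from %d to %d", nComponents, kmax))
    nComponents <- kmax
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  s <- svd(xc, nu = nComponents, nv = nComponents)
  k <- seq_len(nComponents)
  # deterministic sign convention: largest-magnitude loading positive
  flip <- vapply(k, function(j) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  rot <- sweep(s$v, 2, flip, `*`)
  list(center = ctr, rotation = rot,
       sdev = s$d[k] / sqrt(max(1, nrow(x) - 1)),
       scores = sweep(s$u %*% diag(s$d[k], nComponents), 2, flip, `*`))
}

#' @rdname fitPca
#' @param basis a fitted PCA basis.
#' @export
applyPca <- function(x, basis) {
  sweep(x, 2, basis$center) %*% basis$rotation
}

#' Composite OCT feature vectors
#'
#' For each texture block independently: Z-score standardization then PCA,
#' both fitted on the training rows; the per-block scores are concatenated
#' in fixed block order. Test rows reuse the training-derived transforms.
#'
#' @param train records x features training matrix.
#' @param blocks named list of column-index vectors, one per texture block
#'   (fixed order gabor, lbp, lpq, glcm as produced by
#'   [octFeatureMatrix()]).
#' @param perBlockComponents PCA dimensions per block (default 10).
#' @param test optional matrix to transform with the training parameters.
#' @return list with `train` (composite training scores), `test` (or
#'   `NULL`), and `transforms` (per-block standardizer + PCA).
#' @export
buildOctComposite <- function(train, blocks, perBlockComponents = 10L,
                              test = NULL) {
  if (is.null(names(blocks)) || any(!lengths(blocks)))
    stop("blocks must be a named list of column indices")
  transforms <- list(); trs <- list(); tes <- list()
  for (b in names(blocks)) {
    xb <- train[, blocks[[b]], drop = FALSE]
    st <- fitStandardizer(xb)
    zs <- applyStandardizer(xb, st)
    pc <- fitPca(zs, perBlockComponents)
    trs[[b]] <- applyPca(zs, pc)
    if (!is.null(test))
      tes[[b]] <- applyPca(
        applyStandardizer(test[, blocks[[b]], drop = FALSE], st), pc)
    transforms[[b]] <- list(standardizer = st, pca = pc)
  }
  list(train = do.call(cbind, trs),
       test = if (is.null(test)) NULL else do.call(cbind, tes),
       transforms = transforms)
}

#' Hyperparameter grid for the LDA tuning loop
#'
#' Three solver routes (singular value decomposition of the within-class
#' data, least-squares solution of the normal equations, eigenvalue
#' decomposition of the pooled covariance) crossed with seven rank/
#' truncation tolerances, giving 21 configurations evaluated in this fixed
#' order (ties in the tuning score go to the earliest configuration).
#'
#' @return data.frame with columns `solver`, `tol`.
#' @export
ldaGrid <- function() {
  expand.grid(tol = c(1e-2, 1e-4, 1e-6, 1e-8, 1e-10, 1e-12, 1e-14),
              solver = c("svd", "lsqr", "eigen"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
}

## sufficient statistics shared by all solver/tolerance configurations
ldaPrep <- function(x, y) {
  n1 <- sum(y); n0 <- sum(!y); n <- n0 + n1
  mu0 <- colMeans(x[!y, , drop = FALSE])
  mu1 <- colMeans(x[y, , drop = FALSE])
  xc <- x
  xc[!y, ] <- sweep(x[!y, , drop = FALSE], 2, mu0)
  xc[y, ] <- sweep(x[y, , drop = FALSE], 2, mu1)
  Sw <- crossprod(xc) / (n - 2)
  list(mu0 = mu0, mu1 = mu1, n0 = n0, n1 = n1, Sw = Sw,
       svdXc = svd(xc, nu = 0), eigSw = eigen(Sw, symmetric = TRUE))
}

## weight vector from one solver route at one tolerance
ldaWeights <- function(prep, solver, tol) {
  d <- prep$mu1 - prep$mu0
  n <- prep$n0 + prep$n1
  if (solver == "svd") {
    sv <- prep$svdXc$d
    keep <- sv > tol * sv[1]
    lam <- sv[keep]^2 / (n - 2)
    V <- prep$svdXc$v[, keep, drop = FALSE]
    drop(V %*% ((crossprod(V, d)) / lam))
  } else if (solver == "eigen") {
    ev <- prep$eigSw$values
    keep <- ev > tol * ev[1]
    V <- prep$eigSw$vectors[, keep, drop = FALSE]
    drop(V %*% (crossprod(V, d) / ev[keep]))
  } else { # lsqr: least-squares solve of Sw w = d via rank-revealing QR
    qrS <- qr(prep$Sw, tol = tol)
    w <- qr.coef(qrS, d)
    w[is.na(w)] <- 0
    w
  }
}

ldaModel <- function(prep, solver, tol) {
  w <- ldaWeights(prep, solver, tol)
  b <- -sum(w * (prep$mu0 + prep$mu1)) / 2 + log(prep$n1 / prep$n0)
  list(weights = w, intercept = b, solver = solver, tol = tol,
       mu0 = prep$mu0, mu1 = prep$mu1)
}

#' Predict tumor posteriors from a fitted LDA model
#'
#' Posterior probability of the tumor class under the equal-covariance
#' Gaussian model: the logistic of the linear discriminant score.
#'
#' @param model fitted model from [tuneLda()] (`$model`) or an internal fit.
#' @param x records x features matrix (same space the model was fitted in).
#' @return vector of tumor probabilities in \[0, 1\].
#' @export
ldaPredict <- function(model, x) {
  plogis(drop(x %*% model$weights) + model$intercept)
}

#' Tune an LDA classifier by nested leave-one-subject-out CV
#'
#' Evaluates every solver x tolerance configuration of [ldaGrid()] by inner
#' leave-one-subject-out AUC on the training subjects (folds whose held-out
#' records contain a single class are skipped from the score, with a
#' message), then refits the best configuration on the full training set.
#' Ties are broken by the first configuration in the fixed grid order.
#'
#' @param x training feature matrix (already standardized/projected).
#' @param y training labels (logical or healthy/tumor).
#' @param subjects per-row subject ids driving the inner split.
#' @param grid configuration grid, see [ldaGrid()].
#' @return list with `model` (full-training fit), `config` (chosen row),
#'   `scores` (mean inner AUC per configuration), `grid`.
#' @export
tuneLda <- function(x, y, subjects, grid = ldaGrid()) {
  y <- asTumorLogical(y)
  subjects <- as.character(subjects)
  us <- unique(subjects)
  if (length(us) < 2L) stop("nested tuning needs at least 2 training subjects")
  nCfg <- nrow(grid)
  aucs <- matrix(NA_real_, length(us), nCfg)
  skipped <- 0L
  for (k in seq_along(us)) {
    te <- subjects == us[k]
    if (length(unique(y[te])) < 2L) { skipped <- skipped + 1L; next }
    prep <- ldaPrep(x[!te, , drop = FALSE], y[!te])
    for (g in seq_len(nCfg)) {
      m <- ldaModel(prep, grid$solver[g], grid$tol[g])
      p <- ldaPredict(m, x[te, , drop = FALSE])
      aucs[k, g] <- fastAuc(p, y[te])
    }
  }
  if (skipped > 0L)
    message(skipped, " inner fold(s) with one class skipped from the score")
  score <- colMeans(aucs, na.rm = TRUE)
  if (all(is.nan(score))) stop("no informative inner fold available")
  best <- which.max(score) # first maximum wins: fixed grid order
  prep <- ldaPrep(x, y)
  list(model = ldaModel(prep, grid$solver[best], grid$tol[best]),
       config = grid[best, ], scores = score, grid = grid)
}

## fit one outer fold for a modality: standardize -> PCA (per block for
## OCT composites) -> nested-CV-tuned LDA. Only training rows enter any
## fitted parameter.
fitModalityFold <- function(train, trainMeta, nComponents, blocks, grid) {
  y <- asTumorLogical(trainMeta$label)
  if (is.null(blocks)) {
    st <- fitStandardizer(train)
    z <- applyStandardizer(train, st)
    pc <- fitPca(z, nComponents)
    sc <- applyPca(z, pc)
    tuned <- tuneLda(sc, y, trainMeta$subject_id, grid)
    transform <- function(newx) applyPca(applyStandardizer(newx, st), pc)
    transforms <- list(standardizer = st, pca = pc)
  } else {
    comp <- buildOctComposite(train, blocks, nComponents)
    sc <- comp$train
    tuned <- tuneLda(sc, y, trainMeta$subject_id, grid)
    transform <- function(newx) {
      out <- lapply(names(blocks), function(b) {
        tr <- comp$transforms[[b]]
        applyPca(applyStandardizer(newx[, blocks[[b]], drop = FALSE],
                                   tr$standardizer), tr$pca)
      })
      do.call(cbind, out)
    }
    transforms <- comp$transforms
  }
  trainProb <- ldaPredict(tuned$model, sc)
  list(tuned = tuned, transform = transform, transforms = transforms,
       trainProb = trainProb, trainLabel = y)
}

#' Leave-one-subject-out validation of one modality
#'
#' For each outer fold the standardizer, the PCA basis (per texture block
#' for OCT composites) and the nested-CV-tuned LDA are fitted on the
#' training subjects only; the held-out subject's records are transformed
#' with the training parameters and scored. All held-out predictions are
#' pooled into a single ROC curve.
#'
#' @param features records x features matrix.
#' @param meta per-record metadata with `record_id`, `subject_id`,
#'   `sample_id`, `label`.
#' @param nComponents PCA components (10 per the validated design; for OCT
#'   composites, per block).
#' @param blocks `NULL` for a single feature block (Raman), or the named
#'   block index list from [octFeatureMatrix()] for OCT.
#' @param grid hyperparameter grid, see [ldaGrid()].
#' @return list with `predictions` (data.frame: record_id, subject_id,
#'   sample_id, label, probability, fold), `roc` (pooled [RocCurve-class]),
#'   and `models` (per-fold fits: chosen config, transforms, training
#'   probabilities).
#' @export
validateModality <- function(features, meta, nComponents = 10L,
                             blocks = NULL, grid = ldaGrid()) {
  meta <- as.data.frame(meta)
  folds <- losoSplit(meta)
  prob <- rep(NA_real_, nrow(meta))
  foldId <- rep(NA_character_, nrow(meta))
  models <- list()
  for (f in folds) {
    fit <- fitModalityFold(features[f$trainIdx, , drop = FALSE],
                           meta[f$trainIdx, ], nComponents, blocks, grid)
    te <- fit$transform(features[f$testIdx, , drop = FALSE])
    prob[f$testIdx] <- ldaPredict(fit$tuned$model, te)
    foldId[f$testIdx] <- f$subject
    models[[f$subject]] <- fit
  }
  predictions <- data.frame(record_id = meta$record_id,
                            subject_id = meta$subject_id,
                            sample_id = meta$sample_id,
                            label = meta$label,
                            probability = prob, fold = foldId)
  list(predictions = predictions,
       roc = rocCurve(prob, meta$label),
       models = models)
}
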