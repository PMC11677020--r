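## shared fixtures: small cohorts and independent brute-force oracles

smallSpec <- function(seed = 1, nSubjects = 6, nHealthy = 5, nTumor = 7,
                      meanRs = 3, meanOct = 3, rsEffect = 5, octEffect = 1) {
  cohortSpec(nSubjects = nSubjects, nHealthySamples = nHealthy,
             nTumorSamples = nTumor, meanRsRecordsPerSample = meanRs,
             meanOctRecordsPerSample = meanOct,
             rsEffectSize = rsEffect, octEffectSize = octEffect, seed = seed)
}

smallCohort <- function(seed = 1, imageSide = 64, ...) {
  generateCohort(smallSpec(seed = seed, ...), imageSide = imageSide)
}

## random feature matrix + hierarchical metadata for validation tests
toyFeatures <- function(seed, nSubjects = 6, recsPerSubject = 8, p = 12,
                        shift = 0) {
  withSeed(seed, {
    n <- nSubjects * recsPerSubject
    meta <- data.frame(
      record_id = sprintf("R%03d", seq_len(n)),
      subject_id = rep(sprintf("S%02d", seq_len(nSubjects)),
                       each = recsPerSubject),
      sample_id = rep(sprintf("SA%03d", seq_len(nSubjects * 2)),
                      each = recsPerSubject / 2),
      label = rep(rep(c("healthy", "tumor"), each = recsPerSubject / 2),
                  nSubjects))
    x <- matrix(rnorm(n * p), n, p)
    x[meta$label == "tumor", 1:3] <- x[meta$label == "tumor", 1:3] + shift
    list(x = x, meta = meta)
  })
}

## independent bilinear-interpolated LBP reference (plain loops)
lbpRef <- function(img, P, R) {
  nr <- nrow(img); nc <- ncol(img)
  m <- ceiling(R)
  hist <- numeric(P + 2)
  vars <- c()
  sample_at <- function(rr, cc) {
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
    (1 - fr) * (1 - fc) * img[r0, c0] + fr * (1 - fc) * img[r1, c0] +
      (1 - fr) * fc * img[r0, c1] + fr * fc * img[r1, c1]
  }
  for (i in (m + 1):(nr - m)) {
    for (j in (m + 1):(nc - m)) {
      v <- numeric(P)
      for (k in 0:(P - 1)) {
        a <- 2 * pi * k / P
        dr <- -R * sin(a); dc <- R * cos(a)
        if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
        if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
        v[k + 1] <- sample_at(i + dr, j + dc)
      }
      b <- as.integer(v >= img[i, j] - 1e-9)
      trans <- sum(b != c(b[-1], b[1]))
      bin <- if (trans <= 2) sum(b) else P + 1
      hist[bin + 1] <- hist[bin + 1] + 1
      vars <- c(vars, mean((v - mean(v))^2))
    }
  }
  list(hist = hist / sum(hist), varMean = mean(vars),
       varSd = sqrt(mean(vars^2) - mean(vars)^2))
}

## independent LPQ reference: direct windowed DFT at the four frequencies
lpqRef <- function(img, w = 7) {
  m <- w %/% 2; a <- 1 / w
  nr <- nrow(img); nc <- ncol(img)
  codes <- c()
  freqs <- list(c(a, 0), c(0, a), c(a, a), c(a, -a)) # (ux along x=cols, uy)
  for (i in (m + 1):(nr - m)) {
    for (j in (m + 1):(nc - m)) {
      bits <- integer(0)
      for (u in freqs) {
        F <- 0 + 0i
        for (y in -m:m) for (x in -m:m)
          F <- F + img[i + y, j + x] * exp(-2i * pi * (u[1] * x + u[2] * y))
        bits <- c(bits, as.integer(Re(F) > 0), as.integer(Im(F) > 0))
      }
      codes <- c(codes, sum(bits * 2^(seq_along(bits) - 1)))
    }
  }
  h <- tabulate(codes + 1, nbins = 256)
  h / sum(h)
}

## independent GLCM reference: explicit pair enumeration at offset (dr, dc)
glcmRef <- function(q, levels, dr, dc) {
  M <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    i2 <- i + dr; j2 <- j + dc
    if (i2 >= 1 && i2 <= nr && j2 >= 1 && j2 <= nc)
      M[q[i, j] + 1, q[i2, j2] + 1] <- M[q[i, j] + 1, q[i2, j2] + 1] + 1
  }
  M
}

## pairwise Mann-Whitney AUC oracle
uStatAuc <- function(scores, y) {
  s1 <- scores[y]; s0 <- scores[!y]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}
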