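test_that("a rigid trajectory has a vanishing covariance matrix", {
  ref <- generateReferenceStructure(8, 1, seed = 1)
  tr <- rigidTumblingTrajectory(ref, nFrames = 30, seed = 2)
  C <- covarianceMatrix(tr, startFraction = 0)
  expect_lt(max(abs(C)), 1e-12)
  es <- eigenDecompose(C)
  pr <- projectTrajectory(tr, es, 2)
  expect_lt(max(abs(pr$p1)), 1e-6)
  expect_lt(max(abs(pr$p2)), 1e-6)
})

test_that("the covariance trace equals the sum of squared RMSFs", {
  ref <- generateReferenceStructure(10, 2, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.05, nFrames = 200, tumbling = TRUE, seed = 3)
  sp <- protdyn:::superposeToMean(tr, "name CA", startFraction = 0.5)
  C <- covarianceMatrix(tr, superposed = sp)
  p <- rmsfProfile(tr, superposed = sp)
  expect_equal(sum(diag(C)), sum(p$rmsf^2), tolerance = 1e-10)
})

test_that("eigendecomposition obeys the spectral identities", {
  # equal variance in every direction: flat spectrum
  es <- eigenDecompose(diag(6))
  expect_equal(varianceFraction(es), rep(1 / 6, 6))
  expect_equal(cumulativeFraction(es), (1:6) / 6)
  # rank-1: all variance on the first mode
  v <- c(1, 2, 3, 4) / sqrt(30)
  es1 <- eigenDecompose(outer(v, v))
  expect_equal(varianceFraction(es1)[1], 1)
  expect_equal(sum(abs(varianceFraction(es1)[-1])), 0, tolerance = 1e-12)
  # reconstruction and orthonormality on a random PSD matrix
  set.seed(4)
  A <- matrix(rnorm(100), 10)
  C <- crossprod(A) / 10
  es2 <- eigenDecompose(C)
  V <- eigenVectors(es2)
  expect_equal(V %*% diag(eigenValues(es2)) %*% t(V), C, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(crossprod(V), diag(10), tolerance = 1e-9)
  # deterministic sign convention: largest component positive
  expect_true(all(apply(V, 2, function(x) x[which.max(abs(x))]) > 0))
  expect_error(eigenDecompose(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("projection variances reproduce the eigenvalues", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.06, nFrames = 300, tumbling = TRUE, seed = 5)
  sp <- protdyn:::superposeToMean(tr, "name CA", startFraction = 0.5)
  C <- covarianceMatrix(tr, superposed = sp)
  es <- eigenDecompose(C)
  k <- 5
  pr <- projectTrajectory(tr, es, k, superposed = sp)
  P <- as.matrix(pr[, -1])
  nW <- nrow(P)
  # population (1/F) variance, matching the covariance normalization
  vars <- colSums(sweep(P, 2, colMeans(P))^2) / nW
  expect_equal(unname(vars), eigenValues(es)[1:k], tolerance = 1e-9)
  # distinct modes are uncorrelated
  cc <- crossprod(sweep(P, 2, colMeans(P))) / nW
  offdiag <- cc[upper.tri(cc)]
  expect_lt(max(abs(offdiag)), 1e-9)
  expect_error(projectTrajectory(tr, es, 10000), "k must be in")
})

test_that("the correlation map flags coupled and anti-coupled residues", {
  set.seed(6)
  # three residues: 2 moves with 1, 3 moves against 1, plus tiny jitter
  nF <- 400
  base <- matrix(rnorm(3 * nF, sd = 0.1), ncol = 3)
  frames <- lapply(seq_len(nF), function(f) {
    rbind(c(0, 0, 0) + base[f, ],
          c(2, 0, 0) + base[f, ],
          c(4, 0, 0) - base[f, ])
  })
  top <- miniTopology(c("C", "C", "C"), frames[[1]],
                      names = c("CA", "CA", "CA"), resid = 1:3)
  tr <- miniTrajectory(top, frames)
  # no superposition: fitting three coupled points would distort the signal,
  # so compute the map on the raw displacements via a precomputed pass-through
  sp <- list(coords = coords(tr),
             mean = apply(coords(tr), c(1, 2), mean),
             frames = seq_len(nF), times = frameTimes(tr),
             fitSelection = "none", startFraction = 0)
  M <- correlationMap(tr, selection = "name CA", superposed = sp)
  expect_equal(diag(M), rep(1, 3), ignore_attr = TRUE)
  expect_equal(M[1, 2], 1, tolerance = 1e-9)
  expect_equal(M[1, 3], -1, tolerance = 1e-9)
  expect_equal(M, t(M))
})

test_that("zero-variance residues get zeroed correlations with a warning", {
  nF <- 50
  set.seed(7)
  frames <- lapply(seq_len(nF), function(f)
    rbind(c(0, 0, 0), c(2, 0, 0) + rnorm(3, sd = 0.1)))
  top <- miniTopology(c("C", "C"), frames[[1]], names = c("CA", "CA"),
                      resid = 1:2)
  tr <- miniTrajectory(top, frames)
  sp <- list(coords = coords(tr), mean = apply(coords(tr), c(1, 2), mean),
             frames = seq_len(nF), times = frameTimes(tr),
             fitSelection = "none", startFraction = 0)
  expect_warning(M <- correlationMap(tr, selection = "name CA",
                                     superposed = sp), "zero variance")
  expect_equal(M[1, 2], 0)
  expect_equal(diag(M), rep(1, 2), ignore_attr = TRUE)
})

test_that("independent residues decorrelate as frames accumulate", {
  ref <- generateReferenceStructure(12, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.05, nFrames = 2000, seed = 8)
  M <- correlationMap(tr, startFraction = 0, fitSelection = "all")
  off <- abs(M[upper.tri(M)])
  expect_lt(median(off), 0.1)
})

test_that("cumulative variance reporting matches mode construction", {
  es <- eigenDecompose(diag(40))
  expect_equal(unname(cumulativeVarianceReport(es, 2)), 5.0)
  v <- rnorm(12); C1 <- outer(v, v)
  expect_equal(unname(cumulativeVarianceReport(eigenDecompose(C1), 2)), 100)
  # a single dominant collective mode: one direction carries the motion
  set.seed(9)
  ref <- generateReferenceStructure(10, 1, seed = 1)
  nCA <- 10; nF <- 500
  dir <- rnorm(3 * nCA); dir <- dir / sqrt(sum(dir^2))
  amp <- rnorm(nF, sd = 0.2)
  caIdx <- selectAtoms(topology(ref), "name CA")@indices
  co <- array(coords(ref)[, , 1], dim = c(nAtoms(ref), 3, nF))
  for (f in seq_len(nF)) {
    co[caIdx, , f] <- co[caIdx, , f] +
      amp[f] * matrix(dir, ncol = 3, byrow = TRUE) +
      matrix(rnorm(3 * nCA, sd = 0.002), ncol = 3)
  }
  tr <- new("Trajectory", coords = co, times = seq_len(nF) - 1,
            topology = topology(ref))
  sp <- list(coords = co, mean = apply(co, c(1, 2), mean),
             frames = seq_len(nF), times = frameTimes(tr),
             fitSelection = "none", startFraction = 0)
  es2 <- eigenDecompose(covarianceMatrix(tr, superposed = sp))
  expect_gte(unname(cumulativeVarianceReport(es2, 1)), 95)
})
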