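test_that("self-superposition is the identity with zero residual", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  fit <- kabschFit(x, x)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(fit$translation), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
})

test_that("a pure rotation is recovered exactly", {
  set.seed(2)
  x <- matrix(rnorm(30), ncol = 3)
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)  # 90 deg about z
  fit <- kabschFit(x %*% t(Rz), x)
  expect_equal(fit$rotation %*% t(Rz), diag(3), tolerance = 1e-10)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
})

test_that("Kabsch residual equals the quaternion-method oracle", {
  set.seed(3)
  for (case in 1:25) {
    n <- sample(4:100, 1)
    ref <- matrix(rnorm(3 * n), ncol = 3)
    R <- randomRotation()
    noise <- matrix(rnorm(3 * n, sd = runif(1, 0, 0.3)), ncol = 3)
    mobile <- (ref + noise) %*% t(R) + rep(runif(3, -2, 2), each = n)
    w <- if (case %% 2) runif(n, 0.5, 2) else NULL
    fit <- kabschFit(mobile, ref, w)
    oracle <- hornSuperposition(mobile, ref, w)
    expect_lt(abs(fit$rmsd - oracle$rmsd), 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(kabschFit(matrix(rnorm(6), ncol = 3),
                         matrix(rnorm(6), ncol = 3)), ">= 3 points")
  line <- cbind(1:5, 0, 0)
  expect_error(kabschFit(line, line), "collinear")
})

test_that("RMSD vanishes for rigidly transformed copies of the reference", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  tr <- rigidTumblingTrajectory(ref, nFrames = 20, seed = 2)
  for (sel in c("all", "backbone")) {
    r <- rmsdSeries(tr, fitSelection = sel)
    expect_lt(max(r$rmsd), 1e-6)
  }
})

test_that("fitted RMSD never exceeds the unfitted deviation", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.05, nFrames = 30, tumbling = TRUE, seed = 3)
  r <- rmsdSeries(tr, fitSelection = "all", massWeightedFit = FALSE)
  raw <- vapply(seq_len(nFrames(tr)), function(f)
    sqrt(mean(rowSums((coords(tr)[, , f] - coords(tr)[, , 1])^2))), numeric(1))
  expect_true(all(r$rmsd <= raw + 1e-12))
})

test_that("RMSD series agrees with an independent trajectory library", {
  skip_if_not_installed("bio3d")
  ref <- generateReferenceStructure(12, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.05, nFrames = 25, tumbling = TRUE, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writePDBTrajectory(tr, f)
  back <- readPDBTrajectory(f)
  ours <- rmsdSeries(back, fitSelection = "all", massWeightedFit = FALSE)
  pdb <- suppressWarnings(bio3d::read.pdb(f, multi = TRUE))
  # bio3d notes it is fitting on all positions, which is what we compare
  xyz <- suppressWarnings(bio3d::fit.xyz(pdb$xyz[1, ], pdb$xyz))
  theirs <- bio3d::rmsd(xyz[1, ], xyz) / 10  # Angstrom -> nm (printed at 3 d.p. A)
  expect_lt(max(abs(ours$rmsd - as.numeric(theirs))), 1e-4)
})

test_that("radius of gyration has its closed-form and scaling properties", {
  top <- miniTopology(c("C", "C"), rbind(c(0, 0, 0), c(1, 0, 0)))
  tr <- miniTrajectory(top, list(rbind(c(0, 0, 0), c(1, 0, 0))))
  expect_equal(radiusOfGyrationSeries(tr)$rg, 0.5)
  one <- miniTopology("C", matrix(c(1, 2, 3), 1))
  tr1 <- miniTrajectory(one, list(matrix(c(1, 2, 3), 1)))
  expect_equal(radiusOfGyrationSeries(tr1)$rg, 0)
  # homogeneity of degree 1, and rigid-motion invariance
  ref <- generateReferenceStructure(10, 1, seed = 1)
  rg1 <- radiusOfGyrationSeries(ref)$rg
  doubled <- new("Trajectory", coords = coords(ref) * 2, times = 0,
                 topology = topology(ref))
  expect_equal(radiusOfGyrationSeries(doubled)$rg, 2 * rg1)
  moved <- rigidTumblingTrajectory(ref, nFrames = 10, seed = 5)
  expect_equal(radiusOfGyrationSeries(moved)$rg, rep(rg1, 10), tolerance = 1e-9)
})

test_that("RMSF is zero for a static trajectory and linear in sigma", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  static <- generateHarmonicTrajectory(ref, 0, nFrames = 10, seed = 1)
  expect_equal(rmsfProfile(static, startFraction = 0)$rmsf, rep(0, 10),
               tolerance = 1e-12)
  expect_error(rmsfProfile(new("Trajectory", coords = coords(ref),
    times = 0, topology = topology(ref))), "single frame")
  # two sigma levels in 3:1 ratio recover a 3:1 RMSF ratio
  sig <- rep(c(0.05, 0.15), each = 10)
  ref2 <- generateReferenceStructure(20, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref2, sig, nFrames = 3000, seed = 6)
  p <- rmsfProfile(tr, fitSelection = "all", startFraction = 0)
  ratio <- mean(p$rmsf[11:20]) / mean(p$rmsf[1:10])
  expect_equal(ratio, 3, tolerance = 0.1)
})

test_that("B-factor conversion follows the 8 pi^2 / 3 law and inverts", {
  expect_equal(bfactorFromRmsf(0), 0)
  expect_equal(bfactorFromRmsf(0.1), 8 * pi^2 / 3, tolerance = 1e-12)  # 1 A
  expect_equal(bfactorFromRmsf(0.1), 26.3189, tolerance = 1e-5)
  expect_equal(bfactorFromRmsf(rmsfFromBfactor(3.98)), 3.98, tolerance = 1e-9)
  expect_error(bfactorFromRmsf(-0.1), "non-negative")
  # monotone in RMSF
  x <- seq(0, 0.3, by = 0.01)
  expect_true(all(diff(bfactorFromRmsf(x)) > 0))
  # profile form appends a bfactor column
  p <- data.frame(chain = "A", resid = 1:2, rmsf = c(0.1, 0.2))
  expect_equal(bfactorFromRmsf(p)$bfactor, 8 * pi^2 * c(1, 4) / 3)
})
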