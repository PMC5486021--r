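test_that("reference structure has five named backbone atoms per residue", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  expect_equal(nAtoms(ref), 50)
  top <- topology(ref)
  expect_equal(length(selectAtoms(top, "name CA")@indices), 10)
  expect_setequal(unique(atoms(top)$name), c("N", "H", "CA", "C", "O"))
  # N-H bond length is the standard amide 0.10 nm
  pairs <- selectAtoms(top, "amide-NH")@pairs
  co <- coords(ref)[, , 1]
  nh <- sqrt(rowSums((co[pairs[, "H"], ] - co[pairs[, "N"], ])^2))
  expect_equal(nh, rep(0.10, nrow(pairs)), tolerance = 1e-10)
})

test_that("multi-chain reference labels chains A upward and scales residues", {
  ref <- generateReferenceStructure(10, 4, seed = 1)
  top <- topology(ref)
  expect_equal(nResidues(top), 40)
  expect_equal(sort(unique(atoms(top)$chain)), c("A", "B", "C", "D"))
  expect_error(generateReferenceStructure(1, 1), "invalid spec")
})

test_that("generators are deterministic for a fixed seed", {
  r1 <- generateReferenceStructure(8, 2, seed = 7)
  r2 <- generateReferenceStructure(8, 2, seed = 7)
  expect_identical(coords(r1), coords(r2))
  t1 <- generateHarmonicTrajectory(r1, 0.05, nFrames = 20, tumbling = TRUE, seed = 3)
  t2 <- generateHarmonicTrajectory(r2, 0.05, nFrames = 20, tumbling = TRUE, seed = 3)
  expect_identical(coords(t1), coords(t2))
  c1 <- generateConeVectors(30, nFrames = 100, seed = 5)
  c2 <- generateConeVectors(30, nFrames = 100, seed = 5)
  expect_identical(c1$vectors, c2$vectors)
  d1 <- generateMMDataset(10, 50, 0.1, c(1, 5, 10, 50), seed = 9)
  d2 <- generateMMDataset(10, 50, 0.1, c(1, 5, 10, 50), seed = 9)
  expect_identical(d1$velocity, d2$velocity)
})

test_that("zero-amplitude trajectory reproduces the reference in every frame", {
  ref <- generateReferenceStructure(10, 1, seed = 1)
  tr <- generateHarmonicTrajectory(ref, sigma = 0, nFrames = 5, seed = 2)
  for (f in 1:5)
    expect_equal(coords(tr)[, , f], coords(ref)[, , 1], tolerance = 0)
  r <- rmsdSeries(tr, fitSelection = "backbone")
  expect_equal(r$rmsd, rep(0, 5), tolerance = 1e-12)
})

test_that("tumbling leaves superposed internal motion untouched (same seed)", {
  ref <- generateReferenceStructure(12, 1, seed = 1)
  plain <- generateHarmonicTrajectory(ref, 0.04, nFrames = 50, tumbling = FALSE, seed = 4)
  tumbled <- generateHarmonicTrajectory(ref, 0.04, nFrames = 50, tumbling = TRUE, seed = 4)
  r1 <- rmsdSeries(plain, fitSelection = "all")
  r2 <- rmsdSeries(tumbled, fitSelection = "all")
  expect_equal(r1$rmsd, r2$rmsd, tolerance = 1e-6)
})

test_that("per-residue fluctuation amplitude is recovered as sqrt(3) sigma", {
  # parameter-recovery property: fit bias is O(6/(3N)) so use many atoms
  ref <- generateReferenceStructure(60, 2, seed = 1)
  tr <- generateHarmonicTrajectory(ref, 0.08, nFrames = 2000, seed = 6)
  p <- rmsfProfile(tr, fitSelection = "all", startFraction = 0)
  target <- sqrt(3) * 0.08
  # mean over residues, within 3 standard errors of the per-residue spread
  se <- sd(p$rmsf) / sqrt(nrow(p))
  expect_lt(abs(mean(p$rmsf) - target), max(3 * se, 0.02 * target))
})

test_that("cone ensembles match the closed-form order parameter", {
  v0 <- generateConeVectors(0, nFrames = 50, seed = 1)
  expect_equal(max(abs(sweep(v0$vectors, 2, v0$vectors[1, ]))), 0)
  expect_equal(v0$s2True, 1)
  expect_equal(coneS2(90), 0)
  expect_equal(coneS2(30), 0.6528845, tolerance = 1e-6)
  c30 <- generateConeVectors(30, nFrames = 20000, seed = 2)
  expect_equal(s2FromVectors(c30$vectors), 0.6529, tolerance = 0.02 / 0.6529)
  # monotone decreasing in the cone semi-angle
  expect_true(all(diff(coneS2(c(0, 15, 30, 60, 90))) < 0))
})

test_that("noise-free Michaelis-Menten data hit the half-saturation point", {
  d <- generateMMDataset(kmTrue = 10, kcatTrue = 100, enzymeConc = 0.01,
    substrateGrid = c(1, 5, 10, 50), noiseCV = 0, seed = 1)
  vmax <- attr(d, "vmaxTrue")
  expect_equal(d$velocity[d$substrate_mM == 10], vmax / 2)
  # direct evaluation at the d-glucose constants with Vmax scaled to 1
  d2 <- generateMMDataset(17.126, 87.844, enzymeConc = 1 / 87.844,
    substrateGrid = c(200), noiseCV = 0, seed = 1)
  expect_equal(d2$velocity, 200 / 217.126, tolerance = 1e-9)
  d3 <- generateMMDataset(10, 100, 0.01, c(1, 5, 10), noiseCV = 0.05,
    replicates = 3, seed = 1)
  expect_equal(nrow(d3), 9)
  expect_equal(as.vector(table(d3$substrate_mM)), rep(3, 3))
  expect_error(generateMMDataset(10, 100, 0.01, c(-1, 5), noiseCV = 0),
               "invalid spec")
})
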