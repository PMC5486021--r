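#' Idealized reference protein structure
#'
#' Builds a deterministic poly-alanine backbone (atoms N, H, CA, C, O per
#' residue; N-H bond 0.10 nm) arranged as a compressed helix, one helix
#' per chain, chains labeled A, B, ... and placed on a square grid so they
#' do not overlap. The geometry is chemically plausible — backbone amide
#' donors point along the helix axis toward the carbonyl acceptors four
#' residues back, so intra-chain hydrogen bonds exist — but it is an
#' idealized construct, not a homology model: any topology with named
#' backbone atoms suffices for the fluctuation statistics downstream.
#'
#' @param nResidues residues per chain (>= 2).
#' @param nChains number of chains (subunits), labeled A upward.
#' @param seed integer seed (reserved; the construction itself is
#'   deterministic, the seed is recorded for provenance).
#' @return a single-frame [Trajectory] (time 0 ps) holding the topology
#'   and reference coordinates in nm.
#' @examples
#' ref <- generateReferenceStructure(10, 1, seed = 1)
#' nAtoms(ref)     # 50: five atoms per residue
#' @export
generateReferenceStructure <- function(nResidues, nChains = 1L, seed = 1L) {
  if (!is.numeric(nResidues) || nResidues < 2)
    stop("invalid spec: nResidues must be >= 2")
  if (nChains < 1) stop("invalid spec: nChains must be >= 1")
  nResidues <- as.integer(nResidues); nChains <- as.integer(nChains)

  # helix parameters (nm / degrees): radius 0.23, rise 0.10, 100 deg/residue;
  # the reduced rise brings N-H(i)...O=C(i-4) inside the 0.35 nm cutoff
  radius <- 0.23; rise <- 0.10; twist <- 100 * pi / 180
  chainGap <- 3.0
  nSide <- ceiling(sqrt(nChains))

  rows <- vector("list", nChains)
  coordList <- vector("list", nChains)
  for (c in seq_len(nChains)) {
    i <- seq_len(nResidues)
    phi <- i * twist
    ca <- cbind(radius * cos(phi), radius * sin(phi), i * rise)
    # N toward the previous residue, C toward the next, O up the axis,
    # H down the axis (toward the carbonyl of residue i-4)
    dirPrev <- rbind(ca[1, ] - ca[2, ], ca[-nResidues, ] - ca[-1, ])
    dirPrev <- dirPrev / sqrt(rowSums(dirPrev^2))
    dirNext <- -rbind(dirPrev[-1, ], -(ca[nResidues, ] - ca[nResidues - 1, ]) /
                        sqrt(sum((ca[nResidues, ] - ca[nResidues - 1, ])^2)))
    nAt <- ca + 0.145 * dirPrev
    cAt <- ca + 0.152 * dirNext
    oAt <- cAt; oAt[, 3] <- oAt[, 3] + 0.123
    # amide H points at the i-4 carbonyl oxygen (ideal helical H-bond
    # geometry); for the first turn, down the helix axis
    hAt <- nAt; hAt[, 3] <- hAt[, 3] - 0.100
    if (nResidues > 4L) {
      i5 <- 5:nResidues
      hd <- oAt[i5 - 4L, , drop = FALSE] - nAt[i5, , drop = FALSE]
      hd <- hd / sqrt(rowSums(hd^2))
      hAt[i5, ] <- nAt[i5, , drop = FALSE] + 0.100 * hd
    }
    off <- c(((c - 1) %% nSide) * chainGap, ((c - 1) %/% nSide) * chainGap, 0)
    xyz <- matrix(NA_real_, nResidues * 5L, 3L)
    xyz[seq(1, by = 5, length.out = nResidues), ] <- nAt
    xyz[seq(2, by = 5, length.out = nResidues), ] <- hAt
    xyz[seq(3, by = 5, length.out = nResidues), ] <- ca
    xyz[seq(4, by = 5, length.out = nResidues), ] <- cAt
    xyz[seq(5, by = 5, length.out = nResidues), ] <- oAt
    coordList[[c]] <- sweep(xyz, 2, -off)
    rows[[c]] <- data.frame(
      name = rep(c("N", "H", "CA", "C", "O"), nResidues),
      resname = "ALA",
      resid = rep(seq_len(nResidues), each = 5L),
      chain = LETTERS[((c - 1L) %% 26L) + 1L],
      element = rep(c("N", "H", "C", "C", "O"), nResidues),
      stringsAsFactors = FALSE)
  }
  atomTable <- do.call(rbind, rows)
  atomTable$serial <- seq_len(nrow(atomTable))
  xyz <- do.call(rbind, coordList)
  top <- makeTopology(atomTable, xyz)
  new("Trajectory", coords = array(xyz, dim = c(nrow(xyz), 3L, 1L)),
      times = 0, topology = top)
}

#' Synthetic trajectory with prescribed harmonic fluctuations
#'
#' Each frame is the reference structure plus an independent Gaussian
#' displacement N(0, sigma_i^2) applied to every Cartesian coordinate of
#' every atom of residue i; optionally the whole frame is then tumbled by
#' a uniformly random rigid transform (rotation uniform on SO(3) via unit
#' quaternions, translation uniform in a +/-1 nm cube). Because the
#' displacement stream is drawn before any tumbling stream, turning
#' tumbling on or off leaves the internal displacements — and hence any
#' superposed analysis — unchanged for the same seed.
#'
#' The expected per-residue RMSF after superposition is `sqrt(3) * sigma_i`.
#'
#' @param reference a single-frame [Trajectory] (e.g. from
#'   [generateReferenceStructure()]).
#' @param sigma per-residue displacement scale, nm per coordinate: either
#'   one value for all residues or one value per residue (chain/residue
#'   order); all values >= 0.
#' @param nFrames number of frames (>= 2).
#' @param dt time step between stored frames, ps.
#' @param tumbling apply a random global rotation + translation per frame.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return a [Trajectory] of `nFrames` frames.
#' @export
generateHarmonicTrajectory <- function(reference, sigma, nFrames = 1000L,
                                       dt = 10, tumbling = FALSE, seed = 1L) {
  stopifnot(is(reference, "Trajectory"))
  if (nFrames < 2) stop("invalid spec: nFrames must be >= 2")
  nR <- nResidues(reference)
  if (length(sigma) == 1L) sigma <- rep(sigma, nR)
  if (length(sigma) != nR)
    stop(sprintf("invalid spec: sigma must have length 1 or %d", nR))
  if (any(sigma < 0) || any(!is.finite(sigma)))
    stop("invalid spec: sigma values must be finite and >= 0")
  nFrames <- as.integer(nFrames)

  a <- reference@topology@atoms
  res <- unique(a[, c("chain", "resid")])
  atomSigma <- sigma[match(paste(a$chain, a$resid), paste(res$chain, res$resid))]
  nA <- nrow(a)
  ref <- reference@coords[, , 1]

  set.seed(as.integer(seed))
  # displacements first, tumbling after: the two streams never interleave
  disp <- array(stats::rnorm(nA * 3L * nFrames, sd = atomSigma),
                dim = c(nA, 3L, nFrames))
  co <- array(ref, dim = c(nA, 3L, nFrames)) + disp
  if (tumbling) {
    for (f in seq_len(nFrames)) {
      R <- randomRotationMatrix()
      tr <- stats::runif(3, -1, 1)
      co[, , f] <- sweep(co[, , f] %*% t(R), 2, -tr)
    }
  }
  new("Trajectory", coords = co, times = dt * (seq_len(nFrames) - 1L),
      topology = reference@topology)
}

# Uniform random rotation on SO(3) from a normalized Gaussian quaternion.
randomRotationMatrix <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Unit vectors diffusing in a cone, with closed-form order parameter
#'
#' Draws unit vectors uniformly (by solid angle) within a cone of
#' semi-angle `theta0` about the z axis — the diffusion-in-a-cone model
#' whose generalized order parameter is known analytically:
#' \deqn{S^2 = [\cos\theta_0 (1+\cos\theta_0)/2]^2.}
#' This gives a ground-truth ensemble for validating the S^2 estimator:
#' `theta0 = 0` is a rigid bond (S^2 = 1), `theta0 = 90` gives S^2 = 0.
#'
#' @param theta0 cone semi-angle, degrees, in `[0, 90]`.
#' @param nFrames number of vectors to draw.
#' @param seed integer seed.
#' @return list with `vectors` (nFrames x 3 unit vectors) and `s2True`
#'   (the closed-form order parameter).
#' @export
generateConeVectors <- function(theta0, nFrames = 10000L, seed = 1L) {
  if (theta0 < 0 || theta0 > 90)
    stop("invalid spec: theta0 must be between 0 and 90 degrees")
  set.seed(as.integer(seed))
  c0 <- cos(theta0 * pi / 180)
  cosT <- stats::runif(nFrames, min = c0, max = 1)   # uniform in solid angle
  phi <- stats::runif(nFrames, 0, 2 * pi)
  sinT <- sqrt(pmax(0, 1 - cosT^2))
  v <- cbind(sinT * cos(phi), sinT * sin(phi), cosT)
  list(vectors = v, s2True = coneS2(theta0))
}

#' Closed-form order parameter of the diffusion-in-a-cone model
#' @param theta0 cone semi-angle, degrees.
#' @return S^2 value in `[0, 1]`.
#' @export
coneS2 <- function(theta0) {
  c0 <- cos(theta0 * pi / 180)
  (c0 * (1 + c0) / 2)^2
}

#' Synthetic Michaelis-Menten velocity dataset
#'
#' Velocities follow v = Vmax [S] / (Km + [S]) with Vmax = kcat [E]
#' (per-subunit enzyme concentration), plus additive Gaussian noise of
#' standard deviation `noiseCV * Vmax` — constant variance, the simplest
#' model consistent with replicate initial-rate assays.
#'
#' @param kmTrue Michaelis constant, mM.
#' @param kcatTrue turnover number, s^-1.
#' @param enzymeConc enzyme subunit concentration, uM.
#' @param substrateGrid substrate concentrations, mM, all > 0.
#' @param noiseCV noise SD as a fraction of Vmax (>= 0).
#' @param replicates rows per substrate level.
#' @param seed integer seed.
#' @return data.frame with columns `substrate_mM`, `velocity`, `replicate`
#'   and attributes `enzymeConc` (uM), `velocityUnit` ("uM/s"), `vmaxTrue`.
#' @examples
#' d <- generateMMDataset(10, 100, enzymeConc = 0.01,
#'                        substrateGrid = c(1, 5, 10, 50), noiseCV = 0)
#' d$velocity[d$substrate_mM == 10]  # half of Vmax = 0.5 uM/s
#' @export
generateMMDataset <- function(kmTrue, kcatTrue, enzymeConc,
                              substrateGrid, noiseCV = 0.02,
                              replicates = 1L, seed = 1L) {
  if (any(substrateGrid <= 0) || kmTrue <= 0 || enzymeConc <= 0)
    stop("invalid spec: concentrations must be > 0")
  if (noiseCV < 0) stop("invalid spec: noiseCV must be >= 0")
  set.seed(as.integer(seed))
  vmax <- kcatTrue * enzymeConc  # s^-1 * uM = uM/s
  s <- rep(substrateGrid, times = replicates)
  repIdx <- rep(seq_len(replicates), each = length(substrateGrid))
  v <- vmax * s / (kmTrue + s)
  if (noiseCV > 0) v <- v + stats::rnorm(length(s), sd = noiseCV * vmax)
  out <- data.frame(substrate_mM = s, velocity = v, replicate = repIdx)
  attr(out, "enzymeConc") <- enzymeConc
  attr(out, "velocityUnit") <- "uM/s"
  attr(out, "vmaxTrue") <- vmax
  out
}
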