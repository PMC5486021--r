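#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (determinant +1; the reflection branch of the
#' SVD solution is corrected) and translation minimizing the weighted sum
#' of squared deviations between `mobile` and `ref`. The fitted mobile
#' coordinates are `(mobile - wcm) %*% R + wcr` with `wcm`, `wcr` the
#' weighted centroids.
#'
#' @param mobile numeric n x 3 matrix.
#' @param ref numeric n x 3 matrix, same n.
#' @param weights optional non-negative weights (e.g. masses); default
#'   uniform.
#' @return list with `rotation` (3 x 3, acts on row vectors from the
#'   right), `translation` (so `fitted = mobile %*% rotation + translation`),
#'   `fitted` coordinates and weighted `rmsd` residual (same length unit as
#'   the input).
#' @export
kabschFit <- function(mobile, ref, weights = NULL) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  n <- nrow(mobile)
  if (n < 3L || nrow(ref) != n || ncol(mobile) != 3L || ncol(ref) != 3L)
    stop("superposition needs >= 3 points in two equally sized n x 3 sets")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  H <- crossprod(X * w, Y)            # 3x3 weighted cross-covariance
  sv <- svd(H)
  if (sv$d[2] < max(sv$d[1], 1e-12) * 1e-9)
    stop("degenerate geometry: points are (nearly) collinear, rotation is not unique")
  d <- sign(det(sv$u) * det(sv$v))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(X %*% R, 2, -cr)
  rmsd <- sqrt(sum(w * rowSums((fitted - sweep(Y, 2, -cr))^2)))
  list(rotation = R, translation = cr - cm %*% R, fitted = fitted, rmsd = rmsd)
}

# Fit every frame onto refCoords using the fit-selection atoms; returns the
# transformed full-coordinate array. Weights apply to the fit only.
superposeFrames <- function(co, refCoords, fitIdx, weights = NULL) {
  nF <- dim(co)[3]
  out <- co
  refSel <- refCoords[fitIdx, , drop = FALSE]
  for (f in seq_len(nF)) {
    fit <- kabschFit(co[fitIdx, , f], refSel, weights)
    out[, , f] <- sweep(co[, , f] %*% fit$rotation, 2,
                        as.numeric(-fit$translation))
  }
  out
}

# Iterated-mean superposition shared by RMSF, S2 and essential dynamics:
# fit all frames to the first frame of the window, take the mean structure,
# refit to that mean (`passes` times). Returns the fitted coordinates and
# the final mean so downstream identities (trace of the covariance equals
# the sum of squared RMSFs) hold exactly.
superposeToMean <- function(traj, fitSelection = "name CA", passes = 2L,
                            startFraction = 0, massWeighted = TRUE) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L)
    stop("fluctuations are undefined for a single frame")
  keep <- windowFrames(traj, startFraction)
  co <- traj@coords[, , keep, drop = FALSE]
  fitIdx <- resolveSelection(traj@topology, fitSelection)@indices
  w <- if (massWeighted) traj@topology@atoms$mass[fitIdx] else NULL
  ref <- co[, , 1]
  for (p in seq_len(passes)) {
    co <- superposeFrames(co, ref, fitIdx, w)
    ref <- apply(co, c(1, 2), mean)
  }
  list(coords = co, mean = ref, frames = keep, times = traj@times[keep],
       fitSelection = fitSelection, startFraction = startFraction)
}

# frame indices of the analysis window [startFraction, 1]
windowFrames <- function(traj, startFraction) {
  nF <- nFrames(traj)
  if (startFraction < 0 || startFraction >= 1)
    stop("start fraction must be in [0, 1)")
  from <- min(nF, floor(startFraction * nF) + 1L)
  seq.int(from, nF)
}

#' RMSD time series after least-squares superposition
#'
#' Each frame is rigidly fitted to the reference frame on the fit
#' selection (mass-weighted by default), and the root mean square
#' deviation is then evaluated, unweighted, over the measurement
#' selection. The standard presets are all-atom
#' (`measureSelection = "all"`) and backbone RMSD.
#'
#' @param traj a [Trajectory].
#' @param refFrame index of the reference frame (default 1).
#' @param fitSelection selection used for the superposition.
#' @param measureSelection selection the deviation is evaluated over.
#' @param massWeightedFit weight the fit by atomic mass (default TRUE);
#'   the measurement is always unweighted.
#' @param startFraction start of the analysis window as a fraction of the
#'   trajectory (default 0: the full trajectory).
#' @return data.frame with columns `time` (ps) and `rmsd` (nm).
#' @export
rmsdSeries <- function(traj, refFrame = 1L, fitSelection = "backbone",
                       measureSelection = fitSelection,
                       massWeightedFit = TRUE, startFraction = 0) {
  stopifnot(is(traj, "Trajectory"))
  fitIdx <- resolveSelection(traj@topology, fitSelection)@indices
  measIdx <- resolveSelection(traj@topology, measureSelection)@indices
  keep <- windowFrames(traj, startFraction)
  ref <- traj@coords[, , refFrame]
  w <- if (massWeightedFit) traj@topology@atoms$mass[fitIdx] else NULL
  vals <- vapply(keep, function(f) {
    fit <- kabschFit(traj@coords[fitIdx, , f], ref[fitIdx, , drop = FALSE], w)
    moved <- sweep(traj@coords[measIdx, , f] %*% fit$rotation, 2,
                   as.numeric(-fit$translation))
    sqrt(mean(rowSums((moved - ref[measIdx, , drop = FALSE])^2)))
  }, numeric(1))
  data.frame(time = traj@times[keep], rmsd = vals)
}

#' Radius of gyration time series
#'
#' Mass-weighted RMS distance of the selected atoms from their center of
#' mass, per frame: `Rg = sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`.
#'
#' @inheritParams rmsdSeries
#' @param selection atoms to include (default `"all"`).
#' @return data.frame with columns `time` (ps) and `rg` (nm).
#' @export
radiusOfGyrationSeries <- function(traj, selection = "all", startFraction = 0) {
  stopifnot(is(traj, "Trajectory"))
  idx <- resolveSelection(traj@topology, selection)@indices
  m <- traj@topology@atoms$mass[idx]
  M <- sum(m)
  if (M <= 0) stop("total mass of the selection must be positive")
  keep <- windowFrames(traj, startFraction)
  vals <- vapply(keep, function(f) {
    x <- traj@coords[idx, , f, drop = FALSE][, , 1, drop = TRUE]
    x <- matrix(x, ncol = 3)
    com <- colSums(x * (m / M))
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / M)
  }, numeric(1))
  data.frame(time = traj@times[keep], rg = vals)
}

#' Per-residue RMSF profile
#'
#' Root mean square fluctuation of each selected atom about its
#' time-average position, over the equilibrium window. Frames are
#' superposed to the iterated mean structure (two passes by default):
#' fitting to the mean, rather than to frame 1, is the estimator implied
#' by a fluctuation about the time average and avoids the inflation that
#' frame-referencing introduces.
#'
#' @inheritParams rmsdSeries
#' @param selection per-residue atoms to report (default `"name CA"`, one
#'   atom per residue).
#' @param nMeanIterations fit/mean passes (default 2).
#' @param startFraction window start; default 0.5, the equilibrium half.
#' @param superposed optionally a precomputed result of the internal
#'   iterated-mean superposition, reused so that covariance/RMSF
#'   identities hold exactly across analyses.
#' @return data.frame with columns `chain`, `resid`, `rmsf` (nm).
#' @export
rmsfProfile <- function(traj, selection = "name CA",
                        fitSelection = "name CA", nMeanIterations = 2L,
                        startFraction = 0.5, superposed = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L)
    stop("fluctuations are undefined for a single frame")
  sp <- superposed %||% superposeToMean(traj, fitSelection,
    passes = nMeanIterations, startFraction = startFraction)
  idx <- resolveSelection(traj@topology, selection)@indices
  nW <- dim(sp$coords)[3]
  dx <- sp$coords[idx, , , drop = FALSE] -
    array(sp$mean[idx, , drop = FALSE], dim = c(length(idx), 3, nW))
  msf <- apply(dx^2, 1, sum) / nW   # mean over frames of |r - <r>|^2
  a <- traj@topology@atoms[idx, ]
  data.frame(chain = a$chain, resid = a$resid, rmsf = sqrt(msf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert an RMSF profile to crystallographic B-factors
#'
#' Applies the isotropic harmonic relation `B = 8 pi^2 <u^2> / 3` with the
#' mean-square displacement taken as RMSF^2. RMSF is supplied in nm (the
#' trajectory unit) and converted to Angstrom internally, so B is in the
#' crystallographic convention of Angstrom^2. The mapping is exactly
#' invertible via [rmsfFromBfactor()].
#'
#' @param rmsfNm numeric vector or an [rmsfProfile()] data.frame; RMSF in nm.
#' @return same shape with B-factors in Angstrom^2 (column `bfactor` when a
#'   profile is given).
#' @export
bfactorFromRmsf <- function(rmsfNm) {
  if (is.data.frame(rmsfNm)) {
    rmsfNm$bfactor <- bfactorFromRmsf(rmsfNm$rmsf)
    return(rmsfNm)
  }
  if (any(rmsfNm < 0)) stop("RMSF must be non-negative")
  8 * pi^2 * (rmsfNm * 10)^2 / 3
}

#' @rdname bfactorFromRmsf
#' @param bfactorA2 B-factors, Angstrom^2.
#' @export
rmsfFromBfactor <- function(bfactorA2) {
  if (any(bfactorA2 < 0)) stop("B-factor must be non-negative")
  sqrt(3 * bfactorA2 / (8 * pi^2)) / 10
}
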