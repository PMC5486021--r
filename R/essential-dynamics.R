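#' C-alpha covariance matrix of positional fluctuations
#'
#' Frames of the analysis window are superposed onto the iterated mean
#' structure; the covariance of the concatenated selected coordinates
#' (3N-dimensional) is then `C = <dx dx^T>` with `dx = x - <x>` and the
#' plain 1/F normalization, so `trace(C)` equals the sum of squared RMSFs
#' of the same selection over the same window exactly. Covariance is
#' unweighted: for an all-C-alpha selection mass weighting is a constant
#' factor.
#'
#' @param traj a [Trajectory] with >= 2 frames.
#' @param selection atoms entering the covariance (default `"name CA"`).
#' @param fitSelection selection used for the superposition.
#' @param startFraction window start (default 0.5, the equilibrium half).
#' @param superposed optional precomputed superposition (shared across
#'   analyses so cross-identities hold exactly).
#' @return symmetric 3N x 3N matrix (nm^2) with attributes `meanCoords`
#'   (N x 3), `selection`, `fitSelection`, `startFraction`.
#' @export
covarianceMatrix <- function(traj, selection = "name CA",
                             fitSelection = selection, startFraction = 0.5,
                             superposed = NULL) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) < 2L) stop("covariance needs at least 2 frames")
  sp <- superposed %||% superposeToMean(traj, fitSelection,
    startFraction = startFraction)
  idx <- resolveSelection(traj@topology, selection)@indices
  nW <- dim(sp$coords)[3]
  # F x 3N matrix, coordinates ordered x1 y1 z1 x2 ...
  X <- t(apply(sp$coords[idx, , , drop = FALSE], 3, function(m) as.numeric(t(m))))
  mu <- as.numeric(t(sp$mean[idx, , drop = FALSE]))
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nW
  C <- (C + t(C)) / 2
  attr(C, "meanCoords") <- sp$mean[idx, , drop = FALSE]
  attr(C, "selection") <- if (is(selection, "AtomSelection"))
    selection@expression else selection
  attr(C, "fitSelection") <- sp$fitSelection
  attr(C, "startFraction") <- sp$startFraction
  C
}

#' Essential-dynamics eigendecomposition
#'
#' Diagonalizes a (symmetric) covariance matrix into descending
#' eigenvalues and orthonormal eigenvectors; eigenvalues are the amounts
#' of motion along the collective directions the eigenvectors describe.
#' Each eigenvector's sign is fixed so its largest-magnitude component is
#' positive, making projections reproducible. Tiny negative eigenvalues
#' from round-off are clipped to zero.
#'
#' @param C covariance matrix from [covarianceMatrix()] (any symmetric
#'   matrix is accepted; asymmetry beyond 1e-8 is an error).
#' @return an [EigenSystem].
#' @export
eigenDecompose <- function(C) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8)
    stop("covariance matrix must be symmetric")
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-10))
    warning("covariance has eigenvalues below -1e-10; clipping")
  vals <- pmax(vals, 0)
  vecs <- e$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  tot <- sum(vals)
  frac <- if (tot > 0) vals / tot else rep(0, length(vals))
  mc <- attr(C, "meanCoords")
  new("EigenSystem", values = vals, vectors = vecs,
      varianceFraction = frac, cumulativeFraction = cumsum(frac),
      meanCoords = if (is.null(mc)) matrix(numeric(0), 0, 3) else mc,
      selection = attr(C, "selection") %||% "name CA",
      fitSelection = attr(C, "fitSelection") %||% "name CA",
      startFraction = attr(C, "startFraction") %||% 0.5)
}

#' Project a trajectory onto essential-dynamics modes
#'
#' Recomputes the same superposition the eigensystem was built from and
#' projects each frame's displacement from the mean onto the first `k`
#' eigenvectors: `p_i(t) = v_i . (x(t) - <x>)`. Over the same window the
#' sample variance (1/F) of `p_i` equals the eigenvalue `lambda_i` and
#' projections of distinct modes are uncorrelated.
#'
#' @param traj the [Trajectory] the eigensystem came from.
#' @param es an [EigenSystem].
#' @param k number of modes (<= 3N).
#' @param superposed optional precomputed superposition.
#' @return data.frame with `time` and columns `p1 ... pk` (nm).
#' @export
projectTrajectory <- function(traj, es, k = 2L, superposed = NULL) {
  stopifnot(is(traj, "Trajectory"), is(es, "EigenSystem"))
  if (k < 1L || k > length(es@values))
    stop(sprintf("k must be in 1..%d", length(es@values)))
  sp <- superposed %||% superposeToMean(traj, es@fitSelection,
    startFraction = es@startFraction)
  idx <- resolveSelection(traj@topology, es@selection)@indices
  X <- t(apply(sp$coords[idx, , , drop = FALSE], 3, function(m) as.numeric(t(m))))
  mu <- as.numeric(t(sp$mean[idx, , drop = FALSE]))
  P <- sweep(X, 2, mu) %*% es@vectors[, seq_len(k), drop = FALSE]
  out <- data.frame(time = sp$times, P)
  names(out) <- c("time", paste0("p", seq_len(k)))
  out
}

#' Dynamic cross-correlation map of residue motions
#'
#' Normalized covariance of per-residue displacement vectors over the
#' window: `M_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`, in
#' `[-1, 1]`; positive for correlated, negative for anti-correlated
#' motion. A residue with zero variance gets a zero row/column (unit
#' diagonal) and a warning.
#'
#' @inheritParams covarianceMatrix
#' @return symmetric N x N matrix with unit diagonal; row/column names are
#'   `chain:resid` labels.
#' @export
correlationMap <- function(traj, selection = "name CA",
                           fitSelection = selection, startFraction = 0.5,
                           superposed = NULL) {
  sp <- superposed %||% superposeToMean(traj, fitSelection,
    startFraction = startFraction)
  idx <- resolveSelection(traj@topology, selection)@indices
  nW <- dim(sp$coords)[3]
  n <- length(idx)
  D <- sp$coords[idx, , , drop = FALSE] -
    array(sp$mean[idx, , drop = FALSE], dim = c(n, 3, nW))
  # <dr_i . dr_j> = sum over xyz of per-coordinate covariances
  G <- matrix(0, n, n)
  for (d in 1:3) G <- G + tcrossprod(matrix(D[, d, ], nrow = n)) / nW
  v <- diag(G)
  zero <- v <= 0
  if (any(zero))
    warning(sprintf("%d residue(s) with zero variance; correlations set to 0",
                    sum(zero)))
  s <- sqrt(ifelse(zero, 1, v))
  M <- G / outer(s, s)
  M[zero, ] <- 0; M[, zero] <- 0
  diag(M) <- 1
  M <- (M + t(M)) / 2
  a <- traj@topology@atoms
  labels <- paste0(a$chain[idx], ":", a$resid[idx])
  dimnames(M) <- list(labels, labels)
  M
}

#' Cumulative variance captured by leading modes
#'
#' Percent of total positional fluctuation explained by the first k
#' eigenvectors, for each requested k — the quantity used to judge
#' whether the motion is confined to a low-dimensional essential
#' subspace.
#'
#' @param es an [EigenSystem].
#' @param ks integer vector of mode counts (default `c(2, 20)`).
#' @return named numeric vector of percentages.
#' @export
cumulativeVarianceReport <- function(es, ks = c(2L, 20L)) {
  stopifnot(is(es, "EigenSystem"))
  ks <- pmin(as.integer(ks), length(es@values))
  out <- 100 * es@cumulativeFraction[ks]
  names(out) <- paste0("k", ks)
  out
}
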