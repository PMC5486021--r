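#' Lipari-Szabo generalized order parameters for amide N-H vectors
#'
#' Measures the spatial restriction of each backbone amide N-H bond
#' vector's internal motion. Global tumbling is removed first by
#' superposing every frame of the window onto the iterated mean structure
#' over `fitSelection`; the order parameter is then the ensemble
#' second-moment estimator over unit bond vectors u:
#' \deqn{S^2 = \frac{3}{2}\left(\langle u_x^2\rangle^2 +
#'   \langle u_y^2\rangle^2 + \langle u_z^2\rangle^2 +
#'   2\langle u_x u_y\rangle^2 + 2\langle u_x u_z\rangle^2 +
#'   2\langle u_y u_z\rangle^2\right) - \frac{1}{2}}
#' which is the infinite-sampling plateau of the P2 orientational
#' autocorrelation function. S^2 = 1 for a rigid bond vector, 0 for
#' isotropic disorder. An autocorrelation-plateau estimator is available
#' as a validation mode via [s2FromVectors()].
#'
#' Prolines and each chain's first residue carry no amide hydrogen and are
#' excluded by the `"amide-NH"` selection.
#'
#' @param traj a [Trajectory].
#' @param fitSelection selection used to remove global tumbling.
#' @param startFraction window start (default 0.5, the equilibrium half).
#' @param superposed optional precomputed iterated-mean superposition.
#' @return data.frame with columns `chain`, `resid`, `s2`. Values outside
#'   `[0, 1]` by more than 1e-6 are flagged with a warning (they indicate a
#'   numerical problem; small negative excursions are sampling noise).
#' @export
s2Profile <- function(traj, fitSelection = "name CA", startFraction = 0.5,
                      superposed = NULL) {
  stopifnot(is(traj, "Trajectory"))
  pairs <- selectAtoms(traj@topology, "amide-NH")@pairs
  if (!nrow(pairs)) stop("no amide N-H pairs in topology")
  sp <- superposed %||% superposeToMean(traj, fitSelection,
    startFraction = startFraction)
  nW <- dim(sp$coords)[3]
  if (nW < 100L)
    warning(sprintf("only %d frames in window; S^2 estimates will be noisy", nW))
  s2 <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    v <- t(sp$coords[pairs[k, "H"], , ] - sp$coords[pairs[k, "N"], , ])
    s2[k] <- s2FromVectors(v)
  }
  if (any(s2 < -1e-6 | s2 > 1 + 1e-6))
    warning("S^2 value(s) outside [0, 1] beyond sampling tolerance")
  a <- traj@topology@atoms
  data.frame(chain = a$chain[pairs[, "N"]], resid = a$resid[pairs[, "N"]],
             s2 = s2)
}

#' Ensemble order parameter of a bond-vector time series
#'
#' The second-moment S^2 estimator applied directly to a set of bond
#' vectors (normalized internally). Exposed so closed-form ensembles such
#' as [generateConeVectors()] can be scored without a trajectory.
#'
#' @param vectors numeric F x 3 matrix of bond vectors.
#' @return S^2 estimate.
#' @export
s2FromVectors <- function(vectors) {
  v <- as.matrix(vectors)
  n2 <- rowSums(v^2)
  if (any(n2 <= 0)) stop("zero-length bond vector")
  u <- v / sqrt(n2)
  m <- crossprod(u) / nrow(u)      # second-moment matrix <u u^T>
  1.5 * (sum(diag(m)^2) + 2 * (m[1, 2]^2 + m[1, 3]^2 + m[2, 3]^2)) - 0.5
}

#' P2 autocorrelation-plateau estimate of S^2 (validation mode)
#'
#' Computes C2(t) = <P2(u(s) . u(s+t))> and averages the long-time tail
#' (last `tailFraction` of the lags up to `maxLagFraction` of the series).
#' For a stationary ensemble this converges to the same plateau as the
#' second-moment formula; it is provided as an independent check, not as
#' the primary estimator.
#'
#' @param vectors numeric F x 3 bond-vector series.
#' @param maxLagFraction largest lag, as a fraction of the series length.
#' @param tailFraction fraction of the retained lags averaged as plateau.
#' @return plateau estimate of S^2.
#' @export
s2AutocorrelationPlateau <- function(vectors, maxLagFraction = 0.5,
                                     tailFraction = 0.5) {
  u <- as.matrix(vectors)
  u <- u / sqrt(rowSums(u^2))
  nF <- nrow(u)
  maxLag <- max(2L, floor(maxLagFraction * nF))
  c2 <- vapply(seq_len(maxLag), function(lag) {
    dots <- rowSums(u[seq_len(nF - lag), , drop = FALSE] *
                    u[seq_len(nF - lag) + lag, , drop = FALSE])
    mean(1.5 * dots^2 - 0.5)
  }, numeric(1))
  tail <- c2[seq.int(ceiling((1 - tailFraction) * maxLag) + 1L, maxLag)]
  mean(tail)
}

#' Summary of an order-parameter profile
#'
#' Unweighted mean S^2 over all residues, plus means over named residue
#' regions (e.g. a substrate-binding segment).
#'
#' @param profile an [s2Profile()] data.frame.
#' @param regions optional named list of `c(firstResid, lastResid)` pairs
#'   (1-based residue numbering, applied in every chain).
#' @return list with `mean` and, when regions are given, `regionMeans`.
#' @examples
#' p <- data.frame(chain = "A", resid = 2:3, s2 = c(0.8, 0.9))
#' s2Summary(p)$mean  # 0.85
#' @export
s2Summary <- function(profile, regions = NULL) {
  if (!nrow(profile)) stop("empty S^2 profile")
  out <- list(mean = mean(profile$s2))
  if (!is.null(regions)) {
    out$regionMeans <- vapply(regions, function(r) {
      sel <- profile$resid >= r[1] & profile$resid <= r[2]
      if (!any(sel)) return(NA_real_)
      mean(profile$s2[sel])
    }, numeric(1))
  }
  out
}
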