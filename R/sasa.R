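#' Shrake-Rupley SASA parameters
#'
#' Probe radius 0.14 nm (the standard water probe) and 960 test points per
#' atom by default. Van der Waals radii come from the Bondi set (nm):
#' H 0.120, C 0.170, N 0.155, O 0.152, S 0.180, P 0.180. Sphere points are
#' a deterministic Fibonacci lattice, so results are exactly reproducible
#' and refine smoothly as `nSpherePoints` grows.
#'
#' @param probeRadius solvent probe radius, nm (>= 0).
#' @param nSpherePoints test points per atom (>= 32).
#' @param radiiSet named vector mapping element to vdW radius, nm.
#' @return parameter list for [sasaFrame()] / [sasaSeries()].
#' @export
sasaParams <- function(probeRadius = 0.14, nSpherePoints = 960L,
                       radiiSet = .BONDI_RADII_NM) {
  if (probeRadius < 0) stop("probe radius must be >= 0")
  if (nSpherePoints < 32) stop("need at least 32 sphere points")
  list(probeRadius = probeRadius, nSpherePoints = as.integer(nSpherePoints),
       radiiSet = radiiSet)
}

# Deterministic quasi-uniform unit-sphere points (Fibonacci lattice).
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of one frame
#'
#' Shrake-Rupley rejection sampling: each atom is covered with
#' quasi-uniform points at radius `r_i + probe`; the accessible fraction
#' is the share of points inside no neighbouring expanded sphere, and the
#' atom's area is that fraction of `4 pi (r_i + probe)^2`.
#'
#' @param frameCoords numeric A x 3 matrix, nm.
#' @param topology a [Topology]; every element must be present in the
#'   radii set.
#' @param params a [sasaParams()] list.
#' @return numeric vector of per-atom accessible areas, nm^2.
#' @export
sasaFrame <- function(frameCoords, topology, params = sasaParams()) {
  stopifnot(is(topology, "Topology"))
  el <- topology@atoms$element
  r <- params$radiiSet[el]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  pts <- fibonacciSphere(params$nSpherePoints)
  as.numeric(sasa_frame_cpp(frameCoords, as.numeric(r),
                            params$probeRadius, pts))
}

#' Total SASA time series
#'
#' Sum of per-atom Shrake-Rupley areas for every frame in the window.
#'
#' @param traj a [Trajectory].
#' @param params a [sasaParams()] list.
#' @param startFraction analysis window start (default 0: full trajectory).
#' @return data.frame with columns `time` (ps) and `sasa` (nm^2).
#' @export
sasaSeries <- function(traj, params = sasaParams(), startFraction = 0) {
  stopifnot(is(traj, "Trajectory"))
  keep <- windowFrames(traj, startFraction)
  el <- traj@topology@atoms$element
  r <- params$radiiSet[el]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  pts <- fibonacciSphere(params$nSpherePoints)
  vals <- vapply(keep, function(f)
    sum(sasa_frame_cpp(traj@coords[, , f], as.numeric(r),
                       params$probeRadius, pts)), numeric(1))
  data.frame(time = traj@times[keep], sasa = vals)
}
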