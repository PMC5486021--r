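#' Geometric hydrogen-bond criterion
#'
#' The default criterion counts a donor-H / acceptor contact as a hydrogen
#' bond when the donor-acceptor distance is at most 0.35 nm and the
#' H-donor-acceptor angle (at the donor) is at most 30 degrees — the
#' standard geometric definition used by MD analysis suites. Note the
#' angle convention: some tools use the donor-H-acceptor angle instead;
#' here the angle is at the donor.
#'
#' Donors and acceptors are restricted to N and O; a donor must carry at
#' least one attached hydrogen. Heavy-atom pairs closer than
#' `covalentCutoff` are treated as covalently bonded and never reported.
#'
#' @param maxDonorAcceptorDist donor-acceptor distance cutoff, nm (> 0).
#' @param maxHDonorAcceptorAngle H-donor-acceptor angle cutoff, degrees,
#'   in (0, 180].
#' @param covalentCutoff distance below which a pair is covalent, nm.
#' @return a named list used by [detectHBonds()] and [hbondSeries()].
#' @export
hbondCriterion <- function(maxDonorAcceptorDist = 0.35,
                           maxHDonorAcceptorAngle = 30,
                           covalentCutoff = 0.17) {
  if (maxDonorAcceptorDist <= 0) stop("distance cutoff must be > 0")
  if (maxHDonorAcceptorAngle <= 0 || maxHDonorAcceptorAngle > 180)
    stop("angle cutoff must be in (0, 180] degrees")
  list(maxDonorAcceptorDist = maxDonorAcceptorDist,
       maxHDonorAcceptorAngle = maxHDonorAcceptorAngle,
       covalentCutoff = covalentCutoff)
}

# donor-H pairs and acceptor candidates from the topology flags; a polar
# topology with no hydrogens at all cannot support the criterion
hbondParticipants <- function(topology) {
  a <- topology@atoms
  polar <- a$element %in% c("N", "O")
  hIdx <- which(a$element == "H")
  if (any(polar) && !length(hIdx))
    stop(paste("topology has no hydrogens: the geometric hydrogen-bond",
               "criterion is hydrogen-dependent; supply a structure with",
               "explicit polar hydrogens"))
  heavyOfH <- topology@hAttach[hIdx]
  keep <- polar[heavyOfH]
  list(donors = heavyOfH[keep], hydrogens = hIdx[keep],
       acceptors = which(polar))
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion to every donor-H pair against every
#' N/O acceptor, using a cell-list spatial grid so only atom pairs within
#' the distance cutoff are examined. Each (donor, hydrogen, acceptor)
#' triple is reported once.
#'
#' @param frameCoords numeric A x 3 coordinate matrix, nm.
#' @param topology a [Topology] with hydrogens attached.
#' @param criterion a [hbondCriterion()] list.
#' @return integer matrix with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices), one row per bond.
#' @export
detectHBonds <- function(frameCoords, topology, criterion = hbondCriterion()) {
  stopifnot(is(topology, "Topology"))
  pp <- hbondParticipants(topology)
  detect_hbonds_cpp(frameCoords, as.integer(pp$donors),
                    as.integer(pp$hydrogens), as.integer(pp$acceptors),
                    criterion$maxDonorAcceptorDist,
                    criterion$maxHDonorAcceptorAngle,
                    criterion$covalentCutoff)
}

#' Hydrogen-bond count time series
#'
#' Number of intra-protein hydrogen bonds per frame under the geometric
#' criterion.
#'
#' @param traj a [Trajectory].
#' @param criterion a [hbondCriterion()] list.
#' @param startFraction analysis window start (default 0: full trajectory).
#' @return data.frame with columns `time` (ps) and `count`.
#' @export
hbondSeries <- function(traj, criterion = hbondCriterion(), startFraction = 0) {
  stopifnot(is(traj, "Trajectory"))
  keep <- windowFrames(traj, startFraction)
  pp <- hbondParticipants(traj@topology)
  counts <- vapply(keep, function(f)
    nrow(detect_hbonds_cpp(traj@coords[, , f], as.integer(pp$donors),
      as.integer(pp$hydrogens), as.integer(pp$acceptors),
      criterion$maxDonorAcceptorDist, criterion$maxHDonorAcceptorAngle,
      criterion$covalentCutoff)), integer(1))
  data.frame(time = traj@times[keep], count = counts)
}
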