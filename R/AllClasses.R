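#' @useDynLib protdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Topology of a molecular system
#'
#' Holds the per-atom annotation shared by every frame of a trajectory:
#' serial number, atom name, residue name and number, chain identifier,
#' element, and atomic mass. Hydrogen atoms carry an attachment to exactly
#' one heavy atom (resolved by distance when reading coordinates), which
#' the hydrogen-bond detector and the amide N-H selection rely on.
#'
#' @slot atoms data.frame with columns `serial` (integer), `name`
#'   (character), `resname` (character), `resid` (integer), `chain`
#'   (character), `element` (character), `mass` (numeric, unified atomic
#'   mass units).
#' @slot hAttach integer vector, one entry per atom: for a hydrogen, the
#'   row index of its bonded heavy atom; `NA` for heavy atoms.
#'
#' @seealso [readPDBTrajectory()], [selectAtoms()], [generateReferenceStructure()]
#' @export
setClass("Topology",
  representation(atoms = "data.frame", hAttach = "integer"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "resname", "resid", "chain", "element", "mass")
  if (!all(need %in% names(a)))
    return(paste("atoms table must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0L) return("topology has no atoms")
  if (any(!is.finite(a$mass)) || any(a$mass <= 0))
    return("every atom must have positive finite mass")
  if (length(object@hAttach) != nrow(a))
    return("hAttach must have one entry per atom")
  isH <- a$element == "H"
  if (any(is.na(object@hAttach[isH])))
    return("every hydrogen must be attached to exactly one heavy atom")
  if (any(!is.na(object@hAttach[!isH])))
    return("hAttach must be NA for heavy atoms")
  att <- object@hAttach[isH]
  if (length(att) && (any(att < 1L) || any(att > nrow(a)) || any(isH[att])))
    return("hydrogen attachments must point to heavy atoms in range")
  # residue numbers non-decreasing within each chain
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    if (is.unsorted(r)) return(sprintf("residue numbers decrease within chain %s", ch))
  }
  TRUE
})

#' Coordinate trajectory
#'
#' A stack of frames over one [Topology]. Coordinates are stored in
#' nanometres as an `A x 3 x F` array (atoms, xyz, frames); frame times
#' are in picoseconds and strictly increasing.
#'
#' @slot coords numeric array, dim `c(nAtoms, 3, nFrames)`, nm.
#' @slot times numeric vector of frame times, ps, strictly increasing.
#' @slot topology the [Topology] the coordinates refer to.
#'
#' @seealso [readPDBTrajectory()], [generateHarmonicTrajectory()]
#' @export
setClass("Trajectory",
  representation(coords = "array", times = "numeric", topology = "Topology"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an A x 3 x F array")
  if (d[3] < 1L) return("trajectory needs at least one frame")
  if (d[1] != nrow(object@topology@atoms))
    return("coordinate atom count does not match topology")
  if (any(!is.finite(object@coords)))
    return("coordinates must be finite")
  if (length(object@times) != d[3])
    return("times must have one entry per frame")
  if (d[3] > 1L && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  TRUE
})

#' Resolved atom selection
#'
#' The result of evaluating a selection expression against a [Topology]:
#' a sorted, unique, in-bounds atom index list. For the `"amide-NH"`
#' expression the paired (N, H) indices are carried in `pairs`, one row
#' per amide, ordered by chain then residue.
#'
#' @slot expression the selection expression that was evaluated.
#' @slot indices sorted integer atom indices.
#' @slot pairs integer matrix with columns `N`, `H` (zero rows unless the
#'   expression was `"amide-NH"`).
#' @seealso [selectAtoms()]
#' @export
setClass("AtomSelection",
  representation(expression = "character", indices = "integer", pairs = "matrix"))

setValidity("AtomSelection", function(object) {
  i <- object@indices
  if (any(duplicated(i))) return("selection indices must be unique")
  if (is.unsorted(i)) return("selection indices must be sorted")
  if (length(i) && (min(i) < 1L)) return("selection indices out of bounds")
  TRUE
})

#' Eigensystem of a C-alpha covariance matrix
#'
#' Essential-dynamics decomposition: eigenvalues in descending order
#' (nm^2), orthonormal eigenvectors (columns, length 3N), the fraction of
#' total positional variance carried by each mode, and its cumulative sum.
#' The mean structure and window the covariance was computed over are kept
#' so projections reuse exactly the same superposition.
#'
#' @slot values numeric eigenvalues, descending, nm^2.
#' @slot vectors numeric matrix, one orthonormal eigenvector per column.
#' @slot varianceFraction numeric, `values / sum(values)`.
#' @slot cumulativeFraction numeric, running sum of `varianceFraction`.
#' @slot meanCoords numeric matrix N x 3: window-mean selected coordinates.
#' @slot selection character selection expression the modes refer to.
#' @slot fitSelection character selection used for superposition.
#' @slot startFraction numeric window start used (fraction of frames).
#' @seealso [eigenDecompose()], [projectTrajectory()]
#' @export
setClass("EigenSystem",
  representation(values = "numeric", vectors = "matrix",
    varianceFraction = "numeric", cumulativeFraction = "numeric",
    meanCoords = "matrix", selection = "character",
    fitSelection = "character", startFraction = "numeric"))

setValidity("EigenSystem", function(object) {
  v <- object@values
  if (is.unsorted(rev(v))) return("eigenvalues must be in descending order")
  if (any(v < -1e-10)) return("eigenvalues must be non-negative up to round-off")
  if (sum(v) > 0) {
    if (abs(sum(object@varianceFraction) - 1) > 1e-9)
      return("variance fractions must sum to 1")
    cf <- object@cumulativeFraction
    if (any(diff(cf) < -1e-12)) return("cumulative fractions must be non-decreasing")
    if (abs(cf[length(cf)] - 1) > 1e-9) return("cumulative fraction must end at 1")
  }
  if (ncol(object@vectors) != length(v))
    return("one eigenvector per eigenvalue required")
  TRUE
})

#' Michaelis-Menten fit result
#'
#' Parameters of the steady-state fit v = Vmax [S] / (Km + [S]) with
#' standard errors from the Jacobian at the optimum; the turnover number
#' kcat = Vmax / [E] (per subunit) and the catalytic efficiency kcat/Km
#' are derived when the enzyme concentration is supplied.
#'
#' @slot km Michaelis constant, mM.
#' @slot kmSE standard error of `km`.
#' @slot vmax limiting velocity, in the velocity unit of the data.
#' @slot vmaxSE standard error of `vmax`.
#' @slot kcat turnover number, s^-1 (`NA` if no enzyme concentration).
#' @slot kcatSE standard error of `kcat`.
#' @slot efficiency catalytic efficiency kcat/Km, mM^-1 s^-1.
#' @slot enzymeConc enzyme (subunit) concentration used, uM.
#' @slot velocityUnit unit tag carried from the dataset.
#' @slot converged logical convergence flag.
#' @slot rss residual sum of squares.
#' @seealso [fitMichaelisMenten()]
#' @export
setClass("KineticsFit",
  representation(km = "numeric", kmSE = "numeric", vmax = "numeric",
    vmaxSE = "numeric", kcat = "numeric", kcatSE = "numeric",
    efficiency = "numeric", enzymeConc = "numeric",
    velocityUnit = "character", converged = "logical", rss = "numeric"))

setValidity("KineticsFit", function(object) {
  if (isTRUE(object@converged) && (object@km <= 0 || object@vmax <= 0))
    return("converged fit must have positive Km and Vmax")
  TRUE
})
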