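#' @rdname Trajectory-class
#' @param x,object a [Trajectory] or [Topology].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname Topology-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Topology-class
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname Topology-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Trajectory-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname Trajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname Trajectory-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname EigenSystem-class
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))

#' @rdname EigenSystem-class
#' @export
setGeneric("eigenVectors", function(x) standardGeneric("eigenVectors"))

#' @rdname EigenSystem-class
#' @export
setGeneric("varianceFraction", function(x) standardGeneric("varianceFraction"))

#' @rdname EigenSystem-class
#' @export
setGeneric("cumulativeFraction", function(x) standardGeneric("cumulativeFraction"))

setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
setMethod("nResidues", "Topology",
  function(x) nrow(unique(x@atoms[, c("chain", "resid")])))
setMethod("nResidues", "Trajectory", function(x) nResidues(x@topology))
setMethod("atoms", "Topology", function(x) x@atoms)
setMethod("atoms", "Trajectory", function(x) x@topology@atoms)
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
setMethod("coords", "Trajectory", function(x) x@coords)
setMethod("frameTimes", "Trajectory", function(x) x@times)
setMethod("topology", "Trajectory", function(x) x@topology)

setMethod("eigenValues", "EigenSystem", function(x) x@values)
setMethod("eigenVectors", "EigenSystem", function(x) x@vectors)
setMethod("varianceFraction", "EigenSystem", function(x) x@varianceFraction)
setMethod("cumulativeFraction", "EigenSystem", function(x) x@cumulativeFraction)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat(sprintf("Topology: %d atoms, %d residues, %d chain(s) [%s]\n",
    nrow(a), nResidues(object), length(unique(a$chain)),
    paste(unique(a$chain), collapse = "")))
  cat(sprintf("  elements: %s; %d hydrogens attached\n",
    paste(sort(unique(a$element)), collapse = " "), sum(a$element == "H")))
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d frames x %d atoms (nm)\n", d[3], d[1]))
  cat(sprintf("  time %g .. %g ps\n", object@times[1], object@times[d[3]]))
  show(object@topology)
})

setMethod("show", "AtomSelection", function(object) {
  cat(sprintf("AtomSelection \"%s\": %d atoms", object@expression,
    length(object@indices)))
  if (nrow(object@pairs)) cat(sprintf(" (%d N-H pairs)", nrow(object@pairs)))
  cat("\n")
})

setMethod("show", "EigenSystem", function(object) {
  k <- min(5L, length(object@values))
  cat(sprintf("EigenSystem: %d modes over \"%s\"\n",
    length(object@values), object@selection))
  cat(sprintf("  leading eigenvalues (nm^2): %s\n",
    paste(signif(object@values[seq_len(k)], 4), collapse = ", ")))
  cat(sprintf("  cumulative variance at %d modes: %.1f%%\n",
    k, 100 * object@cumulativeFraction[k]))
})

setMethod("show", "KineticsFit", function(object) {
  cat("Michaelis-Menten fit",
    if (!object@converged) "(NOT converged)" else "", "\n")
  cat(sprintf("  Km   = %.4g +/- %.3g mM\n", object@km, object@kmSE))
  cat(sprintf("  Vmax = %.4g +/- %.3g %s\n", object@vmax, object@vmaxSE,
    object@velocityUnit))
  if (!is.na(object@kcat)) {
    cat(sprintf("  kcat = %.4g +/- %.3g s^-1  ([E] = %g uM per subunit)\n",
      object@kcat, object@kcatSE, object@enzymeConc))
    cat(sprintf("  kcat/Km = %.4g mM^-1 s^-1\n", object@efficiency))
  }
  cat(sprintf("  RSS = %.4g\n", object@rss))
})
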