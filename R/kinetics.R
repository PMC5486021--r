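#' Fit Michaelis-Menten kinetics by nonlinear least squares
#'
#' Fits v = Vmax [S] / (Km + [S]) to initial-rate data by unweighted
#' Levenberg-Marquardt least squares. Initial guesses follow the standard
#' recipe: Vmax0 = max(v), Km0 = the substrate concentration of the
#' observation whose velocity is nearest Vmax0/2. Standard errors come
#' from the Jacobian at the optimum. When the enzyme (subunit)
#' concentration is known, the turnover number kcat = Vmax / [E] and the
#' catalytic efficiency kcat/Km are derived; kcat is per subunit, so [E]
#' must be the monomer concentration even for an oligomeric enzyme.
#'
#' @param data data.frame with columns `substrate_mM` and `velocity`
#'   (a `replicate` column is allowed and ignored by the fit), e.g. from
#'   [generateMMDataset()] or [readKineticsTSV()].
#' @param enzymeConc enzyme subunit concentration, uM; defaults to the
#'   dataset's `enzymeConc` attribute when present. With velocities in
#'   uM/s this makes kcat come out in s^-1.
#' @param velocityUnit unit tag carried into the result.
#' @return a [KineticsFit].
#' @examples
#' d <- generateMMDataset(kmTrue = 10, kcatTrue = 100, enzymeConc = 0.01,
#'   substrateGrid = c(1, 2, 5, 10, 20, 50, 100), noiseCV = 0, seed = 1)
#' fitMichaelisMenten(d)
#' @export
fitMichaelisMenten <- function(data, enzymeConc = attr(data, "enzymeConc"),
                               velocityUnit = attr(data, "velocityUnit")) {
  if (!all(c("substrate_mM", "velocity") %in% names(data)))
    stop("data needs columns substrate_mM and velocity")
  s <- data$substrate_mM; v <- data$velocity
  if (any(s <= 0)) stop("substrate concentrations must be > 0")
  if (length(unique(s)) < 4L)
    stop("under-determined fit: need >= 4 distinct substrate concentrations")
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  fit <- try(minpack.lm::nlsLM(v ~ Vmax * s / (Km + s),
    start = list(Vmax = vmax0, Km = km0),
    lower = c(Vmax = 1e-12, Km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error"))
    return(new("KineticsFit", km = NA_real_, kmSE = NA_real_,
      vmax = NA_real_, vmaxSE = NA_real_, kcat = NA_real_, kcatSE = NA_real_,
      efficiency = NA_real_, enzymeConc = enzymeConc %||% NA_real_,
      velocityUnit = velocityUnit %||% "", converged = FALSE,
      rss = NA_real_))
  co <- summary(fit)$coefficients
  km <- co["Km", "Estimate"]; vmax <- co["Vmax", "Estimate"]
  if (km <= 1e-10 || vmax <= 1e-10)
    warning("fitted parameter at its lower bound; estimates unreliable")
  haveE <- !is.null(enzymeConc) && is.finite(enzymeConc)
  kcat <- if (haveE) vmax / enzymeConc else NA_real_
  kcatSE <- if (haveE) co["Vmax", "Std. Error"] / enzymeConc else NA_real_
  new("KineticsFit",
      km = km, kmSE = co["Km", "Std. Error"],
      vmax = vmax, vmaxSE = co["Vmax", "Std. Error"],
      kcat = kcat, kcatSE = kcatSE,
      efficiency = if (haveE) kcat / km else NA_real_,
      enzymeConc = if (haveE) enzymeConc else NA_real_,
      velocityUnit = velocityUnit %||% "",
      converged = TRUE, rss = sum(stats::residuals(fit)^2))
}

#' Catalytic efficiency
#'
#' The specificity constant kcat/Km (mM^-1 s^-1 for kcat in s^-1 and Km in
#' mM) — the second-order rate constant for the enzyme-substrate reaction
#' at sub-saturating substrate.
#'
#' @param kcat turnover number, s^-1.
#' @param km Michaelis constant, mM (> 0).
#' @return kcat / Km.
#' @examples
#' catalyticEfficiency(87.844, 17.126)  # 5.129
#' @export
catalyticEfficiency <- function(kcat, km) {
  if (any(km <= 0)) stop("Km must be > 0")
  kcat / km
}

#' Fold difference between two Michaelis constants
#'
#' @param kmA,kmB Michaelis constants (> 0), same unit.
#' @return `kmA / kmB`.
#' @examples
#' kmRatio(0.404, 0.072)  # NADP vs NAD: 5.6-fold
#' @export
kmRatio <- function(kmA, kmB) {
  if (any(c(kmA, kmB) <= 0)) stop("Km values must be > 0")
  kmA / kmB
}

#' Read / write kinetics tables
#'
#' Plain TSV with a one-line header and columns `substrate_mM`,
#' `velocity`, `replicate`; the enzyme concentration and velocity unit
#' travel as `# key value` comment lines so a round-trip preserves them.
#'
#' @param path TSV file path.
#' @return data.frame like [generateMMDataset()]'s.
#' @export
readKineticsTSV <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  d <- utils::read.delim(text = lines[!startsWith(lines, "#")])
  getMeta <- function(key) {
    m <- meta[grepl(paste0("^# ", key, " "), meta)]
    if (length(m)) sub(paste0("^# ", key, " "), "", m[1]) else NULL
  }
  ec <- getMeta("enzymeConc_uM")
  if (!is.null(ec)) attr(d, "enzymeConc") <- as.numeric(ec)
  vu <- getMeta("velocityUnit")
  if (!is.null(vu)) attr(d, "velocityUnit") <- vu
  d
}

#' @rdname readKineticsTSV
#' @param data kinetics data.frame.
#' @export
writeKineticsTSV <- function(data, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  if (!is.null(attr(data, "enzymeConc")))
    writeLines(sprintf("# enzymeConc_uM %.10g", attr(data, "enzymeConc")), con)
  if (!is.null(attr(data, "velocityUnit")))
    writeLines(paste("# velocityUnit", attr(data, "velocityUnit")), con)
  utils::write.table(data, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
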