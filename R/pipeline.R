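#' Run the full trajectory-analysis pipeline
#'
#' Orchestrates the per-figure analyses over one trajectory and writes one
#' TSV per panel plus a JSON manifest recording every parameter actually
#' used (defaults included) and the package version. The iterated-mean
#' superposition is computed once and shared by the RMSF, S^2 and
#' essential-dynamics stages, so their cross-identities (the covariance
#' trace equalling the sum of squared RMSFs) hold exactly.
#'
#' Supported metrics and their outputs:
#' \describe{
#'   \item{rmsd}{`rmsd.tsv` — time, all_atom, backbone (nm).}
#'   \item{rg}{`rg.tsv` — time, rg (nm).}
#'   \item{hbonds}{`hbonds.tsv` — time, count.}
#'   \item{sasa}{`sasa.tsv` — time, total_nm2.}
#'   \item{rmsf}{`rmsf.tsv` — chain, resid, rmsf_nm, bfactor_A2.}
#'   \item{s2}{`s2.tsv` — chain, resid, s2.}
#'   \item{ed}{`ed_eigenvalues.tsv`, `ed_projections.tsv`,
#'     `correlation_map.tsv`.}
#' }
#' The four time-series metrics default to the full trajectory (the
#' figure-panel convention); the profile metrics use the equilibrium
#' window starting at `windowStart`.
#'
#' @param config a named list, or the path of a YAML file holding one,
#'   with fields `input` (multi-model PDB path; alternatively pass a
#'   [Trajectory] as `trajectory`), `outdir`, optional `metrics`
#'   (character subset of the supported set; default all), `windowStart`
#'   (fraction, default 0.5), `seed` (recorded), and optional overrides
#'   `hbond` (list for [hbondCriterion()]), `sasa` (list for
#'   [sasaParams()]), `edModes` (projection count, default 10).
#' @param trajectory optionally a [Trajectory], bypassing `input`.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, trajectory = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  supported <- c("rmsd", "rg", "hbonds", "sasa", "rmsf", "s2", "ed")
  metrics <- config$metrics %||% supported
  bad <- setdiff(metrics, supported)
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "),
         " (supported: ", paste(supported, collapse = ", "), ")")
  outdir <- config$outdir %||% stop("config needs an output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  windowStart <- config$windowStart %||% 0.5
  edModes <- config$edModes %||% 10L
  hbc <- do.call(hbondCriterion, config$hbond %||% list())
  sap <- do.call(sasaParams, config$sasa %||% list())

  traj <- trajectory %||% readPDBTrajectory(
    config$input %||% stop("config needs an input trajectory"))

  wtsv <- function(d, f) {
    utils::write.table(format(d, digits = 10, trim = TRUE, scientific = FALSE),
      file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  written <- character(0)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- expr
    message(sprintf("[protdyn] %-8s %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    r
  }

  needShared <- any(c("rmsf", "s2", "ed") %in% metrics)
  shared <- if (needShared)
    stage("fit", superposeToMean(traj, "name CA", startFraction = windowStart))
  else NULL

  if ("rmsd" %in% metrics) {
    allAtom <- stage("rmsd", rmsdSeries(traj, fitSelection = "all"))
    bb <- rmsdSeries(traj, fitSelection = "backbone")
    written <- c(written, wtsv(data.frame(time = allAtom$time,
      all_atom = allAtom$rmsd, backbone = bb$rmsd), "rmsd.tsv"))
  }
  if ("rg" %in% metrics)
    written <- c(written, wtsv(stage("rg",
      radiusOfGyrationSeries(traj)), "rg.tsv"))
  if ("hbonds" %in% metrics)
    written <- c(written, wtsv(stage("hbonds",
      hbondSeries(traj, hbc)), "hbonds.tsv"))
  if ("sasa" %in% metrics) {
    s <- stage("sasa", sasaSeries(traj, sap))
    written <- c(written, wtsv(data.frame(time = s$time,
      total_nm2 = s$sasa), "sasa.tsv"))
  }
  rmsf <- NULL
  if ("rmsf" %in% metrics || "ed" %in% metrics)
    rmsf <- stage("rmsf", rmsfProfile(traj, superposed = shared))
  if ("rmsf" %in% metrics)
    written <- c(written, wtsv(data.frame(chain = rmsf$chain,
      resid = rmsf$resid, rmsf_nm = rmsf$rmsf,
      bfactor_A2 = bfactorFromRmsf(rmsf$rmsf)), "rmsf.tsv"))
  if ("s2" %in% metrics)
    written <- c(written, wtsv(stage("s2",
      s2Profile(traj, superposed = shared)), "s2.tsv"))
  if ("ed" %in% metrics) {
    C <- stage("ed", covarianceMatrix(traj, superposed = shared))
    es <- eigenDecompose(C)
    k <- min(edModes, length(es@values))
    ev <- data.frame(mode = seq_along(es@values),
      lambda_nm2 = es@values, fraction = es@varianceFraction,
      cumulative = es@cumulativeFraction)
    written <- c(written, wtsv(ev, "ed_eigenvalues.tsv"))
    written <- c(written,
      wtsv(projectTrajectory(traj, es, k, superposed = shared),
           "ed_projections.tsv"))
    M <- correlationMap(traj, superposed = shared)
    cm <- data.frame(residue = rownames(M), M, check.names = FALSE)
    written <- c(written, wtsv(cm, "correlation_map.tsv"))
  }

  manifest <- list(
    package = "protdyn",
    version = as.character(utils::packageVersion("protdyn")),
    input = config$input %||% "<in-memory trajectory>",
    nFrames = nFrames(traj), nAtoms = nAtoms(traj),
    metrics = metrics, windowStart = windowStart,
    hbondCriterion = hbc,
    sasaParams = list(probeRadius = sap$probeRadius,
                      nSpherePoints = sap$nSpherePoints,
                      radiiSet = as.list(sap$radiiSet)),
    edModes = edModes,
    seed = config$seed %||% NA,
    outputs = written)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
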