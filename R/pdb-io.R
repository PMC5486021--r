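#' Read a multi-model PDB file as a trajectory
#'
#' Parses MODEL/ENDMDL blocks (or a single implicit model) into a
#' [Trajectory]. Coordinates are converted from Angstrom to nm. The
#' element is taken from PDB columns 77-78 when present, otherwise
#' inferred from the atom name; atomic masses come from a fixed internal
#' element table. Hydrogen attachments are resolved from the first frame.
#'
#' Frame times are read from `REMARK 250 TIME` records written by
#' [writePDBTrajectory()]; absent those, frames are numbered 0, 1, 2, ... ps.
#'
#' @param path path to a PDB file with >= 1 model.
#' @return a [Trajectory].
#' @seealso [writePDBTrajectory()], [writePDBWithBfactors()]
#' @export
readPDBTrajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  isAtom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(isAtom)) stop("no ATOM records in ", path)

  modelStarts <- which(rec == "MODEL ")
  atomLineNo <- which(isAtom)
  if (length(modelStarts) == 0L) {
    frameOf <- rep(1L, length(atomLineNo))
    nModels <- 1L
  } else {
    frameOf <- findInterval(atomLineNo, modelStarts)
    if (any(frameOf == 0L))
      stop("ATOM records before the first MODEL record")
    nModels <- length(modelStarts)
  }

  al <- lines[atomLineNo]
  x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("unparseable ATOM line %d: %s", atomLineNo[bad[1]], al[bad[1]]))

  perModel <- tabulate(frameOf, nbins = nModels)
  if (length(unique(perModel)) != 1L) {
    off <- which(perModel != perModel[1])[1]
    stop(sprintf(
      "inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
      off, perModel[off], perModel[1]))
  }
  nA <- perModel[1]

  first <- frameOf == 1L
  name <- trimws(substr(al[first], 13, 16))
  resname <- trimws(substr(al[first], 18, 20))
  chain <- substr(al[first], 22, 22)
  resid <- suppressWarnings(as.integer(substr(al[first], 23, 26)))
  if (any(is.na(resid)))
    stop(sprintf("unparseable residue number on ATOM line %d",
                 atomLineNo[first][which(is.na(resid))[1]]))
  serial <- suppressWarnings(as.integer(substr(al[first], 7, 11)))
  if (any(is.na(serial))) serial <- seq_len(nA)
  element <- trimws(substr(al[first], 77, 78))
  blank <- is.na(element) | element == ""
  element[blank] <- inferElement(name[blank])
  chain[chain == " "] <- "A"

  co <- array(NA_real_, dim = c(nA, 3L, nModels))
  co[, 1, ] <- x / 10  # Angstrom -> nm
  co[, 2, ] <- y / 10
  co[, 3, ] <- z / 10

  atomTable <- data.frame(serial = serial, name = name, resname = resname,
    resid = resid, chain = chain, element = toupper(element),
    stringsAsFactors = FALSE)
  top <- makeTopology(atomTable, co[, , 1])

  tl <- lines[grepl("^REMARK 250 TIME", lines)]
  times <- if (length(tl) == nModels) {
    suppressWarnings(as.numeric(sub("^REMARK 250 TIME *", "", tl)))
  } else NULL
  if (is.null(times) || any(is.na(times)) ||
      (nModels > 1L && any(diff(times) <= 0)))
    times <- as.numeric(seq_len(nModels) - 1L)

  new("Trajectory", coords = co, times = times, topology = top)
}

# One fixed-width ATOM line block for a frame (coords in nm, written in A).
formatAtomLines <- function(atomTable, frame, bfac) {
  el <- atomTable$element
  # atom-name column: element symbols of width 1 start in column 14
  nm <- ifelse(nchar(atomTable$name) < 4L,
               sprintf(" %-3s", atomTable$name), atomTable$name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atomTable$serial %% 100000L, nm, atomTable$resname, atomTable$chain,
    atomTable$resid, frame[, 1] * 10, frame[, 2] * 10, frame[, 3] * 10,
    1.00, bfac, el)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame; coordinates converted nm to Angstrom
#' at the PDB's 3-decimal precision. Frame times are preserved in
#' `REMARK 250 TIME` records so a round-trip through [readPDBTrajectory()]
#' restores them.
#'
#' @param traj a [Trajectory].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDBTrajectory <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@topology@atoms
  nF <- nFrames(traj)
  bfac <- rep(0, nrow(a))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("REMARK 250 TIME %.6f", traj@times), con)
  for (f in seq_len(nF)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(formatAtomLines(a, traj@coords[, , f], bfac), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure with per-residue values in the B-factor column
#'
#' Writes one model whose B-factor column (fixed 6.2 format) carries the
#' given per-residue value on every atom of that residue — the standard
#' device for shading a structure by RMSF-derived B-factors in a molecular
#' viewer. Values beyond the column capacity are clamped to 999.99 with a
#' warning.
#'
#' @param topology a [Topology].
#' @param frameCoords numeric A x 3 matrix, nm.
#' @param perResidueValues numeric vector, one finite value per residue in
#'   chain/residue order (the order of [rmsfProfile()] output).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDBWithBfactors <- function(topology, frameCoords, perResidueValues, path) {
  stopifnot(is(topology, "Topology"))
  a <- topology@atoms
  res <- unique(a[, c("chain", "resid")])
  if (length(perResidueValues) != nrow(res))
    stop(sprintf("need one value per residue: %d values for %d residues",
                 length(perResidueValues), nrow(res)))
  if (any(!is.finite(perResidueValues)))
    stop("per-residue values must be finite")
  key <- paste(a$chain, a$resid)
  b <- perResidueValues[match(key, paste(res$chain, res$resid))]
  if (any(b > 999.99)) {
    warning(sprintf("%d B-factor value(s) exceed the PDB column; clamped to 999.99",
                    sum(unique(key[b > 999.99]) %in% key)))
    b <- pmin(b, 999.99)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(formatAtomLines(a, frameCoords, b), con)
  writeLines("END", con)
  invisible(path)
}
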