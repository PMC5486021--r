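# Fixed internal element tables: atomic masses (u) and Bondi van der Waals
# radii (nm). Restricted to the elements that occur in protein heavy/H atoms;
# unknown elements raise an error at the point of use.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

.BONDI_RADII_NM <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152,
                     S = 0.180, P = 0.180)

# Hydrogens are covalently bonded to a heavy atom no farther than this (nm);
# used to resolve H attachments from coordinates (N-H ~0.10, O-H ~0.096).
.H_ATTACH_CUTOFF_NM <- 0.125

elementMass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (any(is.na(m)))
    stop("unknown element(s) in mass table: ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Element from a PDB atom name
#'
#' Infers the element when the PDB element column is blank: the first
#' alphabetic character of the stripped atom name, with the PDB convention
#' that names starting in column 13 with a digit (e.g. "1HB") are hydrogens.
#'
#' @param name character vector of atom names (stripped).
#' @return character vector of element symbols.
#' @keywords internal
inferElement <- function(name) {
  nm <- gsub("[^A-Za-z]", "", name)
  el <- toupper(substr(nm, 1L, 1L))
  # two-letter elements are absent from standard amino acids; digits-first
  # names (1HB, 2HG1) are hydrogens and gsub already dropped the digit
  el[el == ""] <- NA_character_
  el
}

# Resolve each hydrogen to its bonded heavy atom. Attachment is a topology
# property, so name rules come first (the amide "H"/"HN" bonds to the
# backbone N; "HA.." to CA, "HB.." to CB, ...), then the nearest heavy atom
# of the same residue, and only as a last resort the nearest heavy atom
# overall within a covalent cutoff.
attachHydrogens <- function(atomTable, frameCoords) {
  n <- nrow(atomTable)
  att <- rep(NA_integer_, n)
  isH <- atomTable$element == "H"
  if (!any(isH)) return(att)
  heavy <- which(!isH)
  if (!length(heavy)) stop("topology contains only hydrogens")
  resKey <- paste(atomTable$chain, atomTable$resid)
  for (k in which(isH)) {
    sameRes <- heavy[resKey[heavy] == resKey[k]]
    hname <- sub("^[0-9]+", "", atomTable$name[k])  # 1HB -> HB
    if (hname %in% c("H", "HN")) {
      hit <- sameRes[atomTable$name[sameRes] == "N"]
      if (length(hit) == 1L) { att[k] <- hit; next }
    }
    pool <- if (length(sameRes)) sameRes else heavy
    d2 <- colSums((t(frameCoords[pool, , drop = FALSE]) - frameCoords[k, ])^2)
    j <- which.min(d2)
    if (!length(sameRes) && d2[j] > .H_ATTACH_CUTOFF_NM^2)
      stop(sprintf("hydrogen atom %d has no heavy atom within %.3f nm", k,
                   .H_ATTACH_CUTOFF_NM))
    att[k] <- pool[j]
  }
  att
}

# Construct a Topology from an atom table (+ coordinates for H attachment).
makeTopology <- function(atomTable, frameCoords) {
  if (is.null(atomTable$element) || any(is.na(atomTable$element)) ||
      any(atomTable$element == ""))
    stop("element required for every atom")
  atomTable$mass <- elementMass(atomTable$element)
  att <- attachHydrogens(atomTable, frameCoords)
  new("Topology", atoms = atomTable, hAttach = att)
}
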