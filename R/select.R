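#' Resolve an atom selection expression
#'
#' Evaluates one of the supported selection terms against a topology and
#' returns the matching atom indices. Supported grammar:
#' \describe{
#'   \item{`"all"`}{every atom.}
#'   \item{`"backbone"`}{atoms named N, CA, C, O.}
#'   \item{`"name <NAME>"`}{atoms with that exact name, e.g. `"name CA"`.}
#'   \item{`"chain <ID>"`}{atoms of one chain, e.g. `"chain A"`.}
#'   \item{`"amide-NH"`}{backbone amide (N, H) pairs per residue, excluding
#'     prolines and the first residue of each chain (no amide hydrogen);
#'     the pairs are returned in chain/residue order.}
#' }
#'
#' Selections depend only on the topology, never on coordinates or frame
#' order.
#'
#' @param topology a [Topology].
#' @param expression a single selection string from the grammar above.
#' @return an [AtomSelection]; for `"amide-NH"` its `pairs` slot holds one
#'   `(N, H)` index row per amide.
#' @examples
#' top <- topology(generateReferenceStructure(10, 1, seed = 1))
#' length(selectAtoms(top, "name CA")@indices)  # 10
#' nrow(selectAtoms(top, "amide-NH")@pairs)     # 9: N-terminus excluded
#' @export
selectAtoms <- function(topology, expression) {
  stopifnot(is(topology, "Topology"), is.character(expression),
            length(expression) == 1L)
  a <- topology@atoms
  expr <- trimws(expression)
  pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("N", "H")))
  if (expr == "all") {
    idx <- seq_len(nrow(a))
  } else if (expr == "backbone") {
    idx <- which(a$name %in% c("N", "CA", "C", "O"))
  } else if (grepl("^name ", expr)) {
    idx <- which(a$name == sub("^name +", "", expr))
  } else if (grepl("^chain ", expr)) {
    idx <- which(a$chain == sub("^chain +", "", expr))
  } else if (expr == "amide-NH") {
    pairs <- amideNHPairs(topology)
    idx <- sort(as.integer(pairs))
  } else {
    stop(sprintf("unsupported selection expression: \"%s\"", expression))
  }
  new("AtomSelection", expression = expr, indices = as.integer(sort(idx)),
      pairs = pairs)
}

# (N, H) index pairs for backbone amides: skip prolines and each chain's
# first residue; require exactly one hydrogen attached to the backbone N.
amideNHPairs <- function(topology) {
  a <- topology@atoms
  out <- matrix(integer(0), ncol = 2)
  for (ch in unique(a$chain)) {
    inCh <- a$chain == ch
    resids <- unique(a$resid[inCh])
    for (r in resids[-1]) {
      rows <- which(inCh & a$resid == r)
      if (any(a$resname[rows] == "PRO")) next
      nIdx <- rows[a$name[rows] == "N"]
      if (length(nIdx) != 1L) next
      hIdx <- which(topology@hAttach == nIdx)
      if (length(hIdx) != 1L) next
      out <- rbind(out, c(nIdx, hIdx))
    }
  }
  dimnames(out) <- list(NULL, c("N", "H"))
  out
}

# internal: indices or error on empty
resolveSelection <- function(topology, selection) {
  sel <- if (is(selection, "AtomSelection")) selection
         else selectAtoms(topology, selection)
  if (!length(sel@indices))
    stop(sprintf("selection \"%s\" matches no atoms", sel@expression))
  sel
}
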