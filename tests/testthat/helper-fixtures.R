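# Programmatic fixtures shared across test files. Everything is generated
# in code so the suite carries no binary data.

# small topology built straight from an atom table (coordinates in nm)
miniTopology <- function(elements, coords, names = elements,
                         resid = seq_along(elements), chain = "A",
                         resname = "ALA") {
  at <- data.frame(serial = seq_along(elements), name = names,
    resname = resname, resid = resid, chain = chain,
    element = elements, stringsAsFactors = FALSE)
  protdyn:::makeTopology(at, coords)
}

# trajectory from an explicit list of coordinate frames over a topology
miniTrajectory <- function(topology, frames, dt = 1) {
  co <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  new("Trajectory", coords = co, times = dt * (seq_along(frames) - 1),
      topology = topology)
}

# a rigid-body (tumbling-only) trajectory: random rotations/translations of
# the reference, zero internal motion
rigidTumblingTrajectory <- function(ref, nFrames = 100, seed = 1) {
  generateHarmonicTrajectory(ref, sigma = 0, nFrames = nFrames,
                             tumbling = TRUE, seed = seed)
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

# random protein-like polar cloud for hydrogen-bond oracle equivalence:
# N/O heavy atoms scattered in a box, each N given one hydrogen at ~0.1 nm
randomPolarSystem <- function(nHeavy = 60, box = 1.2, seed = 1) {
  set.seed(seed)
  el <- sample(c("N", "O"), nHeavy, replace = TRUE)
  xyz <- matrix(runif(nHeavy * 3, 0, box), ncol = 3)
  hFor <- which(el == "N")
  hxyz <- xyz[hFor, , drop = FALSE] +
    0.1 * {
      v <- matrix(rnorm(length(hFor) * 3), ncol = 3)
      v / sqrt(rowSums(v^2))
    }
  elements <- c(el, rep("H", length(hFor)))
  coords <- rbind(xyz, hxyz)
  names <- c(el, rep("H", length(hFor)))
  # one residue per heavy atom; hydrogens share their donor's residue
  resid <- c(seq_len(nHeavy), hFor)
  ord <- order(resid)
  list(topology = miniTopology(elements[ord], coords[ord, , drop = FALSE],
         names = names[ord], resid = resid[ord]),
       coords = coords[ord, , drop = FALSE])
}
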