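# Independent oracles used to cross-check package implementations.
# These deliberately take different algorithmic routes from the package:
# the superposition oracle is Horn's quaternion method (the package uses
# Kabsch/SVD), and the hydrogen-bond oracle is an all-pairs scan with no
# spatial pruning (the package uses a cell list).

# Horn (1987) closed-form absolute orientation: the optimal rotation is the
# eigenvector of a 4x4 quaternion matrix with the largest eigenvalue.
hornSuperposition <- function(mobile, ref, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(ref * w)
  X <- sweep(mobile, 2, cm); Y <- sweep(ref, 2, cr)
  S <- crossprod(X * w, Y)
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  e <- eigen(K, symmetric = TRUE)
  q <- e$vectors[, 1]
  qw <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  Rq <- matrix(c(
    1 - 2 * (qy^2 + qz^2), 2 * (qx * qy - qw * qz), 2 * (qx * qz + qw * qy),
    2 * (qx * qy + qw * qz), 1 - 2 * (qx^2 + qz^2), 2 * (qy * qz - qw * qx),
    2 * (qx * qz - qw * qy), 2 * (qy * qz + qw * qx), 1 - 2 * (qx^2 + qy^2)),
    nrow = 3, byrow = TRUE)
  fitted <- X %*% t(Rq)
  rmsd <- sqrt(sum(w * rowSums((fitted - Y)^2)))
  list(rotation = t(Rq), rmsd = rmsd)
}

# Brute-force geometric hydrogen-bond detection: every donor-H pair against
# every acceptor, no neighbor pruning. Same criterion semantics as the
# package: d(D,A) <= distCut, H-D-A angle at the donor <= angCut, pairs
# below covCut are covalent, D != A.
bruteForceHBonds <- function(frameCoords, topology,
                             criterion = hbondCriterion()) {
  a <- atoms(topology)
  polar <- which(a$element %in% c("N", "O"))
  hIdx <- which(a$element == "H")
  att <- topology@hAttach[hIdx]
  keep <- att %in% polar
  donors <- att[keep]; hydro <- hIdx[keep]
  out <- NULL
  for (i in seq_along(donors)) {
    d <- donors[i]; h <- hydro[i]
    vh <- frameCoords[h, ] - frameCoords[d, ]
    for (acc in polar) {
      if (acc == d) next
      va <- frameCoords[acc, ] - frameCoords[d, ]
      dist <- sqrt(sum(va^2))
      if (dist > criterion$maxDonorAcceptorDist ||
          dist <= criterion$covalentCutoff) next
      cosang <- sum(vh * va) / (sqrt(sum(vh^2)) * dist)
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang <= criterion$maxHDonorAcceptorAngle)
        out <- rbind(out, c(d, h, acc))
    }
  }
  if (is.null(out)) out <- matrix(integer(0), ncol = 3)
  colnames(out) <- c("donor", "hydrogen", "acceptor")
  out
}

# canonical string form of a triple set for set equality checks
tripleKey <- function(m) sort(apply(m, 1, paste, collapse = "-"))
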