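# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately share no code with the implementation.

# All residue pairs of two chains with minimum heavy-atom distance <= cutoff,
# by exhaustive double loop over residues.
bruteContactMap <- function(chainA, chainB, cutoff = 4.5) {
  a <- atomTable(chainA); b <- atomTable(chainB)
  keyA <- unique(paste(a$resno, a$insert))
  keyB <- unique(paste(b$resno, b$insert))
  out <- NULL
  for (ka in keyA) {
    ia <- paste(a$resno, a$insert) == ka
    for (kb in keyB) {
      ib <- paste(b$resno, b$insert) == kb
      d2 <- outer(a$x[ia], b$x[ib], "-")^2 +
        outer(a$y[ia], b$y[ib], "-")^2 +
        outer(a$z[ia], b$z[ib], "-")^2
      dm <- sqrt(min(d2))
      if (dm <= cutoff)
        out <- rbind(out, data.frame(resnoA = a$resno[ia][1],
                                     resnoB = b$resno[ib][1], dist = dm))
    }
  }
  out
}

# Exhaustive atom-pair clash count.
bruteClashCount <- function(poseAtoms, model, overlap = 1.5) {
  prot <- atomTable(model)
  prot <- prot[prot$kind == "polymer", ]
  n <- 0L
  for (i in seq_len(nrow(poseAtoms))) {
    d2 <- (prot$x - poseAtoms$x[i])^2 + (prot$y - poseAtoms$y[i])^2 +
      (prot$z - poseAtoms$z[i])^2
    n <- n + sum(d2 < overlap^2)
  }
  n
}

# Center-of-mass deviation by direct mean-coordinate arithmetic.
bruteComDeviation <- function(a, b) {
  ca <- c(mean(a$x), mean(a$y), mean(a$z))
  cb <- c(mean(b$x), mean(b$y), mean(b$z))
  sqrt(sum((ca - cb)^2))
}

# Horn's closed-form quaternion superposition: independent of the Kabsch
# (SVD) route used by the package. Returns the least RMSD of moving -> fixed.
quaternionRmsd <- function(fixed, moving) {
  A <- sweep(fixed, 2, colMeans(fixed))
  B <- sweep(moving, 2, colMeans(moving))
  M <- t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(A^2) + sum(B^2) - 2 * lmax) / nrow(fixed)
  sqrt(max(0, e2))
}

# Random residue-labelled point cloud for oracle-equivalence sweeps.
randomContactFixture <- function(seed, nA = 20, nB = 20, spread = 12) {
  set.seed(seed)
  mkAtoms <- function(n, chain, shift) {
    nat <- sample(1:3, n, replace = TRUE)
    do.call(rbind, lapply(seq_len(n), function(i) {
      base <- runif(3, 0, spread) + shift
      data.frame(chain = chain, resno = i, insert = "",
                 resid = "ALA", elety = paste0("C", seq_len(nat[i])),
                 elesy = "C",
                 x = base[1] + runif(nat[i], -1, 1),
                 y = base[2] + runif(nat[i], -1, 1),
                 z = base[3] + runif(nat[i], -1, 1),
                 occ = 1, het = FALSE, kind = "polymer", metal = FALSE,
                 stringsAsFactors = FALSE)
    }))
  }
  atoms <- rbind(mkAtoms(nA, "A", c(0, 0, 0)),
                 mkAtoms(nB, "B", c(runif(1, 2, 6), 0, 0)))
  newStructureModel(atoms, entryId = sprintf("rnd%d", seed))
}
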