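#' @include fingerprint.R
NULL

## Run code under a temporary RNG state seeded with `seed`.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

.atomRow <- function(chain, resno, resid, elety, elesy, x, y, z,
                     kind = "polymer", het = FALSE, metal = FALSE) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = elety, elesy = elesy, x = x, y = y, z = z,
             occ = 1, het = het, kind = kind, metal = metal,
             stringsAsFactors = FALSE)
}

#' Specification for a synthetic dimer fixture
#'
#' Collects the knobs of [makeDimerFixture]. In the default open-contact
#' geometry, residue and ligand contact counts are planted exactly; with
#' \code{pocketEnclosure = TRUE} the fixture instead builds a closed cavity
#' at the chain-chain seam (wall residues split between the chains, the
#' ligand inside) and the ground-truth contact counts are measured by
#' brute-force distance arithmetic during construction.
#'
#' @param residuesPerChain polymer residues per chain (open mode).
#' @param contacts planted inter-chain residue contact pairs (open mode).
#' @param ligandAtoms total ligand heavy atoms.
#' @param ligandContactsA,ligandContactsB planted distinct-residue contact
#'   counts of the ligand against each chain (open mode).
#' @param ligandCode 3-letter component code given to the planted ligand.
#' @param pocketEnclosure build the closed interface-cavity geometry.
#' @param boxDims interior cavity dimensions in Angstrom (enclosure mode).
#' @param subBoxes number of random attached sub-cavities for shape
#'   diversity (enclosure mode).
#' @param notches number of random sub-boxes carved out of the cavity
#'   (filled with wall residues), further diversifying its shape.
#' @param wallJitter uniform jitter applied to wall atom positions (Angstrom).
#' @param metalSite element symbol to plant a single-atom metal ion
#'   surrounded by a 5+5 residue ring, or NULL.
#' @param nWaters number of water molecules planted far from the interface.
#' @param seed RNG seed (mandatory).
#' @return a list of class \code{"FixtureSpec"}.
#' @export
dimerFixtureSpec <- function(residuesPerChain = 30, contacts = 6,
                             ligandAtoms = 11, ligandContactsA = 6,
                             ligandContactsB = 5, ligandCode = "LG1",
                             pocketEnclosure = FALSE, boxDims = c(6, 6, 6),
                             subBoxes = 0, notches = 0, wallJitter = 0,
                             metalSite = NULL, nWaters = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for fixture specs")
  stopifnot(residuesPerChain >= 0, contacts >= 0, ligandAtoms >= 0,
            ligandContactsA >= 0, ligandContactsB >= 0, nWaters >= 0)
  structure(list(residuesPerChain = residuesPerChain, contacts = contacts,
                 ligandAtoms = ligandAtoms, ligandContactsA = ligandContactsA,
                 ligandContactsB = ligandContactsB, ligandCode = ligandCode,
                 pocketEnclosure = pocketEnclosure, boxDims = boxDims,
                 subBoxes = subBoxes, notches = notches, wallJitter = wallJitter,
                 metalSite = metalSite, nWaters = nWaters, seed = seed),
            class = "FixtureSpec")
}

## Brute-force ground-truth measurement used by the generators: distinct
## inter-chain residue contacts and ligand-residue contacts at <= cutoff.
.measureTruth <- function(atoms, cutoff = 4.5) {
  pol <- atoms[atoms$kind == "polymer", , drop = FALSE]
  lig <- atoms[atoms$kind == "ligand" & !atoms$metal, , drop = FALSE]
  ids <- unique(pol$chain)
  xyz <- function(a) as.matrix(a[, c("x", "y", "z")])
  resKey <- function(a) paste(a$chain, a$resno, a$insert)
  out <- list()
  if (length(ids) == 2) {
    A <- pol[pol$chain == ids[1], ]; B <- pol[pol$chain == ids[2], ]
    d <- sqrt(outer(rowSums(xyz(A)^2), rowSums(xyz(B)^2), "+") -
                2 * xyz(A) %*% t(xyz(B)))
    hit <- which(d <= cutoff, arr.ind = TRUE)
    out$interfaceA <- length(unique(resKey(A)[hit[, 1]]))
    out$interfaceB <- length(unique(resKey(B)[hit[, 2]]))
    if (nrow(lig)) {
      dl <- function(P) sqrt(outer(rowSums(xyz(lig)^2), rowSums(xyz(P)^2), "+") -
                               2 * xyz(lig) %*% t(xyz(P)))
      hA <- which(dl(A) <= cutoff, arr.ind = TRUE)
      hB <- which(dl(B) <= cutoff, arr.ind = TRUE)
      out$ligandContacts <- c(length(unique(resKey(A)[hA[, 2]])),
                              length(unique(resKey(B)[hB[, 2]])))
    }
  }
  out
}

#' Generate a synthetic dimer fixture with known ground truth
#'
#' Open mode emits two parallel idealized C-alpha traces (3.8 A spacing,
#' dummy side-chain centroids) with exactly \code{contacts} planted
#' inter-chain residue contacts at 4.0 A and a ligand contacting exactly
#' (\code{ligandContactsA}, \code{ligandContactsB}) distinct residues.
#' Enclosure mode builds a closed cavity at the interface: a wall shell of
#' single-atom residues split between the two chains (seam at mid-height)
#' with the ligand planted inside the cavity; its ground truth is measured
#' by brute force during construction. All output is a pure function of the
#' spec (including its seed).
#'
#' @param spec a [dimerFixtureSpec].
#' @param entryId entry identifier for the emitted model.
#' @return list with elements \code{model} (a [StructureModel]) and
#'   \code{truth} (interface residue counts per chain, ligand contact
#'   counts, planted pose, and in enclosure mode the cavity region).
#' @export
makeDimerFixture <- function(spec, entryId = sprintf("fx%d", spec$seed)) {
  stopifnot(inherits(spec, "FixtureSpec"))
  if (spec$pocketEnclosure) return(.makeEnclosureDimer(spec, entryId))
  n <- spec$residuesPerChain
  k <- spec$contacts
  cA <- spec$ligandContactsA; cB <- spec$ligandContactsB
  if (k > n || (spec$ligandAtoms > 0 && k + 1 + cA + cB > n))
    stop("infeasible spec: more planted contacts than residues")
  if (spec$ligandAtoms > 0 && spec$ligandAtoms < cA + cB)
    stop("infeasible spec: ligand atom count below its contact counts")
  .withSeed(spec$seed, {
    aaA <- sample(.AA3, n, replace = TRUE)
    aaB <- sample(.AA3, n, replace = TRUE)
    mk <- function(chain, aa, ys) {
      do.call(rbind, lapply(seq_len(n), function(i) rbind(
        .atomRow(chain, i, aa[i], "CA", "C", 3.8 * i, ys[i], 0),
        .atomRow(chain, i, aa[i], "CB", "C", 3.8 * i, ys[i], 1.2))))
    }
    ysA <- rep(0, n)
    ysB <- rep(8, n)
    if (k > 0) ysB[seq_len(k)] <- 4.0
    atoms <- rbind(mk("A", aaA, ysA), mk("B", aaB, ysB))
    pose <- NULL
    if (spec$ligandAtoms > 0) {
      ## one spacer residue after the interface block keeps the ligand's
      ## contact footprint off the planted interface columns
      iA <- if (cA) k + 1 + seq_len(cA) else integer(0)
      iB <- if (cB) k + 1 + cA + seq_len(cB) else integer(0)
      lx <- c(3.8 * iA, 3.8 * iB)
      ly <- c(rep(3.4, cA), rep(4.6, cB))
      extra <- spec$ligandAtoms - cA - cB
      if (extra > 0) {
        lx <- c(lx, 3.8 * seq_len(extra))
        ly <- c(ly, rep(-12, extra))
      }
      pose <- .atomRow("A", 900, spec$ligandCode,
                       sprintf("C%d", seq_along(lx)), "C",
                       lx, ly, rep(0, length(lx)), kind = "ligand", het = TRUE)
      atoms <- rbind(atoms, pose)
    }
    if (!is.null(spec$metalSite)) {
      th <- (0:9) * pi / 5
      cx <- -12
      ring <- .atomRow(rep(c("A", "B"), 5), 500 + (0:9),
                       rep("GLY", 10), "CA", "C",
                       cx + 3 * cos(th), 4, 3 * sin(th))
      met <- .atomRow("A", 950, spec$metalSite, spec$metalSite,
                      spec$metalSite, cx, 4, 0, kind = "ligand",
                      het = TRUE, metal = TRUE)
      atoms <- rbind(atoms, ring, met)
    }
    if (spec$nWaters > 0) {
      atoms <- rbind(atoms, .atomRow("A", 700 + seq_len(spec$nWaters), "HOH",
                                     "O", "O", 3.8 * seq_len(spec$nWaters),
                                     -20, 0, kind = "water", het = TRUE))
    }
    model <- newStructureModel(atoms, entryId = entryId)
    truth <- .measureTruth(atoms)
    truth$plantedContacts <- k
    truth$ligandPlanted <- c(cA, cB)
    truth$pose <- pose
    list(model = model, truth = truth)
  })
}

## Distance from points (rows) to an axis-aligned box; negative depth inside.
.boxSignedDist <- function(P, lo, hi) {
  dx <- pmax(lo[1] - P[, 1], P[, 1] - hi[1])
  dy <- pmax(lo[2] - P[, 2], P[, 2] - hi[2])
  dz <- pmax(lo[3] - P[, 3], P[, 3] - hi[3])
  outside <- sqrt(pmax(dx, 0)^2 + pmax(dy, 0)^2 + pmax(dz, 0)^2)
  inside <- pmin(pmax(dx, dy, dz), 0)
  outside + inside
}

.makeEnclosureDimer <- function(spec, entryId) {
  .withSeed(spec$seed, {
    dims <- spec$boxDims
    boxes <- list(list(lo = c(0, 0, 0), hi = dims))
    for (s in seq_len(spec$subBoxes)) {
      sd <- runif(3, 3, 5.5)
      ## attach to a random face of the main box, overlapping by 1 A
      ax <- sample(1:3, 1)
      lo <- runif(3, 0, pmax(0.1, dims - sd))
      lo[ax] <- dims[ax] - 1
      boxes[[length(boxes) + 1L]] <- list(lo = lo, hi = lo + sd)
    }
    notches <- list()
    for (s in seq_len(spec$notches %||% 0)) {
      nd <- runif(3, 1.5, 0.6 * dims)
      corner <- sample(0:1, 3, replace = TRUE)
      lo <- ifelse(corner == 1, dims - nd, 0)
      notches[[length(notches) + 1L]] <- list(lo = lo, hi = lo + nd)
    }
    bb <- Reduce(function(a, b) list(lo = pmin(a$lo, b$lo),
                                     hi = pmax(a$hi, b$hi)), boxes)
    ## 1.4 A wall lattice: coarse enough to keep lining-residue counts in
    ## the range of real pockets, dense enough that 1.7 A vdW spheres leave
    ## no gap for the enclosure scan rays
    step <- 1.4
    gx <- seq(bb$lo[1] - 3.5, bb$hi[1] + 3.5, by = step)
    gy <- seq(bb$lo[2] - 3.5, bb$hi[2] + 3.5, by = step)
    gz <- seq(bb$lo[3] - 3.5, bb$hi[3] + 3.5, by = step)
    P <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d <- do.call(pmin, lapply(boxes, function(b) .boxSignedDist(P, b$lo, b$hi)))
    ## carve notches out of the cavity (constructive solid geometry
    ## subtraction on the signed distance)
    for (nb in notches)
      d <- pmax(d, -.boxSignedDist(P, nb$lo, nb$hi))
    wall <- P[d >= 1.6 & d < 1.6 + step + 0.05, , drop = FALSE]
    if (spec$wallJitter > 0)
      wall <- wall + matrix(runif(length(wall), -spec$wallJitter,
                                  spec$wallJitter), ncol = 3)
    ## group wall atoms into multi-atom residues (3.2 A spatial blocks) so
    ## that lining-residue counts match real pockets; the atom positions
    ## themselves stay on the blocking lattice
    blk <- floor(sweep(wall, 2, bb$lo - 3.5, "-") / 3.2)
    bkey <- paste(blk[, 1], blk[, 2], blk[, 3])
    bz <- tapply(wall[, 3], bkey, mean)
    zmid <- mean(range(wall[, 3]))
    blockChain <- ifelse(bz < zmid, "A", "B")
    atoms <- NULL
    for (ch in c("A", "B")) {
      keys <- names(blockChain)[blockChain == ch]
      if (!length(keys)) next
      ctr <- cbind(tapply(wall[, 1], bkey, mean)[keys],
                   tapply(wall[, 2], bkey, mean)[keys],
                   tapply(wall[, 3], bkey, mean)[keys])
      keys <- keys[order(ctr[, 3], ctr[, 2], ctr[, 1])]
      aa <- sample(.AA3, length(keys), replace = TRUE)
      for (ri in seq_along(keys)) {
        w <- wall[bkey == keys[ri], , drop = FALSE]
        atoms <- rbind(atoms, .atomRow(
          ch, ri, aa[ri],
          c("CA", sprintf("C%d", seq_len(nrow(w) - 1) + 1)), "C",
          w[, 1], w[, 2], w[, 3]))
      }
    }
    pose <- NULL
    if (spec$ligandAtoms > 0) {
      inner <- P[d < -0.6 & d >= -2.9, , drop = FALSE]
      ctr <- colMeans(P[d < 0, , drop = FALSE])
      zt <- seq(min(inner[, 3]) + 0.4, max(inner[, 3]) - 0.4,
                length.out = spec$ligandAtoms)
      pick <- vapply(zt, function(z) {
        which.min((inner[, 1] - ctr[1])^2 + (inner[, 2] - ctr[2])^2 +
                    (inner[, 3] - z)^2)
      }, 1L)
      lp <- inner[pick, , drop = FALSE]
      pose <- .atomRow("A", 900, spec$ligandCode,
                       sprintf("C%d", seq_len(nrow(lp))), "C",
                       lp[, 1], lp[, 2], lp[, 3], kind = "ligand", het = TRUE)
      atoms <- rbind(atoms, pose)
    }
    model <- newStructureModel(atoms, entryId = entryId)
    truth <- .measureTruth(atoms)
    truth$pose <- pose
    truth$boxes <- boxes
    truth$cavityVolume <- NA_real_   # irregular shell; no analytic volume
    list(model = model, truth = truth)
  })
}

## Atoms sampled on the surface at constant distance r from an axis-aligned
## box: offset face planes, quarter-cylinder edges and sphere-octant
## corners. With r equal to the atoms' van der Waals radius the uncovered
## interior is the box itself (to within the sampling step).
.boxShellAtoms <- function(box, r = 1.7, step = 0.3) {
  pts <- list()
  lin <- function(len) seq(0, len, length.out = max(2L, ceiling(len / step) + 1L))
  ## faces
  for (ax in 1:3) {
    o <- setdiff(1:3, ax)
    uv <- as.matrix(expand.grid(u = lin(box[o[1]]), v = lin(box[o[2]])))
    for (side in c(-r, box[ax] + r)) {
      m <- matrix(0, nrow(uv), 3)
      m[, ax] <- side; m[, o[1]] <- uv[, 1]; m[, o[2]] <- uv[, 2]
      pts[[length(pts) + 1L]] <- m
    }
  }
  nth <- max(2L, ceiling((pi / 2) * r / step) + 1L)
  th <- seq(0, pi / 2, length.out = nth)
  ## edges: quarter cylinders around the 12 box edges
  for (ax in 1:3) {
    o <- setdiff(1:3, ax)
    t <- lin(box[ax])
    for (s1 in c(0, box[o[1]])) for (s2 in c(0, box[o[2]])) {
      d1 <- if (s1 == 0) -1 else 1
      d2 <- if (s2 == 0) -1 else 1
      m <- as.matrix(expand.grid(t = t, th = th))
      out <- matrix(0, nrow(m), 3)
      out[, ax] <- m[, 1]
      out[, o[1]] <- s1 + d1 * r * cos(m[, 2])
      out[, o[2]] <- s2 + d2 * r * sin(m[, 2])
      pts[[length(pts) + 1L]] <- out
    }
  }
  ## corners: sphere octants
  sph <- as.matrix(expand.grid(th = th, ph = th))
  for (sx in c(0, box[1])) for (sy in c(0, box[2])) for (sz in c(0, box[3])) {
    dx <- if (sx == 0) -1 else 1
    dy <- if (sy == 0) -1 else 1
    dz <- if (sz == 0) -1 else 1
    out <- cbind(sx + dx * r * cos(sph[, 1]) * cos(sph[, 2]),
                 sy + dy * r * sin(sph[, 1]) * cos(sph[, 2]),
                 sz + dz * r * sin(sph[, 2]))
    pts[[length(pts) + 1L]] <- out
  }
  wall <- unique(round(do.call(rbind, pts), 4))
  wall[order(wall[, 3], wall[, 2], wall[, 1]), , drop = FALSE]
}

#' Generate a closed-box cavity fixture with analytic volume
#'
#' Builds a closed shell of single-atom (carbon) wall residues sampled on
#' the surface at exactly one van der Waals radius outside the requested
#' box, so that the enclosed empty region is the box itself and the
#' ground-truth volume is the product of the box dimensions (the sampling
#' step leaves a boundary uncertainty of about 0.02 A).
#'
#' @param box interior dimensions in Angstrom (length 3).
#' @param step shell sampling step (default 0.3 A).
#' @return list with \code{model} (single-chain [StructureModel]) and
#'   \code{truth} (\code{volume} = prod(box)).
#' @export
makeCavityFixture <- function(box = c(5, 5, 5), step = 0.3) {
  stopifnot(length(box) == 3, all(box > 0))
  wall <- .boxShellAtoms(box, r = .VDW[["C"]], step = step)
  atoms <- .atomRow("A", seq_len(nrow(wall)), "ALA", "CA", "C",
                    wall[, 1], wall[, 2], wall[, 3])
  list(model = newStructureModel(atoms, entryId = "cavity"),
       truth = list(volume = prod(box)))
}

#' Derive a homolog of a model with known mapping and transform
#'
#' Applies (in order) residue deletions, sequence mutations, Gaussian
#' coordinate noise and a rigid transform to every chain of the model;
#' ligands and waters receive the noise and transform only. The returned
#' truth carries the kept-residue mapping and the planted transform, so
#' tests can verify that superposition and pocket alignment recover them.
#'
#' @param model a [StructureModel].
#' @param mutationRate per-residue substitution probability in [0, 1].
#' @param noiseSigma per-coordinate Gaussian noise (Angstrom).
#' @param deletionRate per-residue deletion probability in [0, 1].
#' @param transform a [RigidTransform] (default: identity).
#' @param seed RNG seed (mandatory).
#' @param entryId identifier of the derived model.
#' @return list with \code{model} and \code{truth} (residue \code{map} with
#'   per-chain kept residue numbers, and \code{transform}).
#' @export
makeHomolog <- function(model, mutationRate = 0, noiseSigma = 0,
                        deletionRate = 0, transform = identityTransform(),
                        seed, entryId = paste0(model@entryId, "_h")) {
  if (missing(seed)) stop("seed is mandatory")
  if (mutationRate < 0 || mutationRate > 1 || deletionRate < 0 || deletionRate > 1)
    stop("rates must lie in [0, 1]")
  .withSeed(seed, {
    a <- model@atoms
    keepRow <- rep(TRUE, nrow(a))
    maps <- list()
    for (ch in chainIds(model)) {
      sel <- a$kind == "polymer" & a$chain == ch
      res <- unique(a[sel, c("resno", "insert")])
      drop <- runif(nrow(res)) < deletionRate
      if (sum(!drop) < 5) drop[] <- FALSE   # keep alignable chains
      gone <- res[drop, , drop = FALSE]
      if (nrow(gone))
        keepRow[sel & paste(a$resno, a$insert) %in%
                  paste(gone$resno, gone$insert)] <- FALSE
      kept <- res[!drop, , drop = FALSE]
      mut <- runif(nrow(kept)) < mutationRate
      for (i in which(mut)) {
        rsel <- sel & a$resno == kept$resno[i] & a$insert == kept$insert[i]
        old <- a$resid[rsel][1]
        a$resid[rsel] <- sample(setdiff(.AA3, old), 1)
      }
      maps[[ch]] <- data.frame(chain = ch, resno = kept$resno,
                               insert = kept$insert, mutated = mut,
                               stringsAsFactors = FALSE)
    }
    a <- a[keepRow, , drop = FALSE]
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (noiseSigma > 0)
      xyz <- xyz + matrix(rnorm(length(xyz), 0, noiseSigma), ncol = 3)
    xyz <- applyTransform(transform, xyz)
    a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
    rownames(a) <- NULL
    hom <- new("StructureModel", entryId = entryId,
               assemblyId = model@assemblyId, provenance = model@provenance,
               atoms = a)
    list(model = hom,
         truth = list(map = do.call(rbind, maps), transform = transform))
  })
}

#' Generate synthetic fingerprint blobs with known labels
#'
#' Builds \code{nBlobs} groups of bit vectors in disjoint bit ranges: within
#' a blob, members share a common core so that all pairwise Tanimoto
#' similarities are at least \code{within}; across blobs the bit sets are
#' disjoint, so similarities are 0 (at most \code{between}).
#'
#' @param nBlobs,membersPerBlob blob layout.
#' @param within minimum within-blob Tanimoto similarity (default 0.9).
#' @param between maximum between-blob similarity (default 0.3; must be
#'   below \code{within}).
#' @param seed RNG seed (mandatory).
#' @param nBits fingerprint length (default 2048).
#' @param coreBits bits per blob core (default 64).
#' @return list with \code{fingerprints} (list of [Fingerprint]) and
#'   \code{labels} (integer blob index per fingerprint).
#' @export
makeFingerprintBlobs <- function(nBlobs, membersPerBlob, within = 0.9,
                                 between = 0.3, seed, nBits = 2048,
                                 coreBits = 64) {
  if (missing(seed)) stop("seed is mandatory")
  if (within <= between) stop("infeasible: within similarity must exceed between")
  flips <- floor(coreBits * (1 - within) / (2 * (1 + within)))
  rangeLen <- coreBits + membersPerBlob * flips + 8
  if (nBlobs * rangeLen > nBits)
    stop("infeasible: bit space too small for the requested blobs")
  .withSeed(seed, {
    fps <- list(); labels <- integer(0)
    for (b in seq_len(nBlobs)) {
      range <- ((b - 1) * rangeLen + 1):(b * rangeLen)
      core <- sort(sample(range, coreBits))
      spare <- setdiff(range, core)
      for (m in seq_len(membersPerBlob)) {
        bits <- core
        if (flips > 0) {
          bits <- setdiff(bits, sample(core, flips))
          add <- sample(spare, flips)
          spare <- setdiff(spare, add)
          bits <- sort(c(bits, add))
        }
        fps[[length(fps) + 1L]] <- new("Fingerprint", bits = as.integer(bits),
                                       nBits = as.integer(nBits),
                                       scheme = "synthetic-blobs-v1",
                                       code = sprintf("B%02dM%02d", b, m))
        labels <- c(labels, b)
      }
    }
    list(fingerprints = fps, labels = labels)
  })
}

#' Random rigid transform
#'
#' Uniform random rotation (via a normalized quaternion) plus a uniform
#' translation in \code{[-shift, shift]^3}; a pure function of the seed.
#'
#' @param seed RNG seed.
#' @param shift translation half-range (Angstrom).
#' @return a [RigidTransform].
#' @export
randomRigidTransform <- function(seed, shift = 15) {
  .withSeed(seed, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
      3, 3, byrow = TRUE)
    new("RigidTransform", rotation = R,
        translation = runif(3, -shift, shift))
  })
}

#' Assemble a synthetic screening benchmark
#'
#' Builds \code{nTargets} interface-cavity dimer fixtures (diverse cavity
#' shapes, each with a distinct planted ligand) and, for each, a
#' remote-homolog template model (sequence mutations at
#' \code{mutationRate}, coordinate noise \code{noiseSigma}, residue
#' deletions, random rigid motion) from which the template library is
#' built. Targets carry their native ligand code and pose as ground truth.
#'
#' @param nTargets number of target dimers.
#' @param seed base RNG seed (mandatory).
#' @param mutationRate,noiseSigma,deletionRate homolog derivation parameters;
#'   the defaults (0.78, 0.5 A, 0.05) emulate remote homologs at roughly 25
#'   percent sequence identity.
#' @param maxIdentity templates are redrawn (fresh mutation seed) until
#'   their measured global sequence identity to both target chains is at
#'   most this bound, so the generated set actually satisfies its stated
#'   remote-homolog condition (at most 8 draws).
#' @return list with \code{targets} (each: model, nativeCode, nativePose)
#'   and \code{library} (list of [TemplateRecord]).
#' @export
makeBenchmarkSet <- function(nTargets = 50, seed = 1, mutationRate = 0.78,
                             noiseSigma = 0.5, deletionRate = 0.05,
                             maxIdentity = 0.29) {
  targets <- list(); library <- list()
  for (i in seq_len(nTargets)) {
    s <- seed * 10000 + i
    code <- sprintf("L%02d", (i - 1) %% 100)
    fx <- makeDimerFixture(
      dimerFixtureSpec(pocketEnclosure = TRUE,
                       boxDims = .withSeed(s, runif(3, 5, 9)),
                       subBoxes = .withSeed(s + 1, sample(0:2, 1)),
                       notches = .withSeed(s + 5, sample(0:2, 1)),
                       wallJitter = 0.45, ligandAtoms = 9,
                       ligandCode = code, seed = s + 2),
      entryId = sprintf("tgt%03d", i))
    dimer <- selectDimer(fx$model)
    hom <- NULL
    for (try in 0:7) {
      cand <- makeHomolog(fx$model, mutationRate = mutationRate,
                          noiseSigma = noiseSigma, deletionRate = deletionRate,
                          transform = randomRigidTransform(s + 3),
                          seed = s + 4 + 101 * try)
      idn <- max(vapply(chainIds(cand$model), function(cc) {
        sq <- getChain(cand$model, cc)@sequence
        max(globalSequenceIdentity(sq, dimer[[1]]@sequence),
            globalSequenceIdentity(sq, dimer[[2]]@sequence))
      }, numeric(1)))
      if (idn <= maxIdentity) { hom <- cand; break }
    }
    if (is.null(hom)) hom <- cand
    recs <- buildTemplateLibrary(list(hom$model), computeExposure = FALSE)
    ## keep only the template whose pocket hosts the planted ligand
    recs <- Filter(function(tr) tr@ligandCode == code, recs)
    targets[[i]] <- list(model = fx$model, nativeCode = code,
                         nativePose = fx$truth$pose)
    library <- c(library, recs)
  }
  list(targets = targets, library = library)
}

#' Generate a library of unrelated pockets for null-model calibration
#'
#' Detects the largest pocket of \code{n} independently seeded
#' diverse-shape cavity fixtures; the resulting pockets are mutually
#' unrelated by construction and serve as draws for [fitNullModel].
#'
#' @param n number of pockets.
#' @param seed base RNG seed.
#' @return list of [Pocket] objects.
#' @export
makeNullPocketSet <- function(n = 40, seed = 7) {
  pockets <- list()
  i <- 0L
  while (length(pockets) < n) {
    i <- i + 1L
    s <- seed * 20000 + i * 7
    fx <- makeDimerFixture(
      dimerFixtureSpec(pocketEnclosure = TRUE,
                       boxDims = .withSeed(s, runif(3, 4.5, 10)),
                       subBoxes = .withSeed(s + 1, sample(0:3, 1)),
                       notches = .withSeed(s + 3, sample(0:2, 1)),
                       wallJitter = 0.45, ligandAtoms = 0, seed = s + 2),
      entryId = sprintf("null%03d", i))
    pk <- detectPockets(fx$model)
    if (length(pk) && nrow(pk[[1]]@lining) >= 5)
      pockets[[length(pockets) + 1L]] <- pk[[1]]
    if (i > 5 * n) stop("could not generate enough null pockets")
  }
  pockets
}

#' Build a labeled feature set for precision calibration
#'
#' Positives are alignments of a target pocket against its own
#' remote-homolog pocket (the pose transfer is correct by construction);
#' negatives are alignments of unrelated pocket pairs. Features are the
#' similarity score and null-model p-value of each alignment.
#'
#' @param nullModel fitted [NullModel] used to assign p-values.
#' @param nPos,nNeg number of positive / negative examples.
#' @param seed base RNG seed.
#' @return data.frame with columns score, pvalue, positive.
#' @export
makeLabeledCalibrationSet <- function(nullModel, nPos = 60, nNeg = 120,
                                      seed = 11) {
  rows <- list()
  i <- 0L
  while (sum(vapply(rows, `[[`, logical(1), "positive")) < nPos &&
         i < 5 * nPos) {
    i <- i + 1L
    s <- seed * 30000 + i * 13
    fx <- makeDimerFixture(
      dimerFixtureSpec(pocketEnclosure = TRUE,
                       boxDims = .withSeed(s, runif(3, 5, 9)),
                       subBoxes = .withSeed(s + 1, sample(0:2, 1)),
                       notches = .withSeed(s + 5, sample(0:2, 1)),
                       wallJitter = 0.45, ligandAtoms = 0, seed = s + 2),
      entryId = sprintf("cal%03d", i))
    hom <- makeHomolog(fx$model, mutationRate = 0.75, noiseSigma = 0.5,
                       deletionRate = 0.05,
                       transform = randomRigidTransform(s + 3), seed = s + 4)
    pq <- detectPockets(fx$model); pt <- detectPockets(hom$model)
    if (!length(pq) || !length(pt)) next
    al <- tryCatch(pocketPvalue(alignPockets(pq[[1]], pt[[1]]), nullModel),
                   error = function(e) NULL)
    if (is.null(al)) next
    rows[[length(rows) + 1L]] <- list(score = al@score, pvalue = al@pvalue,
                                      positive = TRUE)
  }
  nulls <- makeNullPocketSet(max(10, ceiling(sqrt(nNeg)) + 2), seed = seed + 1)
  pairs <- .withSeed(seed + 2, {
    cbind(sample.int(length(nulls), nNeg, replace = TRUE),
          sample.int(length(nulls) - 1L, nNeg, replace = TRUE))
  })
  pairs[, 2] <- ifelse(pairs[, 2] >= pairs[, 1], pairs[, 2] + 1L, pairs[, 2])
  for (k in seq_len(nrow(pairs))) {
    al <- tryCatch(pocketPvalue(
      alignPockets(nulls[[pairs[k, 1]]], nulls[[pairs[k, 2]]]), nullModel),
      error = function(e) NULL)
    if (is.null(al)) next
    rows[[length(rows) + 1L]] <- list(score = al@score, pvalue = al@pvalue,
                                      positive = FALSE)
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
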