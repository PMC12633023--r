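#' @include align.R
NULL

## Deterministic unit-sphere point set (golden-spiral construction).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic test-point SASA: each heavy atom is given a sphere of radius
#' (vdW + probe) sampled at \code{nPoints} deterministic points; the
#' accessible area is the fraction of points not buried inside any
#' neighbouring atom's expanded sphere.
#'
#' @param atoms canonical atom table (heavy atoms).
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param nPoints test points per atom (default 100).
#' @param subset indices of the atoms whose area is wanted (default all);
#'   every atom still occludes, but areas are only computed for the subset.
#' @return numeric vector of per-atom SASA (Angstrom^2), one per subset atom.
#' @export
shrakeRupley <- function(atoms, probe = 1.4, nPoints = 100,
                         subset = seq_len(nrow(atoms))) {
  n <- nrow(atoms)
  if (!n || !length(subset)) return(numeric(0))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .vdwRadius(atoms$elesy) + probe
  pts <- .spherePoints(nPoints)
  out <- numeric(length(subset))
  maxR <- max(rad)
  for (k in seq_along(subset)) {
    i <- subset[k]
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], "-")^2)
    nb <- which(d2 < (rad[i] + maxR)^2 & seq_len(n) != i)
    nb <- nb[d2[nb] < (rad[i] + rad[nb])^2]
    sp <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, nPoints)
      for (j in nb) {
        dj2 <- rowSums(sweep(sp, 2, xyz[j, ], "-")^2)
        free <- free & dj2 > rad[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else frac <- 1
    out[k] <- frac * 4 * pi * rad[i]^2
  }
  out
}

#' Solvent-exposure fraction of a bound ligand
#'
#' SASA of the ligand in the context of the model's polymer atoms divided by
#' its SASA in isolation. Values near 1 mean fully exposed; values near 0
#' mean fully enclosed. Partly exposed monomer-bound ligands are the
#' template mechanism by which a monomer's ligand can nucleate a second
#' protein partner.
#'
#' @param ligand a [LigandInstance].
#' @param model the [StructureModel] providing the protein context.
#' @param probe probe radius in Angstrom.
#' @param nPoints test points per atom.
#' @return exposure fraction in [0, 1].
#' @export
ligandExposureFraction <- function(ligand, model, probe = 1.4, nPoints = 100) {
  la <- ligand@atoms
  if (!nrow(la)) stop("ligand has no atoms")
  iso <- sum(shrakeRupley(la, probe, nPoints))
  if (iso <= 0) return(0)
  prot <- model@atoms[model@atoms$kind == "polymer", , drop = FALSE]
  ctx <- rbind(la[, .ATOM_COLS], prot[, .ATOM_COLS])
  inCtx <- sum(shrakeRupley(ctx, probe, nPoints, subset = seq_len(nrow(la))))
  min(1, max(0, inCtx / iso))
}
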