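#' @include interface.R
NULL

## Per-element van der Waals radii (Angstrom) used for grid occupancy.
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
          CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
.VDW_DEFAULT <- 1.70

.vdwRadius <- function(elesy) {
  r <- .VDW[toupper(elesy)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

## Shift a 3D logical array by one step along an integer direction,
## padding with FALSE.
.shift3 <- function(arr, d) {
  out <- array(FALSE, dim = dim(arr))
  n <- dim(arr)
  src <- dst <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
  for (ax in 1:3) {
    if (d[ax] == 1) { dst[[ax]] <- 2:n[ax]; src[[ax]] <- 1:(n[ax] - 1) }
    else if (d[ax] == -1) { dst[[ax]] <- 1:(n[ax] - 1); src[[ax]] <- 2:n[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

## TRUE for cells that see a protein cell somewhere along +d (exclusive).
.blockedAlong <- function(protein, d, steps) {
  acc <- array(FALSE, dim = dim(protein))
  cur <- protein
  for (s in seq_len(steps)) {
    cur <- .shift3(cur, d)
    if (!any(cur)) break
    acc <- acc | cur
  }
  acc
}

#' Detect cavities on a grid
#'
#' Grid-based cavity detection in the LIGSITE family: the polymer heavy
#' atoms are rasterized onto a cubic grid using per-element van der Waals
#' radii, and an empty cell is a cavity cell when scan lines hit protein on
#' both sides in at least \code{enclosureMin} of 7 direction pairs (the 3
#' axes and 4 body diagonals). Maximal 6-connected sets of cavity cells
#' become pockets. Bound ligands and waters are ignored during
#' rasterization, so a pocket is found whether or not it is occupied.
#'
#' @param model a [StructureModel] with at least one chain.
#' @param spacing grid spacing in Angstrom (default 1.0, valid 0.5 - 2.0).
#' @param probeRadius probe radius in Angstrom (default 1.4); a residue
#'   lines a pocket when one of its heavy atoms lies within
#'   \code{probeRadius + spacing} of a member cell.
#' @param enclosureMin minimum number of enclosing direction pairs (default 5).
#' @return list of [Pocket] objects sorted by decreasing volume. A model
#'   with 3 or fewer atoms yields an empty list.
#' @export
detectPockets <- function(model, spacing = 1.0, probeRadius = 1.4,
                          enclosureMin = 5) {
  stopifnot(spacing >= 0.5, spacing <= 2.0, probeRadius > 0)
  a <- model@atoms[model@atoms$kind == "polymer", , drop = FALSE]
  if (nrow(a) <= 3) return(list())
  if (!length(chainIds(model))) stop("model must have at least one chain")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- .vdwRadius(a$elesy)
  margin <- max(rad) + spacing
  origin <- apply(xyz, 2, min) - margin
  dims <- ceiling((apply(xyz, 2, max) + margin - origin) / spacing) + 1L
  protein <- array(FALSE, dim = dims)

  ## rasterize: mark every cell whose center lies within vdW radius of an atom
  for (i in seq_len(nrow(xyz))) {
    r <- rad[i]
    lo <- pmax(1L, floor((xyz[i, ] - r - origin) / spacing) + 1L)
    hi <- pmin(dims, ceiling((xyz[i, ] + r - origin) / spacing) + 1L)
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    cx <- origin[1] + (ix - 1) * spacing
    cy <- origin[2] + (iy - 1) * spacing
    cz <- origin[3] + (iz - 1) * spacing
    d2 <- outer(outer((cx - xyz[i, 1])^2, (cy - xyz[i, 2])^2, "+"),
                (cz - xyz[i, 3])^2, "+")
    protein[ix, iy, iz] <- protein[ix, iy, iz] | (d2 <= r * r)
  }

  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  steps <- max(dims)
  enclosure <- array(0L, dim = dims)
  for (d in dirs) {
    fwd <- .blockedAlong(protein, d, steps)
    bwd <- .blockedAlong(protein, -d, steps)
    enclosure <- enclosure + (fwd & bwd)
  }
  cavity <- !protein & enclosure >= enclosureMin
  if (!any(cavity)) return(list())

  ## 6-connected components of cavity cells
  lin <- which(cavity)
  pos <- arrayInd(lin, dims)
  id <- seq_along(lin)
  index <- array(0L, dim = dims)
  index[lin] <- id
  edges <- NULL
  for (ax in 1:3) {
    nb <- pos
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= dims[ax]
    nbl <- index[nb[ok, , drop = FALSE]]
    has <- nbl > 0L
    if (any(has)) edges <- rbind(edges, cbind(id[ok][has], nbl[has]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(id) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(id)]

  centers <- sweep((pos - 1) * spacing, 2, origin, "+")
  colnames(centers) <- c("x", "y", "z")
  polymerRes <- .residueKeyTable(a)
  caSel <- a$elety == "CA"
  pockets <- lapply(split(seq_along(id), comp), function(ii) {
    cells <- centers[ii, , drop = FALSE]
    lining <- .pocketLining(cells, a, polymerRes, probeRadius + spacing)
    new("Pocket", id = "P", cells = cells, spacing = spacing,
        volume = length(ii) * spacing^3,
        centroid = colMeans(cells), lining = lining,
        interfaceAdjacent = NA)
  })
  ## deterministic order: decreasing volume, ties by centroid
  ord <- order(-vapply(pockets, function(p) p@volume, 1),
               vapply(pockets, function(p) p@centroid[1], 1),
               vapply(pockets, function(p) p@centroid[2], 1),
               vapply(pockets, function(p) p@centroid[3], 1))
  pockets <- pockets[ord]
  for (i in seq_along(pockets)) pockets[[i]]@id <- paste0("P", i)
  pockets
}

## Residues with a heavy atom within `cut` of any member cell, with their
## representative (C-alpha when present) coordinates for alignment.
.pocketLining <- function(cells, atoms, resKey, cut) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  bb <- apply(cells, 2, range)
  inBox <- xyz[, 1] >= bb[1, 1] - cut & xyz[, 1] <= bb[2, 1] + cut &
           xyz[, 2] >= bb[1, 2] - cut & xyz[, 2] <= bb[2, 2] + cut &
           xyz[, 3] >= bb[1, 3] - cut & xyz[, 3] <= bb[2, 3] + cut
  near <- logical(nrow(resKey$table))
  if (any(inBox)) {
    sub <- which(inBox)
    d2 <- .crossMinDist2(xyz[sub, , drop = FALSE], cells)
    hit <- sub[d2 <= cut * cut]
    near[unique(resKey$idx[hit])] <- TRUE
  }
  tab <- resKey$table[near, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(chain = character(), resno = integer(), insert = character(),
                      resid = character(), aa = character(), x = numeric(),
                      y = numeric(), z = numeric(), stringsAsFactors = FALSE))
  }
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  tkey <- paste(tab$chain, tab$resno, tab$insert, sep = "\r")
  rep <- vapply(tkey, function(k) {
    rows <- which(key == k)
    ca <- rows[atoms$elety[rows] == "CA"]
    if (length(ca)) ca[1] else rows[1]
  }, 1L)
  aa <- suppressWarnings(bio3d::aa321(tab$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out <- data.frame(chain = tab$chain, resno = tab$resno, insert = tab$insert,
                    resid = tab$resid, aa = aa,
                    x = atoms$x[rep], y = atoms$y[rep], z = atoms$z[rep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno, out$insert), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Minimum squared distance from each row of A to any row of B, chunked.
.crossMinDist2 <- function(A, B) {
  out <- rep(Inf, nrow(A))
  step <- max(1L, floor(2e6 / max(1L, nrow(B))))
  for (s in seq(1L, nrow(A), by = step)) {
    e <- min(nrow(A), s + step - 1L)
    chunk <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(chunk^2), rowSums(B^2), "+") - 2 * chunk %*% t(B)
    out[s:e] <- pmax(0, apply(d2, 1, min))
  }
  out
}

#' Library filter for template pockets
#'
#' A pocket enters the template library when it has at least
#' \code{minResidues} lining residues and a volume of at least
#' \code{minVolume} cubic Angstrom.
#'
#' @param pocket a [Pocket].
#' @param minResidues minimum lining residue count (default 10).
#' @param minVolume minimum volume in Angstrom^3 (default 100).
#' @return logical.
#' @export
passesLibraryFilter <- function(pocket, minResidues = 10, minVolume = 100) {
  nrow(pocket@lining) >= minResidues && pocket@volume >= minVolume
}

#' Interface adjacency of a pocket
#'
#' A pocket is interface-adjacent when its lining residues include at least
#' one interface residue from each chain of the dimer.
#'
#' @param pocket a [Pocket].
#' @param summary an [InterfaceSummary] from the same model.
#' @return logical.
#' @export
isInterfaceAdjacent <- function(pocket, summary) {
  l <- pocket@lining
  if (!nrow(l)) return(FALSE)
  lkey <- paste(l$chain, l$resno, l$insert, sep = "\r")
  akey <- paste(summary@residuesA$chain, summary@residuesA$resno,
                summary@residuesA$insert, sep = "\r")
  bkey <- paste(summary@residuesB$chain, summary@residuesB$resno,
                summary@residuesB$insert, sep = "\r")
  any(lkey %in% akey) && any(lkey %in% bkey)
}

#' Flag interface adjacency on a pocket list
#'
#' @param pockets list of [Pocket] objects.
#' @param summary an [InterfaceSummary] from the same model.
#' @return the pocket list with the adjacency flag set.
#' @export
flagInterfaceAdjacency <- function(pockets, summary) {
  lapply(pockets, function(p) {
    p@interfaceAdjacent <- isInterfaceAdjacent(p, summary)
    p
  })
}

#' Write a pocket report TSV
#'
#' @param pockets list of [Pocket] objects.
#' @param path output path.
#' @return invisibly, the report data.frame.
#' @export
writePocketTsv <- function(pockets, path) {
  rep <- do.call(rbind, lapply(pockets, function(p) {
    data.frame(id = p@id, volume = p@volume, residues = nrow(p@lining),
               interfaceAdjacent = p@interfaceAdjacent,
               lining = paste(paste0(p@lining$chain, ":", p@lining$resno),
                              collapse = ","),
               stringsAsFactors = FALSE)
  }))
  write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
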