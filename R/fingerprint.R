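#' @include screen.R
NULL

#' Construct a molecular graph
#'
#' @param elements element symbol per heavy atom.
#' @param bonds data.frame with columns \code{from}, \code{to} (1-based
#'   atom indices) and \code{order} (integer bond order).
#' @param code ligand code to carry along.
#' @return a [MolGraph].
#' @export
makeMolGraph <- function(elements, bonds = data.frame(from = integer(),
                                                      to = integer(),
                                                      order = integer()),
                         code = "LIG") {
  new("MolGraph", elements = toupper(elements),
      bonds = data.frame(from = as.integer(bonds$from),
                         to = as.integer(bonds$to),
                         order = as.integer(bonds$order)),
      code = code)
}

.molFromAtomBond <- function(ab, bb, code) {
  elements <- toupper(sub("_.*$", "", rownames(ab)))
  bonds <- if (is.null(bb) || !nrow(bb))
    data.frame(from = integer(), to = integer(), order = integer())
  else data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                  order = as.integer(bb[, 3]))
  ## drop hydrogens, remapping bond indices
  keep <- which(!elements %in% c("H", "D"))
  map <- match(seq_along(elements), keep)
  bonds <- bonds[!is.na(map[bonds$from]) & !is.na(map[bonds$to]), , drop = FALSE]
  bonds$from <- map[bonds$from]; bonds$to <- map[bonds$to]
  makeMolGraph(elements[keep], bonds, code)
}

#' Read molecular graphs from a component dictionary
#'
#' \code{molFromSmiles} parses a SMILES string (via ChemmineOB),
#' \code{readComponentDictionary} reads an SDF file or a two-column
#' SMILES/code text file into a named list of [MolGraph] objects.
#'
#' @param smiles a SMILES string.
#' @param code ligand code.
#' @return a [MolGraph] (or a named list of them).
#' @export
molFromSmiles <- function(smiles, code = "LIG") {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineR/ChemmineOB required to parse SMILES")
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  .molFromAtomBond(ChemmineR::atomblock(sdf), ChemmineR::bondblock(sdf), code)
}

#' @rdname molFromSmiles
#' @param path SDF file or two-column (smiles, code) whitespace-separated file.
#' @export
readComponentDictionary <- function(path) {
  if (grepl("\\.sdf?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
      stop("ChemmineR required to parse SDF")
    set <- ChemmineR::read.SDFset(path)
    out <- lapply(seq_along(set), function(i) {
      sdf <- set[[i]]
      .molFromAtomBond(ChemmineR::atomblock(sdf), ChemmineR::bondblock(sdf),
                       ChemmineR::sdfid(set[i]))
    })
    names(out) <- vapply(out, function(m) m@code, "")
    return(out)
  }
  tab <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    molFromSmiles(tab[i, 1], tab[i, 2]))
  names(out) <- tab[, 2]
  out
}

## 32-bit FNV-1a over a character string, in double arithmetic (R has no
## unsigned 32-bit integers); multiplication is split into 16-bit halves.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), bitwAnd(as.integer(b), 255L))
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h
}

## All simple linear paths of up to maxPath bonds, as canonical
## element/bond-order token strings (lexicographic min of the two reading
## directions).
.enumeratePaths <- function(mol, maxPath) {
  elements <- mol@elements
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(mol@bonds)) {
    for (k in seq_len(nrow(mol@bonds))) {
      f <- mol@bonds$from[k]; t <- mol@bonds$to[k]; o <- mol@bonds$order[k]
      adj[[f]] <- rbind(adj[[f]], c(t, o))
      adj[[t]] <- rbind(adj[[t]], c(f, o))
    }
  }
  paths <- character(0)
  walk <- function(path, tokens) {
    fwd <- paste(tokens, collapse = "")
    rev <- paste(rev(tokens), collapse = "")
    paths[[length(paths) + 1L]] <<- if (fwd <= rev) fwd else rev
    if (length(path) > maxPath) return()
    a <- adj[[path[length(path)]]]
    if (is.null(a)) return()
    for (r in seq_len(nrow(a))) {
      nxt <- a[r, 1]
      if (nxt %in% path) next
      walk(c(path, nxt), c(tokens, a[r, 2], elements[nxt]))
    }
  }
  for (start in seq_len(n)) walk(start, elements[start])
  unique(paths)
}

.FP_SCHEME <- "fnv1a-linear-paths-v1"

#' Path-based molecular fingerprint
#'
#' Enumerates all linear atom paths of up to \code{maxPath} bonds in the
#' molecular graph (each path read in its canonical direction, labelled by
#' element symbols and bond orders) and hashes each distinct path into a
#' fixed-length bit vector — the folded path-fingerprint family
#' popularized by the Daylight toolkit. Deterministic: the hash function and
#' parameters are recorded in the scheme identifier.
#'
#' @param mol a [MolGraph] with at least one atom.
#' @param maxPath maximum path length in bonds (default 7).
#' @param nBits bit-vector length (default 2048).
#' @return a [Fingerprint].
#' @export
pathFingerprint <- function(mol, maxPath = 7, nBits = 2048) {
  if (!length(mol@elements)) stop("empty molecule")
  paths <- .enumeratePaths(mol, maxPath)
  bits <- sort(unique(vapply(paths, function(p) as.integer(.fnv1a(p) %% nBits) + 1L,
                             integer(1), USE.NAMES = FALSE)))
  new("Fingerprint", bits = bits, nBits = as.integer(nBits),
      scheme = sprintf("%s/maxPath=%d", .FP_SCHEME, maxPath), code = mol@code)
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over the set bits; symmetric, bounded in
#' [0, 1], and 1 for identical fingerprints.
#'
#' @param a,b [Fingerprint] objects of equal bit length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (a@nBits != b@nBits) stop("fingerprint bit lengths differ")
  inter <- length(intersect(a@bits, b@bits))
  uni <- length(union(a@bits, b@bits))
  if (!uni) return(0)
  inter / uni
}

#' Threshold (Butina leader) clustering of fingerprints
#'
#' Classic leader clustering: fingerprints are sorted by their number of
#' neighbours at the similarity threshold (ties by ligand code, then input
#' order); the best-connected unassigned fingerprint becomes a leader and
#' absorbs its unassigned neighbours, until everything is assigned. The
#' result is a partition; the centroid of each cluster is the member with
#' the highest mean similarity to its cluster (ties by code order).
#'
#' @param fingerprints non-empty list of [Fingerprint] objects.
#' @param threshold Tanimoto threshold (default 0.8).
#' @return a [ClusterResult].
#' @export
thresholdCluster <- function(fingerprints, threshold = 0.8) {
  n <- length(fingerprints)
  if (!n) stop("at least one fingerprint required")
  codes <- vapply(fingerprints, function(f) f@code, "")
  sim <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s <- tanimoto(fingerprints[[i]], fingerprints[[j]])
      sim[i, j] <- sim[j, i] <- s
    }
  }
  nb <- lapply(seq_len(n), function(i) setdiff(which(sim[i, ] >= threshold), i))
  counts <- lengths(nb)
  ord <- order(-counts, codes, seq_len(n))
  assigned <- rep(FALSE, n)
  members <- list()
  for (i in ord) {
    if (assigned[i]) next
    cl <- c(i, nb[[i]][!assigned[nb[[i]]]])
    assigned[cl] <- TRUE
    members[[length(members) + 1L]] <- sort(cl)
  }
  cents <- vapply(members, function(cl) {
    if (length(cl) == 1) return(codes[cl])
    meanSim <- vapply(cl, function(i) mean(sim[i, setdiff(cl, i)]), numeric(1))
    best <- cl[order(-meanSim, codes[cl])][1]
    codes[best]
  }, "")
  new("ClusterResult", clusters = lapply(members, function(cl) codes[cl]),
      centroids = cents, threshold = threshold)
}

#' Write a cluster report TSV
#'
#' One row per cluster: id, size, centroid code, member codes.
#'
#' @param result a [ClusterResult].
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
writeClusterTsv <- function(result, path) {
  df <- data.frame(
    cluster = seq_along(result@clusters),
    size = lengths(result@clusters),
    centroid = result@centroids,
    members = vapply(result@clusters, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$centroid), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
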