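#' @include AllClasses.R AllGenerics.R
NULL

## Water residue codes and metal element symbols recognized during
## partitioning. Metals follow the single-atom-HETATM-of-metal-element rule.
.WATER_CODES <- c("HOH", "WAT", "DOD", "H2O")
.METAL_ELEMENTS <- c("LI", "NA", "K", "RB", "CS", "BE", "MG", "CA", "SR", "BA",
                     "MN", "FE", "CO", "NI", "CU", "ZN", "CD", "HG", "AL", "GA",
                     "IN", "TL", "PB", "V", "CR", "MO", "W", "PT", "PD", "AU",
                     "AG", "OS", "IR", "RU", "RH", "SN", "SB", "BI")
## Modified residues kept in the polymer (never treated as ligands) when they
## occur as HETATM records inside a chain; selenomethionine is the canonical case.
.MODIFIED_POLYMER <- c("MSE", "SEP", "TPO", "PTR", "CSO", "MLY", "HYP", "KCX",
                       "CME", "CSD", "PCA", "SEC", "PYL")

.guessElement <- function(elety, elesy) {
  out <- toupper(ifelse(is.na(elesy) | elesy == "", NA, elesy))
  fix <- is.na(out)
  if (any(fix)) {
    nm <- gsub("[0-9'\\*]", "", toupper(elety[fix]))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    out[fix] <- ifelse(two %in% .METAL_ELEMENTS, two, one)
  }
  out
}

.emptyAtoms <- function() {
  data.frame(chain = character(), resno = integer(), insert = character(),
             resid = character(), elety = character(), elesy = character(),
             x = numeric(), y = numeric(), z = numeric(), occ = numeric(),
             het = logical(), kind = character(), metal = logical(),
             stringsAsFactors = FALSE)
}

## Build the canonical atom table from a bio3d atom data.frame: drop
## hydrogens, resolve alternate locations (highest occupancy, ties by altloc
## order), and partition atoms into polymer / ligand / water.
.canonicalAtoms <- function(at) {
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$chain <- ifelse(is.na(at$chain), "A", at$chain)
  at$o <- ifelse(is.na(at$o), 1, pmin(pmax(at$o, 0), 1))
  elesy <- .guessElement(at$elety, at$elesy)
  keep <- !(elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  elesy <- elesy[keep]
  if (!nrow(at)) return(.emptyAtoms())

  ## alternate locations: one conformer per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  elesy <- elesy[ord]
  dup <- duplicated(key[ord])
  at <- at[!dup, , drop = FALSE]
  elesy <- elesy[!dup]
  ## restore file order
  ro <- order(at$eleno)
  at <- at[ro, , drop = FALSE]
  elesy <- elesy[ro]

  isWater <- at$resid %in% .WATER_CODES
  isPolymer <- (at$type == "ATOM" | at$resid %in% .MODIFIED_POLYMER) & !isWater
  kind <- ifelse(isWater, "water", ifelse(isPolymer, "polymer", "ligand"))

  out <- data.frame(chain = at$chain, resno = as.integer(at$resno),
                    insert = at$insert, resid = at$resid, elety = at$elety,
                    elesy = elesy, x = at$x, y = at$y, z = at$z, occ = at$o,
                    het = at$type == "HETATM", kind = kind, metal = FALSE,
                    stringsAsFactors = FALSE)

  ## single-atom hetero groups of a metal element are metals
  lig <- out$kind == "ligand"
  if (any(lig)) {
    grp <- paste(out$chain, out$resno, out$insert, out$resid, sep = "\r")
    sizes <- table(grp[lig])
    single <- lig & grp %in% names(sizes)[sizes == 1] & out$elesy %in% .METAL_ELEMENTS
    out$metal[single] <- TRUE
  }
  out
}

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a [StructureModel]: polymer chains,
#' ligand instances and waters are partitioned, hydrogens are dropped, for
#' alternate locations only the highest-occupancy conformer is kept (ties
#' broken by altloc identifier order), and selenomethionine (and other
#' common covalently linked modified residues) stays in the polymer.
#'
#' No symmetry expansion is performed; the deposited coordinates are used and
#' the requested assembly policy is recorded on the model.
#'
#' @param path path to the structure file.
#' @param format \code{"pdb"}, \code{"mmcif"}, or \code{"auto"} (by extension).
#' @param assemblyPolicy \code{"assembly_1"} (default) or \code{"asymmetric_unit"}.
#' @param provenance \code{"experimental"} (default) or \code{"predicted"}.
#' @return a [StructureModel].
#' @examples
#' fx <- makeDimerFixture(dimerFixtureSpec(seed = 1))
#' path <- tempfile(fileext = ".pdb")
#' writeStructurePdb(fx$model, path)
#' model <- readStructure(path)
#' chainIds(model)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          assemblyPolicy = c("assembly_1", "asymmetric_unit"),
                          provenance = c("experimental", "predicted")) {
  format <- match.arg(format)
  assemblyPolicy <- match.arg(assemblyPolicy)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE, multi = FALSE),
    error = function(e) stop("cannot parse ", format, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  atoms <- .canonicalAtoms(parsed$atom)
  if (!nrow(atoms)) stop("empty structure: no heavy atoms in '", path, "'")
  new("StructureModel",
      entryId = sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE),
      assemblyId = if (assemblyPolicy == "assembly_1") "1" else "asu",
      provenance = provenance, atoms = atoms)
}

#' Construct a StructureModel from an atom table
#'
#' Used by the synthetic-fixture generators and by callers that assemble
#' coordinates programmatically. Columns absent from \code{atoms} are filled
#' with defaults; partition flags (\code{kind}, \code{metal}) are taken as
#' given.
#'
#' @param atoms canonical atom table (see [StructureModel]).
#' @param entryId,assemblyId,provenance model metadata.
#' @return a [StructureModel].
#' @export
newStructureModel <- function(atoms, entryId = "model", assemblyId = "asu",
                              provenance = c("experimental", "predicted")) {
  provenance <- match.arg(provenance)
  defaults <- list(insert = "", occ = 1, het = FALSE, metal = FALSE,
                   elesy = NA_character_, elety = "CA", resid = "ALA",
                   kind = "polymer")
  for (col in names(defaults)) {
    if (is.null(atoms[[col]])) atoms[[col]] <- defaults[[col]]
  }
  bad <- is.na(atoms$elesy)
  if (any(bad)) atoms$elesy[bad] <- .guessElement(atoms$elety[bad], NA)[seq_len(sum(bad))]
  atoms$resno <- as.integer(atoms$resno)
  atoms <- atoms[, .ATOM_COLS]
  new("StructureModel", entryId = entryId, assemblyId = assemblyId,
      provenance = provenance, atoms = atoms)
}

#' Extract one polymer chain
#'
#' @param model a [StructureModel].
#' @param id chain identifier.
#' @return a [Chain] with ordered polymer residues and one-letter sequence.
#' @export
getChain <- function(model, id) {
  a <- model@atoms
  sel <- a$kind == "polymer" & a$chain == id
  if (!any(sel)) stop("no polymer chain '", id, "' in model ", model@entryId)
  ca <- a[sel, , drop = FALSE]
  res <- unique(ca[, c("chain", "resno", "insert", "resid")])
  res <- res[order(res$resno, res$insert), , drop = FALSE]
  rownames(res) <- NULL
  aa <- suppressWarnings(bio3d::aa321(res$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  res$aa <- aa
  new("Chain", id = id, residues = res, sequence = paste(aa, collapse = ""),
      atoms = ca)
}

#' Select the two chains of a dimer
#'
#' Returns the two polymer chains of the model in input order; any other
#' polymer chain count is an error (only dimers are analyzed).
#'
#' @param model a [StructureModel].
#' @return list of two [Chain] objects.
#' @export
selectDimer <- function(model) {
  ids <- chainIds(model)
  if (length(ids) != 2)
    stop("not a dimer: model ", model@entryId, " has ", length(ids),
         " polymer chain(s)")
  list(getChain(model, ids[1]), getChain(model, ids[2]))
}

.poseAtoms <- function(pose) {
  if (is(pose, "LigandInstance")) pose@atoms
  else if (is.data.frame(pose)) pose
  else stop("pose must be a LigandInstance or an atom table")
}

#' Write a ligand pose
#'
#' Writes a ligand pose as a PDB (HETATM records, via bio3d) or as a V2000
#' SD file. Poses carry no bond information, so SDF output has an empty bond
#' block; coordinates round-trip to the 0.001 A precision of both formats.
#'
#' @param pose a [LigandInstance] or canonical atom table.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"sdf"}.
#' @return the path, invisibly.
#' @export
writePose <- function(pose, path, format = c("pdb", "sdf")) {
  format <- match.arg(format)
  at <- .poseAtoms(pose)
  if (!nrow(at)) stop("empty pose")
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("pose coordinates must be finite")
  code <- if (is(pose, "LigandInstance")) pose@code else at$resid[1]
  if (format == "pdb") {
    ok <- tryCatch({
      bio3d::write.pdb(file = path,
                       xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                       type = rep("HETATM", nrow(at)),
                       resno = at$resno, resid = at$resid, chain = at$chain,
                       insert = at$insert, elety = at$elety, elesy = at$elesy,
                       o = at$occ, b = rep(0, nrow(at)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("cannot write pose to '", path, "'")
  } else {
    n <- nrow(at)
    lines <- c(code, "  iapScreen pose export", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, 0L),
               sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       at$x, at$y, at$z,
                       paste0(substr(at$elesy, 1, 1),
                              tolower(substr(at$elesy, 2, 2)))),
               "M  END", "$$$$")
    ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE)
    if (!ok) stop("cannot write pose to '", path, "'")
  }
  invisible(path)
}

#' Read a ligand pose written by [writePose]
#'
#' @param path input file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"sdf"}.
#' @return a [LigandInstance].
#' @export
readPose <- function(path, format = c("auto", "pdb", "sdf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.sdf?$", path, ignore.case = TRUE)) "sdf" else "pdb"
  if (format == "pdb") {
    m <- readStructure(path, format = "pdb")
    lg <- ligands(m, includeWaters = TRUE)
    if (!length(lg)) stop("no hetero group found in '", path, "'")
    return(lg[[1]])
  }
  lines <- readLines(path)
  n <- as.integer(substr(lines[4], 1, 3))
  block <- lines[5:(4 + n)]
  at <- data.frame(
    chain = "L", resno = 1L, insert = "", resid = lines[1],
    elety = toupper(trimws(substr(block, 32, 34))),
    elesy = toupper(trimws(substr(block, 32, 34))),
    x = as.numeric(substr(block, 1, 10)),
    y = as.numeric(substr(block, 11, 20)),
    z = as.numeric(substr(block, 21, 30)),
    occ = 1, het = TRUE, kind = "ligand", metal = FALSE,
    stringsAsFactors = FALSE)
  new("LigandInstance", code = lines[1], chain = "L", resno = 1L, insert = "",
      atoms = at, metal = FALSE, water = FALSE)
}

#' Write a full model as PDB
#'
#' Convenience writer used by the fixture generators and the CLI; polymer
#' atoms become ATOM records and ligand/water atoms HETATM records.
#'
#' @param model a [StructureModel].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructurePdb <- function(model, path) {
  a <- model@atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$kind == "polymer" & !a$het, "ATOM", "HETATM"),
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   insert = a$insert, elety = a$elety, elesy = a$elesy,
                   o = a$occ, b = rep(0, nrow(a)))
  invisible(path)
}

#' @rdname accessors
#' @param includeWaters also return water groups (default FALSE).
#' @export
setMethod("ligands", "StructureModel", function(x, includeWaters = FALSE) {
  a <- x@atoms
  sel <- a$kind == "ligand" | (includeWaters & a$kind == "water")
  if (!any(sel)) return(list())
  h <- a[sel, , drop = FALSE]
  grp <- paste(h$chain, h$resno, h$insert, h$resid, sep = "\r")
  idx <- split(seq_len(nrow(h)), grp)
  ## preserve file order of first occurrence
  idx <- idx[order(vapply(idx, min, 1L))]
  lapply(idx, function(i) {
    at <- h[i, , drop = FALSE]
    rownames(at) <- NULL
    new("LigandInstance", code = at$resid[1], chain = at$chain[1],
        resno = at$resno[1], insert = at$insert[1], atoms = at,
        metal = all(at$metal), water = at$kind[1] == "water")
  })
})
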