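#' @include structure-io.R
NULL

.residueKeyTable <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  fac <- factor(key, levels = unique(key))
  list(idx = as.integer(fac),
       table = atoms[!duplicated(key), c("chain", "resno", "insert", "resid"),
                     drop = FALSE])
}

#' Residue-residue contact map between two chains
#'
#' A residue pair is a contact when its minimum heavy-atom distance is at
#' most \code{cutoff}. The default 4.5 A is the standard heavy-atom contact
#' criterion; the result is symmetric under chain swap.
#'
#' @param chainA,chainB [Chain] objects.
#' @param cutoff heavy-atom distance cutoff in Angstrom (> 0).
#' @return data.frame with one row per contacting residue pair: the residue
#'   identities of both chains and the minimum heavy-atom distance.
#' @export
residueContactMap <- function(chainA, chainB, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  a <- chainA@atoms; b <- chainB@atoms
  if (!nrow(a) || !nrow(b)) stop("chains must be non-empty")
  ka <- .residueKeyTable(a); kb <- .residueKeyTable(b)
  hits <- .residue_contacts_cpp(as.matrix(a[, c("x", "y", "z")]), ka$idx,
                                as.matrix(b[, c("x", "y", "z")]), kb$idx,
                                cutoff, nrow(ka$table), nrow(kb$table))
  ra <- ka$table[hits$ia, , drop = FALSE]
  rb <- kb$table[hits$ib, , drop = FALSE]
  out <- data.frame(chainA = ra$chain, resnoA = ra$resno, insertA = ra$insert,
                    residA = ra$resid, chainB = rb$chain, resnoB = rb$resno,
                    insertB = rb$insert, residB = rb$resid, dist = hits$dist,
                    stringsAsFactors = FALSE)
  out <- out[order(out$resnoA, out$insertA, out$resnoB, out$insertB), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interface residue sets of a dimer
#'
#' Projects the residue contact map onto each chain: a residue is part of
#' the interface iff it participates in at least one inter-chain contact.
#'
#' @param dimer list of two [Chain] objects (as from [selectDimer]).
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @return an [InterfaceSummary].
#' @export
interfaceResidueSets <- function(dimer, cutoff = 4.5) {
  pairs <- residueContactMap(dimer[[1]], dimer[[2]], cutoff)
  resA <- unique(pairs[, c("chainA", "resnoA", "insertA")])
  resB <- unique(pairs[, c("chainB", "resnoB", "insertB")])
  names(resA) <- names(resB) <- c("chain", "resno", "insert")
  rownames(resA) <- rownames(resB) <- NULL
  new("InterfaceSummary", chainA = dimer[[1]]@id, chainB = dimer[[2]]@id,
      residuesA = resA, residuesB = resB, pairs = pairs, cutoff = cutoff)
}

#' Dimer qualification rule
#'
#' A dimer qualifies when each chain contributes at least
#' \code{minPerChain} residues to the protein-protein interface.
#'
#' @param summary an [InterfaceSummary].
#' @param minPerChain minimum interface residues per chain (default 5).
#' @return logical.
#' @export
qualifiesAsDimer <- function(summary, minPerChain = 5) {
  nrow(summary@residuesA) >= minPerChain && nrow(summary@residuesB) >= minPerChain
}

#' Number of chain residues contacted by a ligand
#'
#' Counts the distinct polymer residues of \code{chain} with minimum
#' heavy-atom distance to any ligand atom at most \code{cutoff}.
#'
#' @param ligand a [LigandInstance].
#' @param chain a [Chain].
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @return integer count of distinct contacted residues.
#' @export
ligandChainContacts <- function(ligand, chain, cutoff = 4.5) {
  la <- ligand@atoms
  if (!nrow(la)) stop("ligand must be non-empty")
  ca <- chain@atoms
  kc <- .residueKeyTable(ca)
  hits <- .residue_contacts_cpp(as.matrix(la[, c("x", "y", "z")]),
                                rep(1L, nrow(la)),
                                as.matrix(ca[, c("x", "y", "z")]), kc$idx,
                                cutoff, 1L, nrow(kc$table))
  length(unique(hits$ib))
}

#' Classify a ligand against a dimer interface
#'
#' Applies the interface-adjacent-pocket ligand rule: a ligand is classified
#' \code{"iap"} when it contacts at least \code{minPerChain} distinct
#' residues on each chain of the dimer, \code{"single_chain"} when exactly
#' one chain meets the threshold, and \code{"non_binder"} otherwise. Waters
#' are never classified.
#'
#' @param ligand a [LigandInstance] (not a water).
#' @param dimer list of two [Chain] objects.
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @param minPerChain minimum contacted residues per chain (default 5).
#' @param entryId entry identifier recorded on the result.
#' @return one-row data.frame (an IAP record): code, entry, chain, resno,
#'   countA, countB, classification, metal, element.
#' @export
classifyLigand <- function(ligand, dimer, cutoff = 4.5, minPerChain = 5,
                           entryId = NA_character_) {
  if (ligand@water) stop("waters are never classified as glue candidates")
  ca <- ligandChainContacts(ligand, dimer[[1]], cutoff)
  cb <- ligandChainContacts(ligand, dimer[[2]], cutoff)
  meets <- c(ca, cb) >= minPerChain
  cls <- if (all(meets)) "iap" else if (any(meets)) "single_chain" else "non_binder"
  data.frame(code = ligand@code, entry = entryId, chain = ligand@chain,
             resno = ligand@resno, countA = ca, countB = cb,
             classification = cls, metal = ligand@metal,
             element = if (ligand@metal) ligand@atoms$elesy[1] else NA_character_,
             stringsAsFactors = FALSE)
}

#' Build an IAP ligand catalog over a stream of dimers
#'
#' Classifies every non-water ligand instance of every qualifying dimer and
#' aggregates per-code frequency histograms (metals tallied separately) and
#' the fraction of all classified ligands that bridge the interface.
#' Per-model failures (parse errors, chain count other than two, interfaces
#' below the dimer rule) are logged and skipped, never fatal.
#'
#' @param models list of [StructureModel] objects and/or structure file paths.
#' @param cutoff heavy-atom contact cutoff in Angstrom.
#' @param minPerChain minimum residues per chain for both the dimer rule and
#'   the ligand rule (default 5).
#' @return an [IAPCatalog].
#' @export
buildCatalog <- function(models, cutoff = 4.5, minPerChain = 5) {
  records <- list()
  skipped <- character()
  for (m in models) {
    rec <- tryCatch({
      model <- if (is.character(m)) readStructure(m) else m
      dimer <- selectDimer(model)
      summ <- interfaceResidueSets(dimer, cutoff)
      if (!qualifiesAsDimer(summ, minPerChain))
        stop("interface below the ", minPerChain, "-residue-per-chain rule")
      lg <- ligands(model)
      if (!length(lg)) NULL
      else do.call(rbind, lapply(lg, classifyLigand, dimer = dimer,
                                 cutoff = cutoff, minPerChain = minPerChain,
                                 entryId = entryId(model)))
    }, error = function(e) {
      skipped <<- c(skipped, paste0(if (is.character(m)) m else entryId(m),
                                    ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(code = character(), entry = character(), chain = character(),
               resno = integer(), countA = integer(), countB = integer(),
               classification = character(), metal = logical(),
               element = character(), stringsAsFactors = FALSE)
  rownames(records) <- NULL
  iap <- records[records$classification == "iap", , drop = FALSE]
  hist <- sort(table(iap$code[!iap$metal]), decreasing = TRUE)
  mhist <- sort(table(iap$element[iap$metal]), decreasing = TRUE)
  new("IAPCatalog", records = records,
      histogram = setNames(as.integer(hist), names(hist)),
      metalHistogram = setNames(as.integer(mhist), names(mhist)),
      iapFraction = if (nrow(records)) nrow(iap) / nrow(records) else NA_real_,
      skipped = skipped)
}

#' Write catalog TSV reports
#'
#' Emits the per-ligand record table and the frequency histogram of
#' interface-bridging ligand codes as tab-separated files.
#'
#' @param catalog an [IAPCatalog].
#' @param recordsPath,histogramPath output paths (NULL to skip either).
#' @return invisibly, the catalog.
#' @export
writeCatalogTsv <- function(catalog, recordsPath = NULL, histogramPath = NULL) {
  if (!is.null(recordsPath))
    write.table(catalog@records, recordsPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(histogramPath))
    write.table(data.frame(code = names(catalog@histogram),
                           count = as.integer(catalog@histogram)),
                histogramPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(catalog)
}
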