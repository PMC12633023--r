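#' @include calibration.R
NULL

#' Build a template pocket/ligand library
#'
#' For every model in the stream, detects pockets, keeps those passing the
#' library filter (at least \code{minResidues} lining residues and
#' \code{minVolume} cubic Angstrom), and pairs each qualifying pocket with
#' every non-water, non-metal ligand bound in it. A ligand belongs to the
#' pocket whose lining residues it contacts the most (at least one contact
#' required; ties broken by centroid distance). Ligands of single-chain
#' (monomer) models are annotated with their solvent-exposure fraction —
#' partly exposed monomer ligands are the template mechanism for nucleating
#' a second protein partner. Per-model failures are logged as an attribute,
#' never fatal; the result is deterministic for a fixed input stream.
#'
#' @param models list of [StructureModel] objects and/or structure file paths.
#' @param spacing,probeRadius,enclosureMin pocket-detection parameters
#'   (see [detectPockets]).
#' @param minResidues,minVolume library filter (see [passesLibraryFilter]).
#' @param contactCutoff heavy-atom contact cutoff for ligand-pocket
#'   assignment (Angstrom).
#' @param computeExposure annotate monomer-derived ligands with solvent
#'   exposure (default TRUE).
#' @return list of [TemplateRecord] objects (attribute \code{skipped} logs
#'   failures).
#' @export
buildTemplateLibrary <- function(models, spacing = 1.0, probeRadius = 1.4,
                                 enclosureMin = 5, minResidues = 10,
                                 minVolume = 100, contactCutoff = 4.5,
                                 computeExposure = TRUE) {
  records <- list()
  skipped <- character()
  for (m in models) {
    recs <- tryCatch({
      model <- if (is.character(m)) readStructure(m) else m
      pockets <- Filter(function(p) passesLibraryFilter(p, minResidues, minVolume),
                        detectPockets(model, spacing, probeRadius, enclosureMin))
      lg <- Filter(function(l) !l@metal, ligands(model))
      if (!length(pockets) || !length(lg)) NULL
      else {
        seqs <- vapply(chainIds(model), function(id)
          getChain(model, id)@sequence, character(1))
        monomer <- length(chainIds(model)) == 1
        out <- list()
        for (l in lg) {
          pk <- .assignPocket(l, pockets, contactCutoff)
          if (is.null(pk)) next
          expo <- if (monomer && computeExposure)
            ligandExposureFraction(l, model) else NA_real_
          out[[length(out) + 1L]] <- new(
            "TemplateRecord", entryId = entryId(model), pocket = pk,
            ligandCode = l@code, ligandPose = l@atoms[, .ATOM_COLS],
            sourceSeqs = seqs, exposure = expo)
        }
        out
      }
    }, error = function(e) {
      skipped <<- c(skipped, paste0(if (is.character(m)) m else entryId(m),
                                    ": ", conditionMessage(e)))
      NULL
    })
    if (length(recs)) records <- c(records, recs)
  }
  attr(records, "skipped") <- skipped
  records
}

## Pocket hosting a ligand: most lining residues within the contact cutoff
## of any ligand atom, ties by centroid distance; NULL when no pocket
## contacts the ligand.
.assignPocket <- function(ligand, pockets, cutoff) {
  la <- as.matrix(ligand@atoms[, c("x", "y", "z")])
  com <- colMeans(la)
  best <- NULL; bestN <- 0L; bestD <- Inf
  for (p in pockets) {
    l <- p@lining
    if (!nrow(l)) next
    d2 <- .crossMinDist2(as.matrix(l[, c("x", "y", "z")]), la)
    nContact <- sum(d2 <= cutoff^2)
    d <- sqrt(sum((p@centroid - com)^2))
    if (nContact > bestN || (nContact == bestN && nContact > 0L && d < bestD)) {
      best <- p; bestN <- nContact; bestD <- d
    }
  }
  if (bestN < 1L) NULL else best
}

#' Transfer a template ligand pose through a pocket alignment
#'
#' Maps the template's ligand coordinates into the query frame using the
#' alignment's rigid transform; atom identities are preserved.
#'
#' @param template a [TemplateRecord].
#' @param alignment a [PocketAlignment] whose transform maps the template
#'   pocket onto the query pocket.
#' @return the transferred pose as a canonical atom table.
#' @export
transferPose <- function(template, alignment) {
  if (!is(alignment, "PocketAlignment")) stop("missing alignment transform")
  applyTransform(alignment@transform, template@ligandPose)
}

#' Steric clash count of a pose against a model
#'
#' Number of (ligand atom, polymer heavy atom) pairs closer than
#' \code{overlap} Angstrom.
#'
#' @param pose a [LigandInstance] or canonical atom table.
#' @param model a [StructureModel].
#' @param overlap clash distance in Angstrom (default 1.5).
#' @return integer count.
#' @export
stericClashCount <- function(pose, model, overlap = 1.5) {
  at <- .poseAtoms(pose)
  if (!all(is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("pose coordinates must be finite")
  prot <- model@atoms[model@atoms$kind == "polymer", , drop = FALSE]
  if (!nrow(prot) || !nrow(at)) return(0L)
  P <- as.matrix(at[, c("x", "y", "z")])
  Q <- as.matrix(prot[, c("x", "y", "z")])
  count <- 0L
  step <- max(1L, floor(2e6 / nrow(Q)))
  for (s in seq(1L, nrow(P), by = step)) {
    e <- min(nrow(P), s + step - 1L)
    chunk <- P[s:e, , drop = FALSE]
    d2 <- outer(rowSums(chunk^2), rowSums(Q^2), "+") - 2 * chunk %*% t(Q)
    count <- count + sum(d2 < overlap^2)
  }
  as.integer(count)
}

#' Center-of-mass deviation between two poses
#'
#' Euclidean distance between the unweighted heavy-atom centers of mass.
#'
#' @param poseA,poseB [LigandInstance] objects or canonical atom tables.
#' @return deviation in Angstrom.
#' @export
comDeviation <- function(poseA, poseB) {
  a <- .poseAtoms(poseA); b <- .poseAtoms(poseB)
  if (!nrow(a) || !nrow(b)) stop("poses must be non-empty")
  sqrt(sum((colMeans(as.matrix(a[, c("x", "y", "z")])) -
              colMeans(as.matrix(b[, c("x", "y", "z")])))^2))
}

#' Screen a target dimer against a template library
#'
#' For each interface-adjacent pocket of the target, aligns against every
#' library pocket, keeps matches with p-value at most \code{pCutoff} and
#' template sequence identity at most \code{identityCutoff} to both target
#' chains, transfers the template ligand poses, counts clashes, estimates
#' binding precision, and groups the passing poses by ligand code into
#' ranked [GluePrediction] objects (precision descending, then p-value
#' ascending, then identity descending, then code).
#'
#' @param model the target dimer [StructureModel].
#' @param library list of [TemplateRecord] objects (non-empty).
#' @param nullModel fitted [NullModel] for p-values.
#' @param calibration [CalibrationTable] (default: shipped table).
#' @param pCutoff p-value cutoff (default 0.05).
#' @param identityCutoff maximum template sequence identity to either target
#'   chain (NULL for no cutoff).
#' @param contactCutoff interface contact cutoff (Angstrom).
#' @param overlap steric clash distance (Angstrom).
#' @param requireAdjacent only screen interface-adjacent pockets (default TRUE).
#' @param spacing,probeRadius,enclosureMin pocket-detection parameters.
#' @param identities optional precomputed per-template maximum sequence
#'   identity to the target chains (numeric vector parallel to
#'   \code{library}); computed when NULL.
#' @return list of [GluePrediction] objects, ranked; empty with attribute
#'   \code{reason} when the target has no interface-adjacent pocket.
#' @export
screenTarget <- function(model, library, nullModel,
                         calibration = calibrationDefault(),
                         pCutoff = 0.05, identityCutoff = NULL,
                         contactCutoff = 4.5, overlap = 1.5,
                         requireAdjacent = TRUE, spacing = 1.0,
                         probeRadius = 1.4, enclosureMin = 5,
                         identities = NULL) {
  if (!length(library)) stop("configuration error: empty template library")
  dimer <- selectDimer(model)
  summ <- interfaceResidueSets(dimer, contactCutoff)
  pockets <- flagInterfaceAdjacency(
    detectPockets(model, spacing, probeRadius, enclosureMin), summ)
  if (requireAdjacent)
    pockets <- Filter(function(p) isTRUE(p@interfaceAdjacent), pockets)
  if (!length(pockets)) {
    out <- list()
    attr(out, "reason") <- "no interface-adjacent pocket on target"
    return(out)
  }
  ## identity of each template to the target, computed once per template
  ident <- if (!is.null(identities)) identities
  else templateIdentities(model, library)

  rows <- .screenMatches(model, library, nullModel, calibration, pockets,
                         ident, overlap)
  rows <- Filter(function(r) r$pvalue <= pCutoff &&
                   (is.null(identityCutoff) || r$identity <= identityCutoff),
                 rows)
  .groupPredictions(rows)
}

## All (pocket, template) match rows, unfiltered: alignment features, the
## transferred pose, its clash count and precision estimate.
.screenMatches <- function(model, library, nullModel, calibration, pockets,
                           ident, overlap = 1.5) {
  rows <- list()
  for (ti in seq_along(library)) {
    tr <- library[[ti]]
    for (pk in pockets) {
      al <- tryCatch(alignPockets(pk, tr@pocket), error = function(e) NULL)
      if (is.null(al)) next
      al <- pocketPvalue(al, nullModel)
      pose <- transferPose(tr, al)
      clash <- stericClashCount(pose, model, overlap)
      prec <- estimatePrecision(al@score, al@pvalue, clash, calibration)
      rows[[length(rows) + 1L]] <- list(
        code = tr@ligandCode, pose = pose, score = al@score,
        pvalue = al@pvalue, identity = ident[ti], clash = clash,
        precision = prec)
    }
  }
  rows
}

## Group filtered match rows by ligand code into ranked GluePredictions.
.groupPredictions <- function(rows) {
  if (!length(rows)) return(list())
  codes <- vapply(rows, `[[`, character(1), "code")
  preds <- lapply(split(seq_along(rows), codes), function(ii) {
    grp <- rows[ii]
    prec <- vapply(grp, `[[`, numeric(1), "precision")
    best <- ii[order(-prec,
                     vapply(grp, `[[`, numeric(1), "pvalue"))][1]
    new("GluePrediction",
        ligandCode = rows[[best]]$code,
        poses = lapply(grp, `[[`, "pose"),
        bestScore = max(vapply(grp, `[[`, numeric(1), "score")),
        bestPvalue = min(vapply(grp, `[[`, numeric(1), "pvalue")),
        maxIdentity = max(vapply(grp, `[[`, numeric(1), "identity")),
        precision = rows[[best]]$precision,
        clashCount = as.integer(rows[[best]]$clash))
  })
  ord <- order(-vapply(preds, function(p) p@precision, 1),
               vapply(preds, function(p) p@bestPvalue, 1),
               -vapply(preds, function(p) p@maxIdentity, 1),
               vapply(preds, function(p) p@ligandCode, ""))
  unname(preds[ord])
}

#' Maximum template sequence identity to a target's chains
#'
#' For each template record, the maximum [globalSequenceIdentity] between
#' any of its source chains and either polymer chain of the target.
#'
#' @param model the target [StructureModel].
#' @param library list of [TemplateRecord] objects.
#' @return numeric vector parallel to \code{library}.
#' @export
templateIdentities <- function(model, library) {
  seqs <- vapply(chainIds(model), function(id) getChain(model, id)@sequence,
                 character(1))
  vapply(library, function(tr) {
    max(vapply(tr@sourceSeqs, function(s)
      max(vapply(seqs, function(q) globalSequenceIdentity(s, q),
                 numeric(1))), numeric(1)))
  }, numeric(1))
}

#' Tabulate glue predictions
#'
#' @param predictions list of [GluePrediction] objects.
#' @return data.frame with one row per predicted ligand code.
#' @export
predictionsTable <- function(predictions) {
  if (!length(predictions)) {
    return(data.frame(code = character(), nPoses = integer(),
                      bestScore = numeric(), bestPvalue = numeric(),
                      maxIdentity = numeric(), precision = numeric(),
                      clashCount = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(predictions, function(p) {
    data.frame(code = p@ligandCode, nPoses = length(p@poses),
               bestScore = p@bestScore, bestPvalue = p@bestPvalue,
               maxIdentity = p@maxIdentity, precision = p@precision,
               clashCount = p@clashCount, stringsAsFactors = FALSE)
  }))
}

#' Benchmark the screen on dimers with known native ligands
#'
#' For each (p-value cutoff, identity cutoff) condition, screens every
#' target with its own entry excluded from the library and reports the
#' recall (fraction of targets whose native ligand code is predicted), the
#' mean predicted precision of recovered native ligands, and the mean
#' center-of-mass deviation of the recovered poses from the native pose.
#'
#' @param targets list of lists with elements \code{model} (a
#'   [StructureModel]), \code{nativeCode} and \code{nativePose} (canonical
#'   atom table).
#' @param library list of [TemplateRecord] objects.
#' @param conditions data.frame with columns \code{pCutoff} and
#'   \code{identityCutoff} (NA for no cutoff).
#' @param nullModel fitted [NullModel].
#' @param calibration [CalibrationTable].
#' @return a [BenchmarkReport].
#' @export
runBenchmark <- function(targets, library, conditions, nullModel,
                         calibration = calibrationDefault()) {
  ## alignments, identities and poses are condition-independent: compute
  ## all match rows once per target, then re-filter per condition
  matchCache <- lapply(targets, function(tg) {
    keep <- vapply(library, function(tr)
      tr@entryId != entryId(tg$model), logical(1))
    lib <- library[keep]
    tryCatch({
      dimer <- selectDimer(tg$model)
      summ <- interfaceResidueSets(dimer)
      pockets <- Filter(function(p) isTRUE(p@interfaceAdjacent),
                        flagInterfaceAdjacency(detectPockets(tg$model), summ))
      if (!length(pockets) || !length(lib)) list()
      else .screenMatches(tg$model, lib, nullModel, calibration, pockets,
                          templateIdentities(tg$model, lib))
    }, error = function(e) list())
  })
  condRows <- list(); perTarget <- list()
  for (ci in seq_len(nrow(conditions))) {
    pc <- conditions$pCutoff[ci]
    idc <- conditions$identityCutoff[ci]
    rec <- prec <- dev <- numeric(0)
    hit <- logical(0)
    for (ti in seq_along(targets)) {
      tg <- targets[[ti]]
      preds <- .groupPredictions(Filter(function(r)
        r$pvalue <= pc && (is.na(idc) || r$identity <= idc),
        matchCache[[ti]]))
      codes <- vapply(preds, function(p) p@ligandCode, "")
      got <- tg$nativeCode %in% codes
      hit <- c(hit, got)
      d <- p <- NA_real_
      if (got) {
        pr <- preds[[match(tg$nativeCode, codes)]]
        best <- which.min(vapply(pr@poses, function(ps)
          comDeviation(ps, tg$nativePose), numeric(1)))
        d <- comDeviation(pr@poses[[best]], tg$nativePose)
        p <- pr@precision
        prec <- c(prec, p); dev <- c(dev, d)
      }
      perTarget[[length(perTarget) + 1L]] <- data.frame(
        entry = entryId(tg$model), pCutoff = pc, identityCutoff = idc,
        nativeCode = tg$nativeCode, recovered = got, comDeviation = d,
        precision = p, nPredicted = length(preds), stringsAsFactors = FALSE)
    }
    condRows[[ci]] <- data.frame(
      pCutoff = pc, identityCutoff = idc,
      recall = mean(hit), nRecovered = sum(hit), nTargets = length(hit),
      meanPrecision = if (length(prec)) mean(prec) else NA_real_,
      meanComDeviation = if (length(dev)) mean(dev) else NA_real_,
      stringsAsFactors = FALSE)
  }
  new("BenchmarkReport", conditions = do.call(rbind, condRows),
      perTarget = do.call(rbind, perTarget))
}

#' Summarize a screen over a set of targets
#'
#' @param perTargetPredictions list (one element per target) of
#'   [GluePrediction] lists as returned by [screenTarget].
#' @param precisionThreshold minimum predicted precision for a prediction to
#'   count (default 0.15).
#' @param nativeCatalog optional [IAPCatalog]; predicted codes present among
#'   its interface-bridging records count as known IAP ligands.
#' @return a [ScreenSummary].
#' @export
summarizeScreen <- function(perTargetPredictions, precisionThreshold = 0.15,
                            nativeCatalog = NULL) {
  nT <- length(perTargetPredictions)
  passing <- lapply(perTargetPredictions, function(preds)
    Filter(function(p) p@precision >= precisionThreshold, preds))
  withPred <- vapply(passing, function(x) length(x) > 0, logical(1))
  allPassing <- unlist(passing, recursive = FALSE)
  prec <- vapply(allPassing, function(p) p@precision, numeric(1))
  bestPrec <- vapply(perTargetPredictions, function(preds) {
    if (!length(preds)) return(NA_real_)
    max(vapply(preds, function(p) p@precision, numeric(1)))
  }, numeric(1))
  knownCodes <- if (is.null(nativeCatalog)) character(0) else {
    r <- nativeCatalog@records
    unique(r$code[r$classification == "iap"])
  }
  predCodes <- unique(vapply(allPassing, function(p) p@ligandCode, ""))
  new("ScreenSummary",
      fracWithPrediction = if (nT) mean(withPred) else NA_real_,
      meanPrecision = if (length(prec)) mean(prec) else NA_real_,
      fracKnownIAP = if (length(predCodes) && length(knownCodes))
        mean(predCodes %in% knownCodes)
      else if (length(predCodes)) 0 else NA_real_,
      meanBestPrecision = if (any(!is.na(bestPrec))) mean(bestPrec, na.rm = TRUE)
      else NA_real_,
      maxBestPrecision = if (any(!is.na(bestPrec))) max(bestPrec, na.rm = TRUE)
      else NA_real_,
      threshold = precisionThreshold, nTargets = as.integer(nT))
}

#' Write a per-target screen summary TSV
#'
#' One row per predicted ligand code: code, precision, p-value, maximum
#' template identity and known-IAP flag.
#'
#' @param predictions list of [GluePrediction] objects for one target.
#' @param path output path.
#' @param nativeCatalog optional [IAPCatalog] for the known-IAP flag.
#' @return invisibly, the data.frame written.
#' @export
writeScreenTsv <- function(predictions, path, nativeCatalog = NULL) {
  df <- predictionsTable(predictions)
  known <- if (is.null(nativeCatalog)) rep(NA, nrow(df)) else {
    r <- nativeCatalog@records
    df$code %in% r$code[r$classification == "iap"]
  }
  df$knownIAP <- known
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
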