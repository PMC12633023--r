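#' @include pockets.R
#' @useDynLib iapScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Least-RMSD rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired coordinate sets; the transform maps the second set onto the
#' first.
#'
#' @param fixed,moving n x 3 coordinate matrices with paired rows (n >= 3,
#'   not collinear).
#' @return list with elements \code{transform} (a [RigidTransform]) and
#'   \code{rmsd} (Angstrom).
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' superpose(x, x)$rmsd
#' @export
superpose <- function(fixed, moving) {
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (nrow(fixed) != nrow(moving)) stop("coordinate lists must have equal length")
  if (nrow(fixed) < 3) stop("degenerate input: fewer than 3 point pairs")
  f <- .kabsch_cpp(fixed, moving)
  list(transform = new("RigidTransform", rotation = f$rotation,
                       translation = f$translation),
       rmsd = f$rmsd)
}

#' Identity rigid transform
#' @return a [RigidTransform] that leaves coordinates unchanged.
#' @export
identityTransform <- function() {
  new("RigidTransform", rotation = diag(3), translation = c(0, 0, 0))
}

#' Rigid transform from axis-angle and translation
#'
#' @param axis rotation axis (length-3, need not be unit).
#' @param angle rotation angle in radians.
#' @param translation length-3 translation (Angstrom).
#' @return a [RigidTransform].
#' @export
rigidTransform <- function(axis = c(0, 0, 1), angle = 0, translation = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  new("RigidTransform", rotation = R, translation = translation)
}

#' Compose and invert rigid transforms
#' @param a,b [RigidTransform] objects; \code{composeTransforms(a, b)} applies
#'   \code{b} first, then \code{a}.
#' @return a [RigidTransform].
#' @export
composeTransforms <- function(a, b) {
  new("RigidTransform", rotation = a@rotation %*% b@rotation,
      translation = as.numeric(a@rotation %*% b@translation + a@translation))
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(a) {
  new("RigidTransform", rotation = t(a@rotation),
      translation = as.numeric(-t(a@rotation) %*% a@translation))
}

## Size-dependent distance scale of the similarity score (TM-score style
## scaling, with constants tightened for pocket-sized residue sets so that
## unrelated pockets do not saturate the score).
.d0 <- function(lmin) 0.3 * lmin^(1/3) + 0.4

## Consecutive same-chain lining-residue triples used as alignment seeds.
.liningTriples <- function(lining) {
  n <- nrow(lining)
  if (n < 3) return(matrix(integer(), ncol = 3))
  ok <- lining$chain[1:(n - 2)] == lining$chain[3:n]
  starts <- which(ok)
  cbind(starts, starts + 1L, starts + 2L)
}

#' Iterative pocket structural alignment
#'
#' Aligns two pockets by seeding rigid superpositions from pairs of
#' consecutive lining-residue triples, then iterating mutual-nearest
#' reassignment of representative (C-alpha) atoms under a distance gate of
#' \code{2 * d0} until the correspondence reaches a fixed point, keeping the
#' best-scoring result (ties broken by larger aligned length, then lower
#' RMSD). The similarity score is
#' \deqn{S = \frac{1}{L_{min}} \sum_i \frac{1}{1 + (d_i / d_0)^2}}
#' with \eqn{d_0 = 0.55 L_{min}^{1/3} + 1} and \eqn{L_{min}} the smaller
#' lining-residue count, so a pocket aligned to itself scores exactly 1.
#' Deterministic for fixed inputs and parameters.
#'
#' @param query,template [Pocket] objects with at least 5 lining residues.
#' @param maxIter maximum reassignment iterations per seed (default 50).
#' @param maxSeeds deterministic cap on the number of seed pairs (default 400;
#'   seeds are thinned by a regular stride when the cap is exceeded).
#' @param seedKeep number of best-ranked seeds (by the mutual-pair count of
#'   the raw triple superposition) that receive full iterative refinement
#'   (default 48).
#' @return a [PocketAlignment]; the transform maps template coordinates into
#'   the query frame.
#' @export
alignPockets <- function(query, template, maxIter = 50, maxSeeds = 400,
                         seedKeep = 48) {
  lq <- query@lining; lt <- template@lining
  if (nrow(lq) < 5 || nrow(lt) < 5)
    stop("alignment infeasible: both pockets need at least 5 lining residues")
  Q <- as.matrix(lq[, c("x", "y", "z")])
  T <- as.matrix(lt[, c("x", "y", "z")])
  lmin <- min(nrow(Q), nrow(T))
  d0 <- .d0(lmin)
  tq <- .liningTriples(lq); tt <- .liningTriples(lt)
  if (!nrow(tq) || !nrow(tt))
    stop("alignment infeasible: no consecutive lining triples to seed from")
  combos <- expand.grid(q = seq_len(nrow(tq)), t = seq_len(nrow(tt)))
  if (nrow(combos) > maxSeeds) {
    keep <- unique(round(seq(1, nrow(combos), length.out = maxSeeds)))
    combos <- combos[keep, , drop = FALSE]
  }
  res <- .align_core_cpp(Q, T,
                         tq[combos$q, , drop = FALSE] - 1L,
                         tt[combos$t, , drop = FALSE] - 1L,
                         d0, 2 * d0, as.integer(maxIter), as.integer(lmin),
                         as.integer(seedKeep))
  if (!isTRUE(res$ok))
    stop("alignment infeasible: no seed produced a stable correspondence")
  new("PocketAlignment",
      correspondence = data.frame(query = res$qidx, template = res$tidx),
      transform = new("RigidTransform", rotation = res$rotation,
                      translation = res$translation),
      alignedLength = as.integer(res$alignedLength), rmsd = res$rmsd,
      score = min(1, res$score), pvalue = NA_real_)
}

## Gumbel negative log-likelihood (location, log-scale parameterization).
.gumbelNll <- function(par, x) {
  beta <- exp(par[2])
  z <- (x - par[1]) / beta
  length(x) * par[2] + sum(z) + sum(exp(-z))
}

.fitGumbel <- function(x) {
  beta0 <- max(sd(x), 1e-4) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772156649 * beta0
  fit <- optim(c(mu0, log(beta0)), .gumbelNll, x = x, method = "Nelder-Mead")
  c(loc = fit$par[1], scale = exp(fit$par[2]))
}

.NULL_BINS <- cbind(lo = c(5, 16, 31), hi = c(15, 30, Inf))

#' Fit the null model for pocket-similarity scores
#'
#' Draws random pocket pairs from a library, aligns them, and fits a Gumbel
#' (extreme-value) distribution to the similarity scores per aligned-length
#' bin (5-15, 16-30, >30). The resulting model converts a score into the
#' upper-tail probability of observing it among unrelated pocket pairs.
#' Reproducible for a fixed seed.
#'
#' @param pockets list of (unrelated) [Pocket] objects, length >= 2.
#' @param nPairs number of random pairs to draw (default 10000).
#' @param seed RNG seed (default 17).
#' @param minPerBin bins with fewer successful alignments than this fall back
#'   to the pooled fit (default 30).
#' @return a [NullModel].
#' @export
fitNullModel <- function(pockets, nPairs = 10000, seed = 17, minPerBin = 30) {
  if (length(pockets) < 2) stop("insufficient pockets to draw unrelated pairs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ii <- sample.int(length(pockets), nPairs, replace = TRUE)
  jj <- sample.int(length(pockets) - 1L, nPairs, replace = TRUE)
  jj <- ifelse(jj >= ii, jj + 1L, jj)
  scores <- lens <- numeric(0)
  for (k in seq_len(nPairs)) {
    al <- tryCatch(alignPockets(pockets[[ii[k]]], pockets[[jj[k]]]),
                   error = function(e) NULL)
    if (!is.null(al)) {
      scores <- c(scores, al@score)
      lens <- c(lens, al@alignedLength)
    }
  }
  if (length(scores) < minPerBin)
    stop("insufficient successful alignments (", length(scores),
         ") to calibrate the null model")
  pooled <- .fitGumbel(scores)
  samples <- list()
  bins <- do.call(rbind, lapply(seq_len(nrow(.NULL_BINS)), function(b) {
    sel <- lens >= .NULL_BINS[b, "lo"] & lens <= .NULL_BINS[b, "hi"]
    own <- sum(sel) >= minPerBin
    fit <- if (own) .fitGumbel(scores[sel]) else pooled
    samples[[b]] <<- sort(if (own) scores[sel] else scores)
    data.frame(binLo = .NULL_BINS[b, "lo"], binHi = .NULL_BINS[b, "hi"],
               loc = fit["loc"], scale = fit["scale"], n = sum(sel))
  }))
  rownames(bins) <- NULL
  new("NullModel", bins = bins, samples = samples,
      nPairs = as.integer(nPairs), seed = as.integer(seed))
}

#' p-value of a pocket alignment under the null model
#'
#' Upper-tail probability of the similarity score among unrelated pocket
#' pairs, in the aligned-length bin of the alignment. Within the observed
#' null-score range the p-value comes from a linearly interpolated
#' empirical CDF (so null p-values are uniform by construction); beyond the
#' largest observed null score the fitted Gumbel upper tail takes over.
#' Monotone non-increasing in the score within a bin, strictly decreasing
#' over the observed range.
#'
#' @param alignment a [PocketAlignment] (or a numeric score).
#' @param nullModel a fitted [NullModel].
#' @param alignedLength aligned length when a bare score is given.
#' @return for an alignment, the alignment with its \code{pvalue} slot set;
#'   for a numeric score, the p-value.
#' @export
pocketPvalue <- function(alignment, nullModel, alignedLength = NULL) {
  score <- if (is(alignment, "PocketAlignment")) alignment@score else alignment
  len <- if (is(alignment, "PocketAlignment")) alignment@alignedLength
         else alignedLength
  if (is.null(len)) stop("alignedLength required for a bare score")
  b <- nullModel@bins
  row <- which(len >= b$binLo & len <= b$binHi)
  row <- if (!length(row)) { if (len < b$binLo[1]) 1L else nrow(b) } else row[1]
  s <- nullModel@samples[[row]]
  n <- length(s)
  pTail <- 1 / (n + 1)
  if (score >= s[n]) {
    ## fitted extreme-value upper tail, rescaled to continue the empirical
    ## CDF at the largest observed null score
    gTail <- function(x) -expm1(-exp(-(x - b$loc[row]) / b$scale[row]))
    ref <- gTail(s[n])
    p <- if (ref > 0) pTail * gTail(score) / ref else pTail
    p <- max(min(p, pTail), .Machine$double.xmin)
  } else if (score <= s[1]) {
    p <- 1
  } else {
    Fv <- stats::approx(s, seq_len(n) / (n + 1), xout = score,
                        ties = "ordered")$y
    p <- min(1, max(1 - Fv, pTail))
  }
  if (is(alignment, "PocketAlignment")) {
    alignment@pvalue <- p
    alignment
  } else p
}

#' Global sequence identity
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap open 11, extend 1);
#' identity is the number of identical aligned positions divided by the
#' alignment length including gaps. Symmetric in its arguments.
#'
#' @param seqA,seqB non-empty amino-acid sequences (character strings).
#' @return identity fraction in [0, 1].
#' @export
globalSequenceIdentity <- function(seqA, seqB) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seqA), Biostrings::AAString(seqB),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pm <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  sum(pm == ps & pm != "-") / length(pm)
}

#' Superpose a monomer chain onto its copy in a dimer
#'
#' Sequence-guided C-alpha superposition: the monomer chain is globally
#' aligned to the named dimer chain, matched (non-gap) positions provide the
#' paired coordinates, and a least-RMSD fit is computed with optional
#' outlier-trimming cycles (pairs beyond \code{trimFactor} times the current
#' RMSD are dropped, at most \code{maxCycles} times). Used to quantify how
#' well a ligand-bearing monomer conformation is preserved inside a dimer.
#'
#' @param monomer a [StructureModel] with one polymer chain (or a [Chain]).
#' @param dimer a [StructureModel] containing the partner copy.
#' @param dimerChain chain id of the copy inside \code{dimer}.
#' @param trim perform outlier-trimming cycles (default TRUE).
#' @param trimFactor,maxCycles trimming parameters.
#' @return list: \code{rmsd} (Angstrom, over retained pairs), \code{nFit}
#'   (retained pairs), \code{nMatched} (aligned non-gap pairs),
#'   \code{transform} (a [RigidTransform] mapping monomer onto dimer).
#' @export
monomerDimerDisplacement <- function(monomer, dimer, dimerChain,
                                     trim = TRUE, trimFactor = 2,
                                     maxCycles = 5) {
  chM <- if (is(monomer, "Chain")) monomer else getChain(monomer, chainIds(monomer)[1])
  chD <- getChain(dimer, dimerChain)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(chM@sequence), Biostrings::AAString(chD@sequence),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pm <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  im <- cumsum(pm != "-"); is <- cumsum(ps != "-")
  matched <- which(pm != "-" & ps != "-")
  caCoords <- function(ch) {
    a <- ch@atoms[ch@atoms$elety == "CA", , drop = FALSE]
    key <- paste(a$resno, a$insert)
    rkey <- paste(ch@residues$resno, ch@residues$insert)
    as.matrix(a[match(rkey, key), c("x", "y", "z")])
  }
  M <- caCoords(chM)[im[matched], , drop = FALSE]
  D <- caCoords(chD)[is[matched], , drop = FALSE]
  ok <- stats::complete.cases(M) & stats::complete.cases(D)
  M <- M[ok, , drop = FALSE]; D <- D[ok, , drop = FALSE]
  if (nrow(M) < 3) stop("fewer than 3 matched residues with coordinates")
  keep <- rep(TRUE, nrow(M))
  fit <- superpose(D, M)
  if (trim) {
    for (cyc in seq_len(maxCycles)) {
      Mt <- applyTransform(fit$transform, M)
      d <- sqrt(rowSums((Mt - D)^2))
      newKeep <- d <= trimFactor * max(fit$rmsd, 0.5)
      if (sum(newKeep) < 3 || all(newKeep == keep)) break
      keep <- newKeep
      fit <- superpose(D[keep, , drop = FALSE], M[keep, , drop = FALSE])
    }
  }
  list(rmsd = fit$rmsd, nFit = sum(keep), nMatched = length(matched),
       transform = fit$transform)
}

#' Serialize alignment results as TSV
#'
#' @param alignments named list of [PocketAlignment] objects.
#' @param path output path.
#' @return invisibly, the data.frame written.
#' @export
writeAlignmentTsv <- function(alignments, path) {
  df <- do.call(rbind, lapply(names(alignments), function(nm) {
    a <- alignments[[nm]]
    tf <- c(t(a@transform@rotation), a@transform@translation)
    data.frame(pair = nm, alignedLength = a@alignedLength, rmsd = a@rmsd,
               score = a@score, pvalue = a@pvalue,
               transform = paste(sprintf("%.6f", tf), collapse = " "),
               stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Store / load a null model as structured text
#' @param model a [NullModel].
#' @param path file path.
#' @return \code{readNullModel} returns a [NullModel].
#' @export
writeNullModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nPairs=%d seed=%d", model@nPairs, model@seed), con)
  for (i in seq_along(model@samples))
    writeLines(sprintf("# samples%d=%s", i,
                       paste(format(model@samples[[i]], digits = 17),
                             collapse = ",")), con)
  write.table(model@bins, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNullModel
#' @export
readNullModel <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- as.integer(strsplit(sub(".*nPairs=(\\d+) seed=(\\d+).*", "\\1 \\2",
                                  hdr[1]), " ")[[1]])
  sampleLines <- grep("^# samples", hdr, value = TRUE)
  samples <- lapply(sampleLines, function(l)
    as.numeric(strsplit(sub("^# samples\\d+=", "", l), ",")[[1]]))
  bins <- read.delim(path, skip = length(hdr))
  new("NullModel", bins = bins, samples = samples,
      nPairs = meta[1], seed = meta[2])
}
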