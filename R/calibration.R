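#' @include sasa.R
NULL

## Weighted pool-adjacent-violators along one vector (non-decreasing).
.pava <- function(y, w) {
  n <- length(y)
  if (n < 2) return(y)
  vals <- y; wts <- w; sizes <- rep(1L, n); m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    vals[m] <- y[i]; wts[m] <- w[i]; sizes[m] <- 1L
    while (m > 1L && vals[m - 1L] > vals[m]) {
      tw <- wts[m - 1L] + wts[m]
      vals[m - 1L] <- if (tw > 0) (vals[m - 1L] * wts[m - 1L] +
                                     vals[m] * wts[m]) / tw
                      else (vals[m - 1L] + vals[m]) / 2
      wts[m - 1L] <- tw
      sizes[m - 1L] <- sizes[m - 1L] + sizes[m]
      m <- m - 1L
    }
  }
  rep(vals[seq_len(m)], sizes[seq_len(m)])
}

## Alternate count-weighted isotonic passes (non-decreasing in score along
## rows, non-increasing in p along columns) until stable. Weighting by bin
## counts keeps well-populated bins at their empirical values.
.monotonize <- function(v, w, maxIter = 50) {
  for (it in seq_len(maxIter)) {
    before <- v
    for (p in seq_len(ncol(v))) v[, p] <- .pava(v[, p], w[, p])
    for (s in seq_len(nrow(v))) v[s, ] <- rev(.pava(rev(v[s, ]), rev(w[s, ])))
    if (max(abs(v - before)) < 1e-12) break
  }
  v
}

#' Build a binding-precision calibration table
#'
#' Bins a labeled set of pocket-match features by similarity score and
#' p-value and records the empirical positive fraction per bin, then
#' enforces monotonicity (non-decreasing in score, non-increasing in
#' p-value). Empty bins inherit the overall positive fraction before
#' monotonization.
#'
#' @param labeled data.frame with columns \code{score}, \code{pvalue} and
#'   logical \code{positive}.
#' @param nBins number of bins per feature (default 10, i.e. deciles).
#' @param clashLimit steric-clash disqualification limit stored on the table.
#' @return a [CalibrationTable].
#' @export
buildCalibrationTable <- function(labeled, nBins = 10, clashLimit = 5L) {
  stopifnot(all(c("score", "pvalue", "positive") %in% names(labeled)),
            nrow(labeled) > 0)
  qs <- unique(stats::quantile(labeled$score, probs = seq(0, 1, length.out = nBins + 1)))
  qp <- unique(stats::quantile(labeled$pvalue, probs = seq(0, 1, length.out = nBins + 1)))
  sb <- c(-Inf, qs[-c(1, length(qs))], Inf)
  pb <- c(-Inf, qp[-c(1, length(qp))], Inf)
  si <- findInterval(labeled$score, sb, rightmost.closed = TRUE)
  pi <- findInterval(labeled$pvalue, pb, rightmost.closed = TRUE)
  nS <- length(sb) - 1L; nP <- length(pb) - 1L
  v <- matrix(NA_real_, nS, nP)
  w <- matrix(0, nS, nP)
  for (s in seq_len(nS)) for (p in seq_len(nP)) {
    sel <- si == s & pi == p
    w[s, p] <- sum(sel)
    if (any(sel)) v[s, p] <- mean(labeled$positive[sel])
  }
  ## empty bins carry zero weight and inherit a monotone-consistent lower
  ## bound: the best occupied bin they dominate (lower score, higher p)
  fill <- v
  for (s in seq_len(nS)) for (p in seq_len(nP)) {
    if (!is.na(v[s, p])) next
    dom <- v[seq_len(s), p:nP, drop = FALSE]
    fill[s, p] <- if (any(!is.na(dom))) max(dom, na.rm = TRUE)
                  else min(v, na.rm = TRUE)
  }
  v <- .monotonize(fill, w)
  new("CalibrationTable", scoreBreaks = sb, pBreaks = pb, values = v,
      clashLimit = as.integer(clashLimit))
}

#' Estimate binding precision from match features
#'
#' Piecewise-constant lookup in a [CalibrationTable]: monotone
#' non-decreasing in the similarity score and non-increasing in the p-value
#' and clash count. Features outside the table range are clamped to the edge
#' bins. A clash count above the table's hard limit disqualifies the pose
#' (precision 0).
#'
#' @param score pocket-similarity score.
#' @param pvalue alignment p-value.
#' @param clashCount steric clash count of the pose (default 0).
#' @param calibration a [CalibrationTable] (default: the shipped table).
#' @return precision estimate in [0, 1].
#' @export
estimatePrecision <- function(score, pvalue, clashCount = 0L,
                              calibration = calibrationDefault()) {
  if (clashCount > calibration@clashLimit) return(0)
  s <- findInterval(score, calibration@scoreBreaks, rightmost.closed = TRUE)
  p <- findInterval(pvalue, calibration@pBreaks, rightmost.closed = TRUE)
  s <- min(max(s, 1L), nrow(calibration@values))
  p <- min(max(p, 1L), ncol(calibration@values))
  calibration@values[s, p]
}

#' Store / load a calibration table as structured text
#'
#' @param table a [CalibrationTable].
#' @param path file path.
#' @return \code{readCalibrationTable} returns a [CalibrationTable].
#' @export
writeCalibrationTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# clashLimit=%d", table@clashLimit),
               paste0("# scoreBreaks=", paste(table@scoreBreaks, collapse = ",")),
               paste0("# pBreaks=", paste(table@pBreaks, collapse = ","))), con)
  write.table(table@values, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeCalibrationTable
#' @export
readCalibrationTable <- function(path) {
  hdr <- readLines(path, n = 3)
  clash <- as.integer(sub("# clashLimit=", "", hdr[1]))
  sb <- as.numeric(strsplit(sub("# scoreBreaks=", "", hdr[2]), ",")[[1]])
  pb <- as.numeric(strsplit(sub("# pBreaks=", "", hdr[3]), ",")[[1]])
  v <- as.matrix(read.delim(path, skip = 3, header = FALSE))
  dimnames(v) <- NULL
  new("CalibrationTable", scoreBreaks = sb, pBreaks = pb, values = v,
      clashLimit = clash)
}

.calibCache <- new.env(parent = emptyenv())

#' Default calibration table shipped with the package
#'
#' Loaded from \code{inst/extdata/calibration_default.tsv}, which was built
#' with \code{scripts/build_calibration.R} from a synthetic labeled set of
#' homologous (positive) and unrelated (negative) pocket matches. Substitute
#' a user-built table via [readCalibrationTable].
#'
#' @return a [CalibrationTable].
#' @export
calibrationDefault <- function() {
  if (is.null(.calibCache$default)) {
    path <- system.file("extdata", "calibration_default.tsv",
                        package = "iapScreen", mustWork = TRUE)
    .calibCache$default <- readCalibrationTable(path)
  }
  .calibCache$default
}
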