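#' @import methods
#' @importFrom stats setNames runif rnorm sd optim ks.test ecdf
#' @importFrom utils head read.delim write.table
NULL

## Canonical atom-table columns used throughout the package. Coordinates are
## in Angstrom, residue numbering is author numbering (1-based, insertion
## codes kept as characters, "" when absent).
.ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "occ", "het", "kind", "metal")

.validAtomTable <- function(a) {
  if (!is.data.frame(a)) return("atoms must be a data.frame")
  miss <- setdiff(.ATOM_COLS, names(a))
  if (length(miss)) return(paste("atom table missing columns:", paste(miss, collapse = ", ")))
  if (nrow(a) && !all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("atom coordinates must be finite")
  if (nrow(a) && !all(a$occ >= 0 & a$occ <= 1, na.rm = TRUE))
    return("occupancy must lie in [0, 1]")
  TRUE
}

#' Parsed macromolecular structure
#'
#' Holds one entry/assembly partitioned into polymer chains, ligand
#' instances and waters. The atom table is the single source of coordinates
#' for every geometric operation in the package; the \code{kind} column
#' partitions atoms into \code{"polymer"}, \code{"ligand"} and
#' \code{"water"} (every atom belongs to exactly one class).
#'
#' @slot entryId entry identifier (e.g. PDB id or fixture name).
#' @slot assemblyId assembly identifier, \code{"asu"} for the asymmetric unit.
#' @slot provenance \code{"experimental"} or \code{"predicted"}.
#' @slot atoms canonical atom table (see Details).
#' @exportClass StructureModel
setClass("StructureModel",
         representation(entryId = "character", assemblyId = "character",
                        provenance = "character", atoms = "data.frame"),
         validity = function(object) {
           v <- .validAtomTable(object@atoms)
           if (!isTRUE(v)) return(v)
           if (!object@provenance %in% c("experimental", "predicted"))
             return("provenance must be 'experimental' or 'predicted'")
           TRUE
         })

#' Polymer chain view
#'
#' One polymer chain of a [StructureModel]: its ordered residues, one-letter
#' sequence and heavy atoms.
#'
#' @slot id chain identifier.
#' @slot residues one row per polymer residue (chain, resno, insert, resid, aa).
#' @slot sequence one-letter sequence, same length as the residue table.
#' @slot atoms heavy atoms of this chain (canonical atom table).
#' @exportClass Chain
setClass("Chain",
         representation(id = "character", residues = "data.frame",
                        sequence = "character", atoms = "data.frame"),
         validity = function(object) {
           if (nchar(object@sequence) != nrow(object@residues))
             return("sequence length must equal polymer residue count")
           if (nrow(object@residues) < 1) return("chain must have at least one residue")
           TRUE
         })

#' Ligand instance
#'
#' A single bound hetero group: its chemical component code, residue
#' identity and heavy atoms. Waters and single-atom metal ions are flagged;
#' the two flags are mutually exclusive.
#'
#' @slot code 3-character chemical component code.
#' @slot chain,resno,insert residue identity of the instance.
#' @slot atoms heavy atoms (canonical atom table).
#' @slot metal TRUE for single-atom metal ions.
#' @slot water TRUE for waters.
#' @exportClass LigandInstance
setClass("LigandInstance",
         representation(code = "character", chain = "character",
                        resno = "integer", insert = "character",
                        atoms = "data.frame", metal = "logical", water = "logical"),
         validity = function(object) {
           if (nrow(object@atoms) < 1) return("ligand must have at least one atom")
           if (object@metal && object@water) return("metal and water flags are mutually exclusive")
           TRUE
         })

#' Protein-protein interface summary
#'
#' Contact pairs between two chains and the projected per-chain interface
#' residue sets. A residue is an interface residue iff it participates in at
#' least one contact pair.
#'
#' @slot chainA,chainB chain identifiers.
#' @slot residuesA,residuesB interface residues per chain (chain, resno, insert).
#' @slot pairs contact pairs with the minimum heavy-atom distance per pair.
#' @slot cutoff heavy-atom distance cutoff used (Angstrom).
#' @exportClass InterfaceSummary
setClass("InterfaceSummary",
         representation(chainA = "character", chainB = "character",
                        residuesA = "data.frame", residuesB = "data.frame",
                        pairs = "data.frame", cutoff = "numeric"))

#' Catalog of interface-adjacent-pocket ligand classifications
#'
#' Aggregates per-ligand classification records over a set of dimers, with
#' a per-code frequency histogram of ligands classified as interface
#' bridging (\code{iap}), a separate histogram for metal ions, and the
#' fraction of all classified ligands that are \code{iap}.
#'
#' @slot records one row per classified ligand instance.
#' @slot histogram named counts of iap-classified non-metal ligand codes.
#' @slot metalHistogram named counts of iap-classified metal elements.
#' @slot iapFraction fraction of classified ligands that are iap (NA when empty).
#' @slot skipped log of entries skipped during cataloguing.
#' @exportClass IAPCatalog
setClass("IAPCatalog",
         representation(records = "data.frame", histogram = "integer",
                        metalHistogram = "integer", iapFraction = "numeric",
                        skipped = "character"),
         validity = function(object) {
           if (!is.na(object@iapFraction) &&
               (object@iapFraction < 0 || object@iapFraction > 1))
             return("iapFraction must lie in [0, 1]")
           TRUE
         })

#' Grid-derived cavity
#'
#' A maximal 6-connected set of cavity grid cells with its volume, lining
#' residues (with their representative C-alpha coordinates used by pocket
#' alignment) and interface-adjacency flag.
#'
#' @slot id pocket identifier within its model.
#' @slot cells n x 3 matrix of member cell centers (Angstrom).
#' @slot spacing grid spacing (Angstrom).
#' @slot volume cell count x spacing^3 (Angstrom^3).
#' @slot centroid mean of member cell centers.
#' @slot lining lining residues (chain, resno, insert, resid, aa, x, y, z).
#' @slot interfaceAdjacent adjacency flag (NA until classified).
#' @exportClass Pocket
setClass("Pocket",
         representation(id = "character", cells = "matrix", spacing = "numeric",
                        volume = "numeric", centroid = "numeric",
                        lining = "data.frame", interfaceAdjacent = "logical"),
         validity = function(object) {
           if (object@spacing <= 0) return("spacing must be positive")
           if (abs(object@volume - nrow(object@cells) * object@spacing^3) > 1e-6)
             return("volume must equal cell count x spacing^3")
           TRUE
         })

#' Rigid-body transform
#'
#' Proper rotation plus translation; maps a coordinate row-matrix X to
#' \code{X \%*\% t(rotation) + translation}.
#'
#' @slot rotation 3 x 3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric (Angstrom).
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"),
         validity = function(object) {
           R <- object@rotation
           if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
           if (max(abs(crossprod(R) - diag(3))) > 1e-8)
             return("rotation must be orthonormal to 1e-8")
           if (abs(det(R) - 1) > 1e-8) return("rotation determinant must be +1")
           if (length(object@translation) != 3) return("translation must have length 3")
           TRUE
         })

#' Pocket structural alignment
#'
#' Residue correspondence between a query and a template pocket, the rigid
#' transform that maps template coordinates into the query frame, and the
#' normalized similarity score with its (optional) empirical p-value.
#'
#' @slot correspondence matched lining-residue indices (query, template).
#' @slot transform [RigidTransform] mapping template onto query.
#' @slot alignedLength number of matched residue pairs.
#' @slot rmsd RMSD over matched representative atoms (Angstrom).
#' @slot score similarity score in (0, 1].
#' @slot pvalue empirical p-value in (0, 1] (NA until assigned).
#' @exportClass PocketAlignment
setClass("PocketAlignment",
         representation(correspondence = "data.frame", transform = "RigidTransform",
                        alignedLength = "integer", rmsd = "numeric",
                        score = "numeric", pvalue = "numeric"),
         validity = function(object) {
           if (object@score < 0 || object@score > 1 + 1e-9)
             return("score must lie in (0, 1]")
           if (!is.na(object@pvalue) && (object@pvalue <= 0 || object@pvalue > 1))
             return("pvalue must lie in (0, 1]")
           TRUE
         })

#' Null model for pocket-similarity scores
#'
#' Semiparametric null for scores of randomly drawn unrelated pocket pairs,
#' per aligned-length bin: the retained score sample provides an
#' interpolated empirical CDF over the observed range, and a fitted Gumbel
#' (extreme-value) location/scale pair provides the upper tail beyond it.
#'
#' @slot bins per-bin Gumbel fit (binLo, binHi, loc, scale, n).
#' @slot samples per-bin sorted score samples (list parallel to bins).
#' @slot nPairs number of random pairs drawn.
#' @slot seed RNG seed used for the draw.
#' @exportClass NullModel
setClass("NullModel",
         representation(bins = "data.frame", samples = "list",
                        nPairs = "integer", seed = "integer"),
         validity = function(object) {
           if (nrow(object@bins) && any(object@bins$scale <= 0))
             return("all fitted scales must be positive")
           TRUE
         })

#' Template library entry
#'
#' A template pocket paired with the pose of its bound ligand, the source
#' chain sequences used for identity filtering, and (for monomer-derived
#' templates) the ligand's solvent-exposure fraction.
#'
#' @slot entryId source entry identifier.
#' @slot pocket the template [Pocket].
#' @slot ligandCode 3-character component code.
#' @slot ligandPose heavy-atom pose (canonical atom table).
#' @slot sourceSeqs one-letter sequences of the source chains.
#' @slot exposure solvent-exposure fraction in [0, 1] (NA when not computed).
#' @exportClass TemplateRecord
setClass("TemplateRecord",
         representation(entryId = "character", pocket = "Pocket",
                        ligandCode = "character", ligandPose = "data.frame",
                        sourceSeqs = "character", exposure = "numeric"))

#' Predicted glue ligand for one target
#'
#' One ligand code with its ensemble of transferred poses and the
#' best-feature values representing the prediction.
#'
#' @slot ligandCode 3-character component code.
#' @slot poses list of transferred heavy-atom pose tables (at least one).
#' @slot bestScore best pocket-similarity score among supporting matches.
#' @slot bestPvalue best (smallest) p-value among supporting matches.
#' @slot maxIdentity maximum template sequence identity to either target chain.
#' @slot precision calibrated binding-precision estimate in [0, 1].
#' @slot clashCount steric clash count of the best pose.
#' @exportClass GluePrediction
setClass("GluePrediction",
         representation(ligandCode = "character", poses = "list",
                        bestScore = "numeric", bestPvalue = "numeric",
                        maxIdentity = "numeric", precision = "numeric",
                        clashCount = "integer"),
         validity = function(object) {
           if (length(object@poses) < 1) return("pose ensemble must be non-empty")
           if (object@precision < 0 || object@precision > 1)
             return("precision must lie in [0, 1]")
           TRUE
         })

#' Benchmark report over known-ligand dimers
#'
#' Recall, mean predicted precision and mean center-of-mass deviation of
#' recovered native ligands, per (p-value cutoff, identity cutoff) condition.
#'
#' @slot conditions one row per condition with the summary metrics.
#' @slot perTarget per-target outcome rows for the last condition set.
#' @exportClass BenchmarkReport
setClass("BenchmarkReport",
         representation(conditions = "data.frame", perTarget = "data.frame"))

#' Screen summary over a set of targets
#'
#' @slot fracWithPrediction fraction of targets with >= 1 prediction at the
#'   precision threshold.
#' @slot meanPrecision mean precision of predictions passing the threshold.
#' @slot fracKnownIAP fraction of predicted codes present in the native catalog.
#' @slot meanBestPrecision,maxBestPrecision mean and max of per-target best precision.
#' @slot threshold precision threshold applied.
#' @slot nTargets number of targets summarized.
#' @exportClass ScreenSummary
setClass("ScreenSummary",
         representation(fracWithPrediction = "numeric", meanPrecision = "numeric",
                        fracKnownIAP = "numeric", meanBestPrecision = "numeric",
                        maxBestPrecision = "numeric", threshold = "numeric",
                        nTargets = "integer"))

#' Molecular graph
#'
#' Minimal molecular graph for fingerprinting: heavy-atom element symbols
#' plus a bond table with integer bond orders.
#'
#' @slot elements element symbol per heavy atom.
#' @slot bonds data.frame with columns from, to (1-based) and order.
#' @slot code source ligand code.
#' @exportClass MolGraph
setClass("MolGraph",
         representation(elements = "character", bonds = "data.frame",
                        code = "character"),
         validity = function(object) {
           if (length(object@elements) < 1) return("molecule must have at least one atom")
           b <- object@bonds
           if (nrow(b) && (any(b$from < 1) || any(b$to > length(object@elements))))
             return("bond indices out of range")
           TRUE
         })

#' Path-based molecular fingerprint
#'
#' Fixed-length bit vector produced by hashing all linear atom/bond paths of
#' a molecular graph.
#'
#' @slot bits sorted positions of set bits (1-based).
#' @slot nBits bit-vector length.
#' @slot scheme hashing-scheme identifier.
#' @slot code source ligand code.
#' @exportClass Fingerprint
setClass("Fingerprint",
         representation(bits = "integer", nBits = "integer",
                        scheme = "character", code = "character"),
         validity = function(object) {
           if (length(object@bits) < 1) return("a non-empty molecule sets at least one bit")
           if (any(object@bits < 1 | object@bits > object@nBits))
             return("bit positions out of range")
           TRUE
         })

#' Threshold clustering result
#'
#' @slot clusters list of member-code character vectors (a partition of the input).
#' @slot centroids centroid code per cluster (always a member of its cluster).
#' @slot threshold Tanimoto threshold used.
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(clusters = "list", centroids = "character",
                        threshold = "numeric"),
         validity = function(object) {
           if (length(object@clusters) != length(object@centroids))
             return("one centroid per cluster required")
           ok <- mapply(function(cl, ce) ce %in% cl, object@clusters, object@centroids)
           if (length(ok) && !all(ok)) return("each centroid must be a member of its cluster")
           TRUE
         })

#' Binding-precision calibration table
#'
#' Piecewise-constant map from (similarity score, p-value) bins to a
#' precision estimate, monotone non-decreasing in score and non-increasing
#' in p-value. Poses whose clash count exceeds the hard limit are assigned
#' precision 0 regardless of the table.
#'
#' @slot scoreBreaks increasing break points over score (length nS + 1).
#' @slot pBreaks increasing break points over p-value (length nP + 1).
#' @slot values nS x nP precision matrix.
#' @slot clashLimit hard steric-clash disqualification limit.
#' @exportClass CalibrationTable
setClass("CalibrationTable",
         representation(scoreBreaks = "numeric", pBreaks = "numeric",
                        values = "matrix", clashLimit = "integer"),
         validity = function(object) {
           v <- object@values
           if (nrow(v) != length(object@scoreBreaks) - 1 ||
               ncol(v) != length(object@pBreaks) - 1)
             return("values dimensions must match the break vectors")
           if (any(v < 0 | v > 1)) return("precision values must lie in [0, 1]")
           TRUE
         })
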