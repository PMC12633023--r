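#' @include AllClasses.R
NULL

#' Accessors for structural objects
#'
#' Small accessor generics used across the package instead of direct slot
#' access.
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("entryId", function(x) standardGeneric("entryId"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("ligands", function(x, ...) standardGeneric("ligands"))
#' @rdname accessors
#' @export
setGeneric("chainSequence", function(x, ...) standardGeneric("chainSequence"))
#' @rdname accessors
#' @export
setGeneric("pocketVolume", function(x) standardGeneric("pocketVolume"))
#' @rdname accessors
#' @export
setGeneric("liningResidues", function(x) standardGeneric("liningResidues"))
#' @rdname accessors
#' @export
setGeneric("isInterfaceAdjacentFlag", function(x) standardGeneric("isInterfaceAdjacentFlag"))
#' @rdname accessors
#' @export
setGeneric("alignScore", function(x) standardGeneric("alignScore"))
#' @rdname accessors
#' @export
setGeneric("alignPvalue", function(x) standardGeneric("alignPvalue"))
#' @rdname accessors
#' @export
setGeneric("alignTransform", function(x) standardGeneric("alignTransform"))
#' @rdname accessors
#' @export
setGeneric("iapFraction", function(x) standardGeneric("iapFraction"))
#' @rdname accessors
#' @export
setGeneric("catalogRecords", function(x) standardGeneric("catalogRecords"))
#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' Apply a rigid transform to coordinates
#'
#' @param transform a [RigidTransform].
#' @param coords an n x 3 coordinate matrix (rows are points) or an atom table
#'   with x, y, z columns.
#' @return the transformed coordinates, same shape as the input.
#' @export
setGeneric("applyTransform", function(transform, coords) standardGeneric("applyTransform"))

setMethod("entryId", "StructureModel", function(x) x@entryId)
setMethod("provenance", "StructureModel", function(x) x@provenance)
setMethod("atomTable", "StructureModel", function(x) x@atoms)
setMethod("atomTable", "LigandInstance", function(x) x@atoms)
setMethod("atomTable", "Chain", function(x) x@atoms)
setMethod("chainIds", "StructureModel", function(x) {
  unique(x@atoms$chain[x@atoms$kind == "polymer"])
})
setMethod("chainSequence", "Chain", function(x, ...) x@sequence)
setMethod("pocketVolume", "Pocket", function(x) x@volume)
setMethod("liningResidues", "Pocket", function(x) x@lining)
setMethod("isInterfaceAdjacentFlag", "Pocket", function(x) x@interfaceAdjacent)
setMethod("alignScore", "PocketAlignment", function(x) x@score)
setMethod("alignPvalue", "PocketAlignment", function(x) x@pvalue)
setMethod("alignTransform", "PocketAlignment", function(x) x@transform)
setMethod("iapFraction", "IAPCatalog", function(x) x@iapFraction)
setMethod("catalogRecords", "IAPCatalog", function(x) x@records)
setMethod("clusters", "ClusterResult", function(x) x@clusters)
setMethod("centroids", "ClusterResult", function(x) x@centroids)
setMethod("fpBits", "Fingerprint", function(x) x@bits)

setMethod("applyTransform", signature("RigidTransform", "matrix"),
          function(transform, coords) {
            sweep(coords %*% t(transform@rotation), 2, transform@translation, "+")
          })
setMethod("applyTransform", signature("RigidTransform", "data.frame"),
          function(transform, coords) {
            xyz <- as.matrix(coords[, c("x", "y", "z")])
            out <- sweep(xyz %*% t(transform@rotation), 2, transform@translation, "+")
            coords$x <- out[, 1]; coords$y <- out[, 2]; coords$z <- out[, 3]
            coords
          })

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel", object@entryId,
      sprintf("[%s, assembly %s]\n", object@provenance, object@assemblyId))
  cat(sprintf("  %d polymer chains (%s), %d ligand instances, %d water atoms\n",
              length(chainIds(object)), paste(chainIds(object), collapse = ","),
              length(unique(paste(a$chain, a$resno, a$insert)[a$kind == "ligand"])),
              sum(a$kind == "water")))
})

setMethod("show", "Pocket", function(object) {
  cat(sprintf("Pocket %s: %d cells, volume %.1f A^3, %d lining residues, interface-adjacent: %s\n",
              object@id, nrow(object@cells), object@volume, nrow(object@lining),
              ifelse(is.na(object@interfaceAdjacent), "unclassified",
                     object@interfaceAdjacent)))
})

setMethod("show", "PocketAlignment", function(object) {
  cat(sprintf("PocketAlignment: L=%d, RMSD=%.3f A, score=%.4f, p=%s\n",
              object@alignedLength, object@rmsd, object@score,
              ifelse(is.na(object@pvalue), "NA", format(object@pvalue, digits = 3))))
})

setMethod("show", "IAPCatalog", function(object) {
  cat(sprintf("IAPCatalog: %d records, iap fraction %s, %d iap codes, %d metal codes\n",
              nrow(object@records),
              ifelse(is.na(object@iapFraction), "undefined",
                     sprintf("%.3f", object@iapFraction)),
              length(object@histogram), length(object@metalHistogram)))
})

setMethod("show", "NullModel", function(object) {
  cat(sprintf("NullModel: %d pairs, seed %d\n", object@nPairs, object@seed))
  print(object@bins)
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d clusters at Tanimoto threshold %.2f\n",
              length(object@clusters), object@threshold))
})

setMethod("show", "ScreenSummary", function(object) {
  cat(sprintf(paste0("ScreenSummary over %d targets (precision threshold %.2f):\n",
                     "  fraction with prediction: %.3f\n",
                     "  mean precision:           %.3f\n",
                     "  fraction known IAP codes: %.3f\n",
                     "  best precision mean/max:  %.3f / %.3f\n"),
              object@nTargets, object@threshold, object@fracWithPrediction,
              object@meanPrecision, object@fracKnownIAP,
              object@meanBestPrecision, object@maxBestPrecision))
})

setMethod("show", "BenchmarkReport", function(object) {
  cat("BenchmarkReport:\n")
  print(object@conditions)
})
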