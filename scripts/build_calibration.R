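#!/usr/bin/env Rscript
# Rebuilds the default binding-precision calibration table shipped at
# inst/extdata/calibration_default.tsv from a synthetic labeled set:
# positives are remote-homolog pocket matches (pose transfer correct by
# construction), negatives are unrelated pocket pairs. Run from the
# repository root after installing the package:
#   Rscript scripts/build_calibration.R

library(iapScreen)

nulls <- makeNullPocketSet(40, seed = 7)
nm <- fitNullModel(nulls, nPairs = 2000, seed = 17)
labeled <- makeLabeledCalibrationSet(nm, nPos = 60, nNeg = 140, seed = 11)
cat(sprintf("labeled set: %d rows (%d positive)\n",
            nrow(labeled), sum(labeled$positive)))
table <- buildCalibrationTable(labeled, nBins = 5)
out <- file.path("inst", "extdata", "calibration_default.tsv")
writeCalibrationTable(table, out)
cat("wrote", out, "\n")
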