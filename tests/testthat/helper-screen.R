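# Shared (lazily built, memoized) screening scaffolding for the test files:
# a small unrelated-pocket library, a null model fitted on it, and a small
# calibration table. Deliberately modest sizes to keep the suite fast; the
# acceptance tests rebuild these at the sizes the validation design states.
.screenEnv <- new.env()

testNullPockets <- function() {
  if (is.null(.screenEnv$pockets))
    .screenEnv$pockets <- makeNullPocketSet(18, seed = 7)
  .screenEnv$pockets
}

testNullModel <- function() {
  if (is.null(.screenEnv$nullModel))
    .screenEnv$nullModel <- fitNullModel(testNullPockets(), nPairs = 250,
                                         seed = 17)
  .screenEnv$nullModel
}

testCalibration <- function() {
  if (is.null(.screenEnv$calib)) {
    lab <- makeLabeledCalibrationSet(testNullModel(), nPos = 10, nNeg = 30,
                                     seed = 11)
    .screenEnv$calib <- buildCalibrationTable(lab, nBins = 4)
  }
  .screenEnv$calib
}

testBenchmark <- function() {
  if (is.null(.screenEnv$bench))
    .screenEnv$bench <- makeBenchmarkSet(nTargets = 6, seed = 3)
  .screenEnv$bench
}
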