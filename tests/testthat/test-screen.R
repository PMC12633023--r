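test_that("template library construction pairs qualifying pockets with ligands", {
  fx <- makeDimerFixture(dimerFixtureSpec(pocketEnclosure = TRUE, seed = 111,
                                          wallJitter = 0.3, ligandCode = "TPL"))
  lib <- buildTemplateLibrary(list(fx$model), computeExposure = FALSE)
  expect_length(lib, 1)
  expect_equal(lib[[1]]@ligandCode, "TPL")
  expect_equal(lib[[1]]@entryId, entryId(fx$model))
  expect_length(lib[[1]]@sourceSeqs, 2)

  ## identical streams give identical libraries
  lib2 <- buildTemplateLibrary(list(fx$model), computeExposure = FALSE)
  expect_equal(predictionsTable(list()), predictionsTable(list()))
  expect_identical(lib[[1]]@ligandPose, lib2[[1]]@ligandPose)
  expect_identical(liningResidues(lib[[1]]@pocket),
                   liningResidues(lib2[[1]]@pocket))

  ## a pocket failing the library filter yields no record
  none <- buildTemplateLibrary(list(fx$model), minVolume = 1e5)
  expect_length(none, 0)
})

test_that("pose transfer is exact for self-templates and rigidly invariant", {
  bench <- testBenchmark()
  tr <- bench$library[[1]]
  ## self-alignment of the template pocket: identity transform, pose unchanged
  al <- alignPockets(tr@pocket, tr@pocket)
  pose <- transferPose(tr, al)
  expect_equal(comDeviation(pose, tr@ligandPose), 0, tolerance = 1e-8)

  ## rigidly pre-moving the whole template changes nothing after transfer
  tf <- randomRigidTransform(112)
  moved <- tr
  moved@pocket@lining[, c("x", "y", "z")] <-
    applyTransform(tf, as.matrix(tr@pocket@lining[, c("x", "y", "z")]))
  moved@ligandPose <- applyTransform(tf, tr@ligandPose)
  al2 <- alignPockets(tr@pocket, moved@pocket)
  pose2 <- transferPose(moved, al2)
  expect_lt(comDeviation(pose2, pose), 1e-5)

  expect_error(transferPose(tr, NULL), "alignment")
})

test_that("clash counts and CoM deviations match brute force", {
  for (seed in 113:115) {
    model <- randomContactFixture(seed)
    set.seed(seed + 50)
    pose <- data.frame(chain = "L", resno = 1L, insert = "", resid = "LIG",
                       elety = paste0("C", 1:8), elesy = "C",
                       x = runif(8, 0, 15), y = runif(8, 0, 15),
                       z = runif(8, 0, 15), occ = 1, het = TRUE,
                       kind = "ligand", metal = FALSE)
    expect_identical(stericClashCount(pose, model, overlap = 2.5),
                     as.integer(bruteClashCount(pose, model, overlap = 2.5)))
    pose2 <- pose
    pose2$x <- pose2$x + 3
    expect_equal(comDeviation(pose, pose2), bruteComDeviation(pose, pose2),
                 tolerance = 1e-12)
  }
  ## a far-away pose never clashes; a coincident atom always does
  model <- randomContactFixture(116)
  far <- data.frame(chain = "L", resno = 1L, insert = "", resid = "LIG",
                    elety = "C1", elesy = "C", x = 200, y = 200, z = 200,
                    occ = 1, het = TRUE, kind = "ligand", metal = FALSE)
  expect_equal(stericClashCount(far, model), 0L)
  onTop <- far
  onTop$x <- atomTable(model)$x[1]
  onTop$y <- atomTable(model)$y[1]
  onTop$z <- atomTable(model)$z[1]
  expect_gte(stericClashCount(onTop, model), 1L)
  ## pure translation shows up exactly in the CoM deviation
  expect_equal(comDeviation(far, transform(far, x = x + 3)), 3)
})

test_that("precision estimation respects the table and the clash rule", {
  calib <- testCalibration()
  top <- estimatePrecision(1, 1e-12, 0, calib)
  expect_equal(top, max(calib@values))
  expect_equal(estimatePrecision(1, 1e-12, calib@clashLimit + 1L, calib), 0)
  ## monotone: score up never lowers, p up never raises
  ss <- seq(0, 1, by = 0.1)
  for (p in c(1e-4, 0.05, 0.5)) {
    est <- vapply(ss, estimatePrecision, numeric(1), pvalue = p,
                  calibration = calib)
    expect_true(all(diff(est) >= 0))
  }
  ps <- c(1e-6, 1e-3, 0.05, 0.2, 0.8)
  for (s in c(0.3, 0.7, 0.95)) {
    est <- vapply(ps, function(p) estimatePrecision(s, p, 0, calib), numeric(1))
    expect_true(all(diff(est) <= 0))
  }
})

test_that("calibration tables agree with the labeled set bin-wise", {
  lab <- makeLabeledCalibrationSet(testNullModel(), nPos = 10, nNeg = 30,
                                   seed = 11)
  calib <- buildCalibrationTable(lab, nBins = 4)
  est <- mapply(function(s, p) estimatePrecision(s, p, 0, calib),
                lab$score, lab$pvalue)
  si <- findInterval(lab$score, calib@scoreBreaks, rightmost.closed = TRUE)
  pi <- findInterval(lab$pvalue, calib@pBreaks, rightmost.closed = TRUE)
  for (key in unique(paste(si, pi))) {
    sel <- paste(si, pi) == key
    expect_lte(abs(mean(est[sel]) - mean(lab$positive[sel])), 0.05)
  }
  ## round trip through the text format
  path <- tempfile(fileext = ".tsv")
  writeCalibrationTable(calib, path)
  back <- readCalibrationTable(path)
  expect_equal(back@values, calib@values, tolerance = 1e-9)
})

test_that("screening ranks the true remote-homolog ligand first", {
  bench <- testBenchmark()
  tg <- bench$targets[[1]]
  lib <- Filter(function(tr) tr@entryId != entryId(tg$model), bench$library)
  own <- bench$library[vapply(bench$library, function(tr)
    tr@ligandCode == tg$nativeCode, TRUE)]
  expect_length(own, 1)
  preds <- screenTarget(tg$model, c(lib, own), testNullModel(),
                        testCalibration(), pCutoff = 0.05,
                        identityCutoff = 0.30)
  expect_gt(length(preds), 0)
  expect_equal(preds[[1]]@ligandCode, tg$nativeCode)
  best <- which.min(vapply(preds[[1]]@poses, function(p)
    comDeviation(p, tg$nativePose), 1))
  expect_lt(comDeviation(preds[[1]]@poses[[best]], tg$nativePose), 2)

  ## a high-identity template is excluded by the identity cutoff: the
  ## target's own pocket/ligand as template has identity ~1
  self <- buildTemplateLibrary(list(tg$model), computeExposure = FALSE)
  self <- Filter(function(tr) tr@ligandCode == tg$nativeCode, self)
  selfRenamed <- self[[1]]
  selfRenamed@entryId <- "selfcopy"
  got <- screenTarget(tg$model, list(selfRenamed), testNullModel(),
                      testCalibration(), pCutoff = 0.05, identityCutoff = 0.30)
  expect_length(got, 0)
  gotLoose <- screenTarget(tg$model, list(selfRenamed), testNullModel(),
                           testCalibration(), pCutoff = 0.05,
                           identityCutoff = NULL)
  expect_equal(gotLoose[[1]]@ligandCode, tg$nativeCode)

  expect_error(screenTarget(tg$model, list(), testNullModel()), "empty")
})

test_that("self-recovery: own pocket and ligand give CoM deviation ~0", {
  bench <- testBenchmark()
  tg <- bench$targets[[2]]
  self <- buildTemplateLibrary(list(tg$model), computeExposure = FALSE)
  self <- Filter(function(tr) tr@ligandCode == tg$nativeCode, self)
  preds <- screenTarget(tg$model, self, testNullModel(), testCalibration(),
                        pCutoff = 0.05, identityCutoff = NULL)
  expect_equal(preds[[1]]@ligandCode, tg$nativeCode)
  devs <- vapply(preds[[1]]@poses, function(p)
    comDeviation(p, tg$nativePose), 1)
  expect_lt(min(devs), 1e-6)
})

test_that("prediction filters are nested", {
  bench <- testBenchmark()
  tg <- bench$targets[[3]]
  lib <- bench$library
  strict <- screenTarget(tg$model, lib, testNullModel(), testCalibration(),
                         pCutoff = 0.01, identityCutoff = 0.30)
  loose <- screenTarget(tg$model, lib, testNullModel(), testCalibration(),
                        pCutoff = 0.05, identityCutoff = 0.40)
  codes <- function(x) vapply(x, function(p) p@ligandCode, "")
  expect_true(all(codes(strict) %in% codes(loose)))
})

test_that("screen summaries compute all four fields", {
  mkPred <- function(code, prec) new("GluePrediction", ligandCode = code,
                                     poses = list(data.frame(x = 0)),
                                     bestScore = 0.9, bestPvalue = 0.01,
                                     maxIdentity = 0.2, precision = prec,
                                     clashCount = 0L)
  perTarget <- list(list(mkPred("AAA", 0.5), mkPred("BBB", 0.10)),
                    list(mkPred("AAA", 0.2)),
                    list(mkPred("CCC", 0.149)),
                    list(),
                    list(mkPred("DDD", 0.15)))
  fx <- makeDimerFixture(dimerFixtureSpec(ligandCode = "AAA", seed = 117),
                         entryId = "cat1")
  catalog <- buildCatalog(list(fx$model))
  s <- summarizeScreen(perTarget, precisionThreshold = 0.15,
                       nativeCatalog = catalog)
  ## exactly targets 1, 2 and 5 pass at the threshold (0.15 is inclusive)
  expect_equal(s@fracWithPrediction, 3 / 5)
  expect_equal(s@meanPrecision, mean(c(0.5, 0.2, 0.15)))
  ## predicted codes at threshold: AAA, DDD; only AAA is a known IAP code
  expect_equal(s@fracKnownIAP, 0.5)
  expect_equal(s@meanBestPrecision, mean(c(0.5, 0.2, 0.149, 0.15)))
  expect_equal(s@maxBestPrecision, 0.5)

  none <- summarizeScreen(list(list(mkPred("ZZZ", 0.10))), 0.15, catalog)
  expect_equal(none@fracWithPrediction, 0)
})

test_that("benchmark reports are deterministic across runs", {
  bench <- testBenchmark()
  conds <- data.frame(pCutoff = 0.05, identityCutoff = 0.30)
  r1 <- runBenchmark(bench$targets[1:2], bench$library, conds,
                     testNullModel(), testCalibration())
  r2 <- runBenchmark(bench$targets[1:2], bench$library, conds,
                     testNullModel(), testCalibration())
  expect_identical(r1@conditions, r2@conditions)
  expect_identical(r1@perTarget, r2@perTarget)
})
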