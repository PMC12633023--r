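test_that("contact map equals the brute-force oracle on planted fixtures", {
  for (seed in c(31, 32, 33)) {
    k <- 4 + seed %% 4
    fx <- makeDimerFixture(dimerFixtureSpec(contacts = k, seed = seed))
    dimer <- selectDimer(fx$model)
    got <- residueContactMap(dimer[[1]], dimer[[2]])
    oracle <- bruteContactMap(dimer[[1]], dimer[[2]])
    expect_equal(nrow(got), k)
    expect_equal(got[, c("resnoA", "resnoB")],
                 oracle[order(oracle$resnoA, oracle$resnoB),
                        c("resnoA", "resnoB")],
                 ignore_attr = TRUE)
    expect_equal(sort(got$dist), sort(oracle$dist), tolerance = 1e-12)
  }
})

test_that("contact map is symmetric and empty for distant chains", {
  fx <- makeDimerFixture(dimerFixtureSpec(contacts = 5, seed = 34))
  dimer <- selectDimer(fx$model)
  ab <- residueContactMap(dimer[[1]], dimer[[2]])
  ba <- residueContactMap(dimer[[2]], dimer[[1]])
  expect_equal(ab[order(ab$resnoA, ab$resnoB), c("resnoA", "resnoB", "dist")],
               setNames(ba[order(ba$resnoB, ba$resnoA),
                           c("resnoB", "resnoA", "dist")],
                        c("resnoA", "resnoB", "dist")),
               ignore_attr = TRUE)

  far <- makeDimerFixture(dimerFixtureSpec(contacts = 0, ligandAtoms = 0,
                                           seed = 35))
  fd <- selectDimer(far$model)
  expect_equal(nrow(residueContactMap(fd[[1]], fd[[2]])), 0)
})

test_that("contact sets are monotone in the cutoff", {
  fx <- makeDimerFixture(dimerFixtureSpec(contacts = 6, seed = 36))
  dimer <- selectDimer(fx$model)
  key <- function(df) paste(df$resnoA, df$resnoB)
  cuts <- c(3.5, 4.0, 4.5, 5.5, 7.0)
  maps <- lapply(cuts, function(cc) residueContactMap(dimer[[1]], dimer[[2]], cc))
  for (i in seq_along(cuts)[-1])
    expect_true(all(key(maps[[i - 1]]) %in% key(maps[[i]])))
})

test_that("interface projections and the dimer rule behave at the boundary", {
  fx <- makeDimerFixture(dimerFixtureSpec(contacts = 6, seed = 37))
  summ <- interfaceResidueSets(selectDimer(fx$model))
  expect_equal(nrow(summ@residuesA), 6)
  expect_equal(nrow(summ@residuesB), 6)
  expect_true(qualifiesAsDimer(summ))

  none <- makeDimerFixture(dimerFixtureSpec(contacts = 0, ligandAtoms = 0,
                                            seed = 38))
  s0 <- interfaceResidueSets(selectDimer(none$model))
  expect_equal(nrow(s0@residuesA), 0)
  expect_equal(nrow(s0@residuesB), 0)
  expect_false(qualifiesAsDimer(s0))

  five <- makeDimerFixture(dimerFixtureSpec(contacts = 5, ligandAtoms = 0,
                                            seed = 39))
  s5 <- interfaceResidueSets(selectDimer(five$model))
  expect_true(qualifiesAsDimer(s5, minPerChain = 5))
  expect_false(qualifiesAsDimer(s5, minPerChain = 6))
})

test_that("ligand-chain contacts count distinct residues exactly", {
  fx <- makeDimerFixture(dimerFixtureSpec(ligandContactsA = 6,
                                          ligandContactsB = 5, seed = 40))
  dimer <- selectDimer(fx$model)
  lig <- ligands(fx$model)[[1]]
  expect_equal(ligandChainContacts(lig, dimer[[1]]), 6)
  expect_equal(ligandChainContacts(lig, dimer[[2]]), 5)

  ## moving the ligand 20 A away zeroes both counts
  farAtoms <- atomTable(lig)
  farAtoms$y <- farAtoms$y - 40
  far <- new("LigandInstance", code = "LG1", chain = "A", resno = 900L,
             insert = "", atoms = farAtoms, metal = FALSE, water = FALSE)
  expect_equal(ligandChainContacts(far, dimer[[1]]), 0)

  ## duplicate atom contacts to one residue still count once: a ligand with
  ## 3 atoms around a single residue contacts exactly 1 residue
  ## atoms strung out perpendicular to the chain axis reach only residue 1
  ca <- atomTable(dimer[[1]])
  one <- data.frame(chain = "A", resno = 900L, insert = "", resid = "XXX",
                    elety = c("C1", "C2", "C3"), elesy = "C",
                    x = ca$x[1], y = ca$y[1] - c(2.6, 3.1, 3.6),
                    z = ca$z[1], occ = 1, het = TRUE, kind = "ligand",
                    metal = FALSE, stringsAsFactors = FALSE)
  multi <- new("LigandInstance", code = "XXX", chain = "A", resno = 900L,
               insert = "", atoms = one, metal = FALSE, water = FALSE)
  expect_equal(ligandChainContacts(multi, dimer[[1]]), 1)
})

test_that("ligand classification follows the per-chain rule", {
  fx <- makeDimerFixture(dimerFixtureSpec(ligandContactsA = 6,
                                          ligandContactsB = 5, seed = 41))
  dimer <- selectDimer(fx$model)
  rec <- classifyLigand(ligands(fx$model)[[1]], dimer, entryId = "fx41")
  expect_equal(rec$classification, "iap")
  expect_equal(c(rec$countA, rec$countB), c(6, 5))

  ## (5, 4) is single-chain: one chain under the threshold
  fx2 <- makeDimerFixture(dimerFixtureSpec(ligandContactsA = 5,
                                           ligandContactsB = 4, seed = 42))
  rec2 <- classifyLigand(ligands(fx2$model)[[1]], selectDimer(fx2$model))
  expect_equal(rec2$classification, "single_chain")

  ## (0, 0) is a non-binder
  fx3 <- makeDimerFixture(dimerFixtureSpec(ligandContactsA = 0,
                                           ligandContactsB = 0,
                                           ligandAtoms = 5, seed = 43))
  rec3 <- classifyLigand(ligands(fx3$model)[[1]], selectDimer(fx3$model))
  expect_equal(rec3$classification, "non_binder")

  ## waters are rejected outright
  fxw <- makeDimerFixture(dimerFixtureSpec(nWaters = 1, seed = 44))
  w <- Filter(function(l) l@water, ligands(fxw$model, includeWaters = TRUE))[[1]]
  expect_error(classifyLigand(w, selectDimer(fxw$model)), "water")
})

test_that("catalog aggregation counts, conserves and tallies metals", {
  mk <- function(seed, cA, cB, code)
    makeDimerFixture(dimerFixtureSpec(ligandContactsA = cA, ligandContactsB = cB,
                                      ligandCode = code, seed = seed),
                     entryId = sprintf("e%d", seed))$model
  ## 2 iap + 3 single-chain ligands across 4 dimers -> fraction 0.4
  models <- list(mk(51, 6, 5, "AAA"), mk(52, 5, 5, "BBB"),
                 mk(53, 5, 4, "CCC"), mk(54, 6, 4, "AAA"))
  fx5 <- makeDimerFixture(dimerFixtureSpec(ligandContactsA = 4,
                                           ligandContactsB = 5,
                                           ligandCode = "DDD", seed = 55),
                          entryId = "e55")
  models <- c(models, list(fx5$model))
  catalog <- buildCatalog(models)
  rec <- catalogRecords(catalog)
  expect_equal(nrow(rec), 5)
  expect_equal(iapFraction(catalog), 0.4)
  expect_equal(sum(catalog@histogram), sum(rec$classification == "iap"))
  expect_equal(as.integer(catalog@histogram[c("AAA", "BBB")]), c(1L, 1L))

  ## a planted interfacial Zn shows up in the metal sub-histogram
  zn <- makeDimerFixture(dimerFixtureSpec(ligandAtoms = 0, metalSite = "ZN",
                                          seed = 56), entryId = "zn")
  czn <- buildCatalog(list(zn$model))
  expect_equal(as.integer(czn@metalHistogram["ZN"]), 1L)
  expect_equal(sum(czn@histogram), 0L)

  ## empty stream: empty catalog with undefined fraction
  c0 <- buildCatalog(list())
  expect_equal(nrow(catalogRecords(c0)), 0)
  expect_true(is.na(iapFraction(c0)))

  ## parse failures are logged, never fatal
  bad <- tempfile(fileext = ".pdb")
  writeLines("garbage", bad)
  cbad <- buildCatalog(c(list(mk(57, 6, 5, "EEE")), bad))
  expect_equal(nrow(catalogRecords(cbad)), 1)
  expect_length(cbad@skipped, 1)
})
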