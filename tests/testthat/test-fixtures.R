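test_that("fixture truths are verified by independent brute force", {
  fx <- makeDimerFixture(dimerFixtureSpec(contacts = 6, ligandContactsA = 6,
                                          ligandContactsB = 5, seed = 131))
  dimer <- selectDimer(fx$model)
  oracle <- bruteContactMap(dimer[[1]], dimer[[2]])
  expect_equal(nrow(oracle), fx$truth$plantedContacts)
  expect_equal(fx$truth$interfaceA, length(unique(oracle$resnoA)))
  rec <- classifyLigand(ligands(fx$model)[[1]], dimer)
  expect_equal(c(rec$countA, rec$countB), fx$truth$ligandPlanted)
  expect_equal(rec$classification, "iap")
})

test_that("zero planted contacts fail the dimer rule", {
  fx <- makeDimerFixture(dimerFixtureSpec(contacts = 0, ligandAtoms = 0,
                                          seed = 132))
  expect_false(qualifiesAsDimer(interfaceResidueSets(selectDimer(fx$model))))
})

test_that("generators are pure functions of spec and seed", {
  f1 <- makeDimerFixture(dimerFixtureSpec(seed = 133))
  f2 <- makeDimerFixture(dimerFixtureSpec(seed = 133))
  p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
  writeStructurePdb(f1$model, p1)
  writeStructurePdb(f2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
  f3 <- makeDimerFixture(dimerFixtureSpec(seed = 134))
  expect_false(identical(atomTable(f1$model), atomTable(f3$model)))

  e1 <- makeDimerFixture(dimerFixtureSpec(pocketEnclosure = TRUE, seed = 135,
                                          wallJitter = 0.4, subBoxes = 2,
                                          notches = 1))
  e2 <- makeDimerFixture(dimerFixtureSpec(pocketEnclosure = TRUE, seed = 135,
                                          wallJitter = 0.4, subBoxes = 2,
                                          notches = 1))
  expect_identical(atomTable(e1$model), atomTable(e2$model))

  b1 <- makeFingerprintBlobs(2, 3, seed = 136)
  b2 <- makeFingerprintBlobs(2, 3, seed = 136)
  expect_identical(lapply(b1$fingerprints, fpBits),
                   lapply(b2$fingerprints, fpBits))
})

test_that("infeasible specs are rejected", {
  expect_error(dimerFixtureSpec(), "seed")
  expect_error(makeDimerFixture(dimerFixtureSpec(residuesPerChain = 8,
                                                 contacts = 9, seed = 1)),
               "infeasible")
  expect_error(makeDimerFixture(dimerFixtureSpec(residuesPerChain = 10,
                                                 contacts = 2,
                                                 ligandContactsA = 5,
                                                 ligandContactsB = 5,
                                                 seed = 1)),
               "infeasible")
  expect_error(makeHomolog(makeDimerFixture(dimerFixtureSpec(seed = 2))$model,
                           mutationRate = 1.4, seed = 3), "rates")
  expect_error(makeFingerprintBlobs(2, 3, within = 0.3, between = 0.5,
                                    seed = 4), "infeasible")
})

test_that("cavity fixture volumes hit the filter boundaries", {
  expect_equal(makeCavityFixture(c(5, 5, 5))$truth$volume, 125)
  expect_equal(makeCavityFixture(c(4, 5, 5))$truth$volume, 100)
  expect_lt(makeCavityFixture(c(3, 3, 3))$truth$volume, 100)
})

test_that("homolog derivation hits the requested identity and recovers its transform", {
  base <- makeDimerFixture(dimerFixtureSpec(residuesPerChain = 200,
                                            contacts = 6, ligandAtoms = 0,
                                            seed = 141))
  ## identity: no structural change, no mutations
  same <- makeHomolog(base$model, seed = 142)
  expect_equal(atomTable(same$model)[, c("x", "y", "z", "resid")],
               atomTable(base$model)[, c("x", "y", "z", "resid")],
               tolerance = 1e-12)

  ## 75% substitutions, no indels: identity ~ 0.25 on a 200-mer
  mut <- makeHomolog(base$model, mutationRate = 0.75, seed = 143)
  idn <- globalSequenceIdentity(getChain(base$model, "A")@sequence,
                                getChain(mut$model, "A")@sequence)
  expect_lt(abs(idn - 0.25), 0.05)

  ## planted rigid transform is recovered by superposition on mapped residues
  tf <- randomRigidTransform(144)
  noisy <- makeHomolog(base$model, noiseSigma = 0.3, deletionRate = 0.1,
                       transform = tf, seed = 145)
  map <- noisy$truth$map
  a0 <- atomTable(base$model)
  a1 <- atomTable(noisy$model)
  ## C-alpha plus side-chain centroid: the bare C-alpha trace of the open
  ## fixture is collinear, which superpose correctly rejects
  pick <- function(a, ch, resnos) {
    sel <- a$kind == "polymer" & a$chain == ch &
      a$elety %in% c("CA", "CB") & a$resno %in% resnos
    as.matrix(a[sel, c("x", "y", "z")])
  }
  resA <- map$resno[map$chain == "A"]
  fit <- superpose(pick(a1, "A", resA), pick(a0, "A", resA))
  expect_equal(fit$transform@rotation, tf@rotation, tolerance = 0.05)
  ## RMSD scales with the planted noise (sigma 0.3 per coordinate)
  expect_lt(abs(fit$rmsd - 0.3 * sqrt(3)), 0.25)
})

test_that("enclosure fixtures plant an interface-adjacent IAP ligand", {
  for (seed in 146:148) {
    fx <- makeDimerFixture(dimerFixtureSpec(pocketEnclosure = TRUE,
                                            seed = seed, wallJitter = 0.45,
                                            subBoxes = 1, notches = 1))
    expect_gte(min(fx$truth$ligandContacts), 5)
    summ <- interfaceResidueSets(selectDimer(fx$model))
    expect_true(qualifiesAsDimer(summ))
    pockets <- detectPockets(fx$model)
    expect_gte(length(pockets), 1)
    expect_true(isInterfaceAdjacent(pockets[[1]], summ))
  }
})
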