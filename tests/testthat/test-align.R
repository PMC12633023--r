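test_that("superposition recovers exact rigid motions", {
  set.seed(71)
  x <- matrix(rnorm(60), ncol = 3)
  self <- superpose(x, x)
  expect_lt(self$rmsd, 1e-10)
  expect_equal(self$transform@rotation, diag(3), tolerance = 1e-8)

  tf <- rigidTransform(axis = c(0, 0, 1), angle = pi / 2,
                       translation = c(5, -1, 2))
  y <- applyTransform(tf, x)
  fit <- superpose(y, x)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$transform@rotation, tf@rotation, tolerance = 1e-8)
  expect_equal(fit$transform@translation, tf@translation, tolerance = 1e-8)
})

test_that("superposition RMSD agrees with the quaternion oracle on noisy sets", {
  for (seed in 72:75) {
    set.seed(seed)
    x <- matrix(rnorm(150), ncol = 3) * 4
    y <- applyTransform(randomRigidTransform(seed), x) +
      matrix(rnorm(150, 0, 0.5), ncol = 3)
    got <- superpose(x, y)$rmsd
    oracle <- quaternionRmsd(x, y)
    expect_lt(abs(got - oracle), 0.2 * oracle)
  }
})

test_that("superposition rejects degenerate input", {
  expect_error(superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "degenerate")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line + 1), "degenerate")
})

test_that("superposition RMSD is invariant under rigid pre-motion", {
  set.seed(76)
  x <- matrix(rnorm(90), ncol = 3) * 3
  y <- x + matrix(rnorm(90, 0, 0.4), ncol = 3)
  base <- superpose(x, y)$rmsd
  for (seed in 77:79) {
    tf <- randomRigidTransform(seed)
    expect_lt(abs(superpose(x, applyTransform(tf, y))$rmsd - base), 1e-6)
    expect_lt(abs(superpose(applyTransform(tf, x), y)$rmsd - base), 1e-6)
  }
})

## shared fixtures for the pocket-alignment cases
.pocketPair <- local({
  fx <- makeDimerFixture(dimerFixtureSpec(pocketEnclosure = TRUE, seed = 80,
                                          wallJitter = 0.45, subBoxes = 1))
  hom <- makeHomolog(fx$model, mutationRate = 0.2, noiseSigma = 0.5,
                     deletionRate = 0.2,
                     transform = randomRigidTransform(81), seed = 82)
  list(query = detectPockets(fx$model)[[1]],
       template = detectPockets(hom$model)[[1]],
       map = hom$truth$map)
})

test_that("a pocket aligned to itself scores exactly 1", {
  al <- alignPockets(.pocketPair$query, .pocketPair$query)
  expect_equal(alignScore(al), 1, tolerance = 1e-9)
  expect_lt(al@rmsd, 1e-8)
  expect_equal(al@alignedLength, nrow(liningResidues(.pocketPair$query)))
})

test_that("alignment is invariant under rigid motion of the template", {
  pk <- .pocketPair$query
  moved <- pk
  moved@lining[, c("x", "y", "z")] <-
    applyTransform(randomRigidTransform(83),
                   as.matrix(pk@lining[, c("x", "y", "z")]))
  moved@cells <- applyTransform(randomRigidTransform(83), pk@cells)
  al <- alignPockets(pk, moved)
  expect_equal(alignScore(al), 1, tolerance = 1e-6)
})

test_that("alignment recovers the planted homolog correspondence", {
  al <- alignPockets(.pocketPair$query, .pocketPair$template)
  q <- liningResidues(.pocketPair$query)
  t <- liningResidues(.pocketPair$template)
  corr <- al@correspondence
  ## residue numbering survives homolog derivation: matched pairs should
  ## pair up the same (chain, resno)
  hits <- q$chain[corr$query] == t$chain[corr$template] &
    q$resno[corr$query] == t$resno[corr$template]
  expect_gte(mean(hits), 0.8)
  expect_gte(al@alignedLength, 5)
})

test_that("alignment score is symmetric and errors on tiny pockets", {
  a <- alignPockets(.pocketPair$query, .pocketPair$template)
  b <- alignPockets(.pocketPair$template, .pocketPair$query)
  expect_lt(abs(alignScore(a) - alignScore(b)), 0.02)

  small <- .pocketPair$query
  small@lining <- small@lining[1:4, ]
  expect_error(alignPockets(small, .pocketPair$query), "infeasible")
})

test_that("global sequence identity matches direct counting", {
  expect_equal(globalSequenceIdentity("MKVLAT", "MKVLAT"), 1)
  set.seed(84)
  s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 100,
                    replace = TRUE), collapse = "")
  v <- strsplit(s, "")[[1]]
  idx <- sample(100, 30)
  for (i in idx) v[i] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                        v[i]), 1)
  mut <- paste(v, collapse = "")
  expect_equal(globalSequenceIdentity(s, mut), 0.70, tolerance = 0.021)
  expect_equal(globalSequenceIdentity(s, mut), globalSequenceIdentity(mut, s))
  expect_lt(globalSequenceIdentity(strrep("A", 40), strrep("W", 40)), 0.05)
  expect_error(globalSequenceIdentity("", "MKV"), "non-empty")
})

test_that("single mutations shift gapless identity by exactly one position", {
  s <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  v <- strsplit(s, "")[[1]]
  v[7] <- "A"
  expect_equal(globalSequenceIdentity(s, paste(v, collapse = "")),
               (nchar(s) - 1) / nchar(s), tolerance = 1e-9)
})

test_that("monomer-dimer displacement recovers a planted conformational change", {
  ## synthetic analogue of a ligase monomer vs its dimer copy: a helical
  ## chain duplicated into a two-chain model; the monomer copy is rigidly
  ## moved and lightly perturbed
  set.seed(85)
  t <- seq_len(60)
  helix <- function(chain, shift) {
    aa <- sample(c("ALA", "LEU", "SER", "GLY", "VAL"), 60, replace = TRUE)
    data.frame(chain = chain, resno = t, insert = "", resid = aa,
               elety = "CA", elesy = "C",
               x = 1.5 * t + shift, y = 2.3 * cos(t * 1.7),
               z = 2.3 * sin(t * 1.7), occ = 1, het = FALSE,
               kind = "polymer", metal = FALSE, stringsAsFactors = FALSE)
  }
  a <- helix("A", 0)
  dimer <- newStructureModel(rbind(a, helix("B", 4)), entryId = "dim")
  mono <- a
  set.seed(86)
  xyz <- applyTransform(randomRigidTransform(87),
                        as.matrix(mono[, c("x", "y", "z")])) +
    matrix(rnorm(3 * nrow(mono), 0, 0.3), ncol = 3)
  mono$x <- xyz[, 1]; mono$y <- xyz[, 2]; mono$z <- xyz[, 3]
  monomer <- newStructureModel(mono, entryId = "mono")
  res <- monomerDimerDisplacement(monomer, dimer, "A")
  expect_lt(res$rmsd, 0.6)
  expect_equal(res$nMatched, 60)
})
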