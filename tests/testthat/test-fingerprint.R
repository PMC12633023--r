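# Small molecular graphs used across the fingerprint cases.
butane <- makeMolGraph(c("C", "C", "C", "C"),
                       data.frame(from = 1:3, to = 2:4, order = 1),
                       code = "BUT")
isobutane <- makeMolGraph(c("C", "C", "C", "C"),
                          data.frame(from = c(1, 1, 1), to = 2:4, order = 1),
                          code = "IBU")

test_that("path fingerprints are deterministic and non-empty", {
  a <- pathFingerprint(butane)
  b <- pathFingerprint(butane)
  expect_identical(fpBits(a), fpBits(b))
  expect_gte(length(fpBits(a)), 1)
  expect_error(pathFingerprint(makeMolGraph(character(0))), "atom")
})

test_that("a single heavy atom sets exactly its one-atom path bit", {
  methane <- makeMolGraph("C", code = "CH4")
  fp <- pathFingerprint(methane)
  expect_length(fpBits(fp), 1)
  ## the same element always hashes to the same bit
  fp2 <- pathFingerprint(makeMolGraph("C", code = "other"))
  expect_identical(fpBits(fp), fpBits(fp2))
  ## a different element hashes elsewhere (for this fixture pair)
  fpN <- pathFingerprint(makeMolGraph("N", code = "NH3"))
  expect_false(identical(fpBits(fp), fpBits(fpN)))
})

test_that("constitutional isomers get different fingerprints", {
  ## oracle: enumerate paths by hand. Butane has a 4-atom chain (C-C-C-C);
  ## isobutane's longest linear path is 3 atoms, and it has three
  ## equivalent 2-atom paths from the central carbon.
  fb <- pathFingerprint(butane)
  fi <- pathFingerprint(isobutane)
  expect_false(identical(fpBits(fb), fpBits(fi)))
  ## both share the paths "C" and "C1C": bit sets must overlap
  expect_gt(length(intersect(fpBits(fb), fpBits(fi))), 0)
})

test_that("bond orders distinguish otherwise identical paths", {
  single <- makeMolGraph(c("C", "C"), data.frame(from = 1, to = 2, order = 1))
  double <- makeMolGraph(c("C", "C"), data.frame(from = 1, to = 2, order = 2))
  expect_false(identical(fpBits(pathFingerprint(single)),
                         fpBits(pathFingerprint(double))))
})

test_that("tanimoto matches direct set arithmetic", {
  mkFp <- function(bits) new("Fingerprint", bits = as.integer(bits),
                             nBits = 2048L, scheme = "test", code = "X")
  a <- mkFp(c(1, 2, 3, 4))
  b <- mkFp(c(3, 4, 5, 6, 7))
  expect_equal(tanimoto(a, b), 2 / 7)
  expect_equal(tanimoto(a, a), 1)
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_equal(tanimoto(mkFp(1:4), mkFp(10:13)), 0)
  short <- new("Fingerprint", bits = 1L, nBits = 64L, scheme = "test",
               code = "Y")
  expect_error(tanimoto(a, short), "length")
})

test_that("one minus tanimoto behaves as a distance on a small set", {
  blobs <- makeFingerprintBlobs(3, 5, seed = 121)
  fps <- blobs$fingerprints
  n <- length(fps)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- 1 - tanimoto(fps[[i]], fps[[j]])
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("threshold clustering recovers planted blobs exactly", {
  blobs <- makeFingerprintBlobs(3, 5, within = 0.9, between = 0.3, seed = 122)
  res <- thresholdCluster(blobs$fingerprints, threshold = 0.8)
  expect_length(clusters(res), 3)
  got <- lapply(clusters(res), sort)
  want <- lapply(split(vapply(blobs$fingerprints, function(f) f@code, ""),
                       blobs$labels), sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  ## centroids belong to their clusters (validity also enforces this)
  expect_true(all(mapply(function(cl, ce) ce %in% cl,
                         clusters(res), centroids(res))))
})

test_that("clustering degenerate cases and threshold monotonicity", {
  blobs <- makeFingerprintBlobs(1, 6, seed = 123)
  expect_length(clusters(thresholdCluster(blobs$fingerprints, 0.8)), 1)

  ## mutually dissimilar singletons stay singletons
  apart <- makeFingerprintBlobs(5, 1, seed = 124)
  res <- thresholdCluster(apart$fingerprints, 0.8)
  expect_length(clusters(res), 5)

  ## cluster count is non-increasing as the threshold loosens
  mixed <- makeFingerprintBlobs(4, 4, within = 0.85, between = 0.2, seed = 125)
  counts <- vapply(c(0.95, 0.8, 0.5, 0.1),
                   function(th) length(clusters(thresholdCluster(
                     mixed$fingerprints, th))), 1L)
  expect_true(all(diff(counts) <= 0))

  ## partition property: every input lands in exactly one cluster
  all <- unlist(clusters(res))
  expect_equal(sort(all), sort(vapply(apart$fingerprints,
                                      function(f) f@code, "")))
})

test_that("SMILES parsing feeds the fingerprint pipeline", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  mol <- molFromSmiles("CCO", code = "EOH")
  expect_equal(mol@elements, c("C", "C", "O"))
  expect_equal(nrow(mol@bonds), 2)
  fp <- pathFingerprint(mol)
  ## paths: C, C, O, CC, CO, CCO -> 5 distinct canonical strings, minus
  ## the duplicate single-atom C
  expect_lte(length(fpBits(fp)), 5)
  expect_gte(length(fpBits(fp)), 4)
})
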