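# Tanimoto similarity, reference distances, threshold derivation and MDS.

test_that("tanimoto similarity matches set arithmetic", {
  expect_equal(tanimotoSimilarity(fpRow(c(1, 5, 9)), fpRow(c(1, 5, 9))), 1)
  expect_equal(tanimotoSimilarity(fpRow(1:2), fpRow(3:4)), 0)
  expect_equal(tanimotoSimilarity(fpRow(1:2), fpRow(2:3)), 1 / 3)
  expect_error(tanimotoSimilarity(fpRow(1, L = 8), fpRow(1, L = 16)),
               "length")
  expect_warning(s0 <- tanimotoSimilarity(integer(8), integer(8)), "empty")
  expect_equal(s0, 1)
})

test_that("the distance matrix agrees with an element-wise oracle", {
  M <- fpMat(list(1:8, 5:12, c(1, 2, 20)))
  D <- tanimotoDistanceMatrix(M)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(M)))
  expect_equal(unname(D), unname(t(D)))
  for (i in 1:3) for (j in 1:3)
    expect_equal(D[i, j], 1 - tanimotoSimilarity(M[i, ], M[j, ]))
  same <- fpMat(list(1:4, 1:4)); disj <- fpMat(list(1:4, 9:12))
  expect_equal(tanimotoDistanceMatrix(same)[1, 2], 0)
  expect_equal(tanimotoDistanceMatrix(disj)[1, 2], 1)
})

test_that("tanimoto distance satisfies the triangle inequality", {
  set.seed(17)
  for (rep in 1:200) {
    M <- matrix(rbinom(3 * 24, 1, 0.4), 3, 24)
    if (any(rowSums(M) == 0)) next
    D <- tanimotoDistanceMatrix(M)
    expect_lte(D[1, 2], D[1, 3] + D[2, 3] + 1e-12)
  }
})

test_that("average cluster distance is the mean member distance", {
  ref1 <- ClusterReference("S1", FingerprintMatrix(fpMat(list(1:6))), 0.6)
  expect_equal(unname(averageClusterDistance(fpRow(1:6), ref1)), 0)
  expect_equal(unname(averageClusterDistance(fpRow(10:15), ref1)), 1)
  # members at similarity 0.8 and 0.4 from the query -> mean distance 0.4
  query <- fpRow(1:4)
  ref2 <- ClusterReference("S2",
    FingerprintMatrix(fpMat(list(1:5, c(1, 2, 6)))), 0.6)
  expect_equal(unname(averageClusterDistance(query, ref2)), 0.4)
})

test_that("adding a member moves the mean distance in the right direction", {
  set.seed(23)
  for (rep in 1:50) {
    rows <- replicate(4, which(rbinom(24, 1, 0.5) == 1), simplify = FALSE)
    if (any(lengths(rows) == 0)) next
    q <- fpRow(rows[[1]], L = 24)
    refA <- ClusterReference("S1",
      FingerprintMatrix(fpMat(rows[2:3], L = 24)), 0.5)
    refB <- ClusterReference("S1",
      FingerprintMatrix(fpMat(rows[2:4], L = 24)), 0.5)
    dNew <- 1 - tanimotoSimilarity(q, fpRow(rows[[4]], L = 24))
    mA <- averageClusterDistance(q, refA)
    mB <- averageClusterDistance(q, refB)
    if (dNew > mA) expect_gt(mB, mA) else if (dNew < mA) expect_lt(mB, mA)
  }
})

test_that("the threshold lands in the widest gap of the distance distribution", {
  # distances to the single reference member: 0 (itself), 0.1, 0.2, 0.7, 0.8
  train <- FingerprintMatrix(fpMat(
    list(1:10, 1:9, 1:8, 1:3, 1:2),
    ids = c("ref", "a", "b", "c", "d")))
  ref <- ClusterReference("S1", train["ref"], 0.5)
  expect_equal(deriveThreshold(train, ref), 0.45)
})

test_that("flat distance distributions fall back or error", {
  # distances in steps of 0.05: no gap wide enough
  train <- FingerprintMatrix(fpMat(
    c(list(1:20), lapply(seq(19, 10), function(k) 1:k)), ids = letters[1:11]))
  ref <- ClusterReference("S1", train["a"], 0.5)
  expect_warning(th <- deriveThreshold(train, ref, default = 0.6), "default")
  expect_equal(th, 0.6)
  allSame <- FingerprintMatrix(fpMat(list(1:5, 1:5, 1:5)))
  refSame <- ClusterReference("S1", allSame[1], 0.5)
  expect_error(deriveThreshold(allSame, refSame), "manually")
})

test_that("classical MDS reconstructs a line and orders variance", {
  x <- c(0, 1, 2, 3)
  D <- abs(outer(x, x, "-"))
  rownames(D) <- colnames(D) <- paste0("p", 1:4)
  expect_warning(res <- classicalMds(D, k = 2), "rank")
  ev <- explainedVariance(res)
  expect_gt(ev[1], 0.999)
  expect_true(all(diff(ev) <= 1e-12))
  Dhat <- as.matrix(dist(mdsCoords(res)))
  expect_lt(max(abs(unname(Dhat) - unname(D))), 1e-8)
})

test_that("degenerate MDS inputs behave", {
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  res <- classicalMds(D0, k = 1)
  expect_equal(max(abs(mdsCoords(res))), 0)
  expect_warning(classicalMds(abs(outer(0:3, 0:3, "-")), k = 3), "rank|trunc")
})

test_that("MDS separates the planted fingerprint clusters", {
  cfg <- syntheticConfig(nS1 = 20, nS2 = 20, nC3Sweet = 0, nC3NonSweet = 0)
  ds <- generateSyntheticDataset(cfg, seed = 4)
  D <- tanimotoDistanceMatrix(ds$fingerprints)
  res <- classicalMds(D, k = 2)
  sil <- cluster::silhouette(
    as.integer(ds$metadata$cluster[rownames(D)] == "S1") + 1L,
    dist(mdsCoords(res)))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("sweet reference clusters are recovered from the embedding", {
  ds <- generateSyntheticDataset(seed = 21)
  cl <- findSweetClusters(ds$fingerprints, ds$labels)
  expect_named(cl$references, c("S1", "S2"))
  truth <- ds$metadata$cluster[names(cl$assignment)]
  gates <- cl$assignment != "C3"
  # every gated molecule is a planted cluster member, and vice versa
  expect_equal(unname(gates), unname(truth != "C3"))
  expect_equal(refThreshold(cl$references$S1), 0.6)
  expect_equal(refThreshold(cl$references$S2), 0.8)
})
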