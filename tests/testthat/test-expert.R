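# Gate semantics, strict consensus, full predictions and the applicability
# domain.

test_that("the gate routes by average distance with strict thresholds", {
  sysAny <- tinyExpertSystem("any")
  sysAll <- tinyExpertSystem("all")
  # on-bit sets and their distances to S1 {1..10} / S2 {21..30}:
  qs <- list(nearS1 = 1:5,                  # (0.5, 1.0)
             nearBoth = c(1:6, 21:24),      # (~0.57, 0.75)
             farBoth = c(1, 32))            # (~0.91, 1.0)
  Q <- fpMat(qs, ids = c("n1", "nb", "fb"))
  gAny <- gate(Q, sysAny)
  expect_equal(gAny$pathway, c("gate_S1", "gate_S1", "consensus"))
  expect_equal(gAny$gateSweet, c(TRUE, TRUE, FALSE))
  expect_equal(gAny["n1", "dS1"], 0.5)
  gAll <- gate(Q, sysAll)
  expect_equal(gAll$gateSweet, c(FALSE, TRUE, FALSE))
})

test_that("a distance at the threshold does not pass (strict inequality)", {
  sys <- tinyExpertSystem("any")
  q <- fpRow(1:4)                           # similarity 4/10 to S1
  d <- unname(averageClusterDistance(q, sys@refS1))
  expect_gte(d, 0.6)
  expect_equal(gate(matrix(q, 1), sys)$pathway, "consensus")
  qIn <- fpRow(c(1:4, 11))                  # similarity 4/11 -> d < 0.64; widen S1
  sys2 <- sys; sys2@refS1@threshold <- 0.65
  expect_equal(gate(matrix(qIn, 1), sys2)$pathway, "gate_S1")
})

test_that("strict consensus only assigns on agreement", {
  lv <- c("sweet", "non-sweet")
  f <- function(x) factor(x, levels = lv)
  expect_equal(as.character(consensusPredict(f("sweet"), f("sweet"))), "sweet")
  expect_true(is.na(consensusPredict(f("sweet"), f("non-sweet"))))
  expect_true(is.na(consensusPredict(f("non-sweet"), f(NA))))
  expect_equal(as.character(consensusPredict(f(c("sweet", "non-sweet")),
                                             f(c("sweet", "non-sweet")))),
               c("sweet", "non-sweet"))
})

test_that("predict() covers every molecule through exactly one pathway", {
  ds <- generateSyntheticDataset(seed = 71)
  sp <- stratifiedSplit(ds$labels, 90, seed = 71)
  sys <- trainExpertSystem(ds$fingerprints[sp$train],
                           ds$descriptors[sp$train, ], ds$labels[sp$train])
  pr <- predict(sys, ds$fingerprints[sp$test], ds$descriptors[sp$test, ])
  expect_equal(nrow(pr), length(sp$test))
  expect_equal(sum(table(pr$pathway)), length(sp$test))
  # gate pathways always classify sweet
  expect_true(all(pr$class[startsWith(pr$pathway, "gate")] == "sweet"))
  # consensus rows agree with both components or are rejected
  cons <- pr[pr$pathway == "consensus" & !is.na(pr$class), ]
  expect_true(all(cons$class == cons$n3Class & cons$class == cons$plsdaClass))
})

test_that("an empty gate reduces the system to pure consensus", {
  sys <- tinyExpertSystem("any")
  sysNoGate <- sys
  sysNoGate@refS1 <- NULL
  sysNoGate@refS2 <- NULL
  d <- shiftedDescriptors(n = 10, seed = 72)
  fps <- FingerprintMatrix(
    matrix(rbinom(10 * 32, 1, 0.4), 10, 32,
           dimnames = list(rownames(d$X), NULL)),
    fingerprintParams(nBits = 32L))
  pr <- predict(sysNoGate, fps, d$X)
  expect_true(all(pr$pathway == "consensus"))
  direct <- consensusPredict(predict(sys@n3, d$X)$class,
                             predict(sys@plsda, d$X)$class)
  expect_equal(pr$class, as.character(direct))
})

test_that("empty input gives empty output and missing descriptors error per molecule", {
  sys <- tinyExpertSystem("any")
  empty <- predict(sys, matrix(integer(0), 0, 32))
  expect_equal(nrow(empty), 0L)
  d <- shiftedDescriptors(n = 10, seed = 73)
  # both queries far from either gate; only the first has a descriptor row
  fps <- FingerprintMatrix(
    fpMat(list(c(15, 16, 31), c(14, 17, 32)),
          ids = c(rownames(d$X)[1], "ghost")),
    fingerprintParams(nBits = 32L))
  pr <- predict(sys, fps, d$X)
  expect_true(is.na(pr$class[pr$id == "ghost"]))
  expect_match(pr$error[pr$id == "ghost"], "missing")
  expect_true(is.na(pr$error[pr$id != "ghost"]))
})

test_that("leverage-based applicability domain behaves like a Mahalanobis fence", {
  sys <- tinyExpertSystem("any")
  d <- shiftedDescriptors(n = 40, effect = 3, seed = 7L)       # the training set
  ad <- assessAd(sys, d$X)
  # mean training leverage is nLv / n (standard identity)
  expect_equal(mean(ad$leverage), sys@plsda@nLv / nrow(d$X), tolerance = 1e-10)
  # the centroid has leverage ~0
  centroid <- matrix(colMeans(d$X), 1, dimnames = list("c", colnames(d$X)))
  expect_lt(assessAd(sys, centroid)$leverage, 1e-20)
  expect_true(assessAd(sys, centroid)$leverageOk)
  # a far outlier exceeds h*
  far <- centroid + 100 * apply(d$X, 2, sd)
  adFar <- assessAd(sys, far)
  expect_gt(adFar$leverage, adFar$hStar)
  expect_false(adFar$inAD)
  # >= 95% of training molecules pass the similarity branch by construction
  expect_gte(mean(ad$simOk), 0.95)
  # gate-path molecules are in-AD by definition
  expect_true(assessAd(sys, far, gatePath = TRUE)$inAD)
})
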