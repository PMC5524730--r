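# Rejection-aware metrics, stratified splitting and Monte Carlo validation.

test_that("metrics follow the rejection-aware definitions", {
  yTrue <- factor(rep(c("sweet", "non-sweet"), c(6, 4)),
                  levels = c("sweet", "non-sweet"))
  yPred <- c("sweet", "sweet", "non-sweet", "sweet", NA, "sweet",
             "non-sweet", "non-sweet", NA, "sweet")
  rep <- classMetrics(yTrue, yPred)
  # hand confusion over the 8 assigned: sweet 4/5 correct, non-sweet 2/3
  expect_equal(sensitivitySweet(rep), 4 / 5)
  expect_equal(specificitySweet(rep), 2 / 3)
  expect_equal(nonErrorRate(rep), (4 / 5 + 2 / 3) / 2)
  expect_equal(pctNotAssigned(rep), 20)
  expect_equal(sum(rep@confusion), 8)
})

test_that("perfect predictions report cleanly and ids do not matter", {
  y <- factor(rep(c("sweet", "non-sweet"), 5), levels = c("sweet", "non-sweet"))
  rep <- classMetrics(y, as.character(y), context = "test")
  expect_equal(c(nonErrorRate(rep), sensitivitySweet(rep),
                 specificitySweet(rep), pctNotAssigned(rep)), c(1, 1, 1, 0))
  expect_equal(classMetrics(setNames(y, letters[1:10]), as.character(y))@ner,
               rep@ner)
})

test_that("degenerate metric inputs are rejected", {
  y <- factor(rep(c("sweet", "non-sweet"), 3), levels = c("sweet", "non-sweet"))
  pred <- c("sweet", NA, "sweet", NA, "sweet", NA)  # no assigned non-sweet
  expect_error(classMetrics(y, pred), "undefined")
  expect_error(classMetrics(y[1:3], pred), "length")
})

test_that("the NER identity is enforced at construction", {
  expect_error(new("ValidationReport", ner = 0.9, snSweet = 0.8,
                   spSweet = 0.8, pctNotAssigned = 0,
                   confusion = matrix(0, 2, 2), context = "fitting"),
               "NER")
})

test_that("stratified splits use largest-remainder proportional allocation", {
  labels <- factor(rep(c("sweet", "non-sweet"), c(435, 214)),
                   levels = c("sweet", "non-sweet"))
  sp <- stratifiedSplit(labels, 161, seed = 2)
  expect_length(sp$test, 161)
  expect_equal(unname(table(labels[sp$test])), c(108, 53),
               ignore_attr = TRUE)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  # empty test set, and determinism of counts across seeds
  sp0 <- stratifiedSplit(labels, 0)
  expect_length(sp0$test, 0)
  spA <- stratifiedSplit(labels, 161, seed = 5)
  expect_false(identical(sp$test, spA$test))
  expect_equal(table(labels[spA$test]), table(labels[sp$test]))
  expect_error(stratifiedSplit(factor(c("sweet", "non-sweet", "sweet")), 2),
               "emptied")
})

test_that("an always-correct classifier scores NER 1 in Monte Carlo", {
  labels <- factor(rep(c("sweet", "non-sweet"), c(40, 20)),
                   levels = c("sweet", "non-sweet"))
  oracle <- function(trainIdx, testIdx, iterSeed) labels[testIdx]
  rep <- monteCarloValidate(labels, oracle, nIter = 25, seed = 3)
  expect_equal(nonErrorRate(rep), 1)
  expect_equal(pctNotAssigned(rep), 0)
  # cumulative pool size = iterations x evaluation size
  expect_equal(sum(rep@confusion), 25 * 12)
})

test_that("one iteration equals a single stratified split at the derived seed", {
  labels <- factor(rep(c("sweet", "non-sweet"), c(30, 20)),
                   levels = c("sweet", "non-sweet"))
  seen <- NULL
  spy <- function(trainIdx, testIdx, iterSeed) {
    seen <<- list(train = trainIdx, test = testIdx, seed = iterSeed)
    labels[testIdx]
  }
  monteCarloValidate(labels, spy, nIter = 1, seed = 10)
  manual <- stratifiedSplit(labels, 10, seed = seen$seed)
  expect_equal(seen$test, manual$test)
  expect_equal(seen$train, manual$train)
})

test_that("failing iterations are skipped up to the abort limit", {
  labels <- factor(rep(c("sweet", "non-sweet"), 25),
                   levels = c("sweet", "non-sweet"))
  flaky <- local({
    i <- 0L
    function(trainIdx, testIdx, iterSeed) {
      i <<- i + 1L
      if (i == 1L) stop("boom")
      labels[testIdx]
    }
  })
  rep <- monteCarloValidate(labels, flaky, nIter = 40, seed = 4)
  expect_length(attr(rep, "failures"), 1L)
  alwaysFail <- function(...) stop("boom")
  expect_error(monteCarloValidate(labels, alwaysFail, nIter = 20, seed = 4),
               "failed")
})

test_that("reports assemble into a performance table", {
  y <- factor(rep(c("sweet", "non-sweet"), 10), levels = c("sweet", "non-sweet"))
  tab <- performanceTable(list(Fitting = classMetrics(y, as.character(y))))
  expect_equal(tab["Fitting", "NER"], 1)
  expect_equal(colnames(tab), c("NER", "Sn", "Sp", "pct_not_assigned"))
})
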