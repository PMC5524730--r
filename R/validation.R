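## Rejection-aware classification metrics, stratified splitting and Monte
## Carlo (leave-many-out) validation.

#' Rejection-aware classification metrics
#'
#' Sensitivity of the sweet class is the fraction of sweet molecules
#' correctly classified among the *assigned* sweet molecules; specificity is
#' the analogous fraction for the non-sweet class (in a two-class problem
#' this equals the sensitivity of the non-sweet class). Not-assigned
#' molecules are excluded from both numerator and denominator and reported
#' as a percentage of the total. The non-error rate is the mean of the two
#' sensitivities.
#'
#' @param yTrue factor of true classes.
#' @param yPred factor of predicted classes; \code{NA} (or the literal value
#'   "not-assigned") marks rejected molecules.
#' @param context one of "fitting", "cv", "monte_carlo", "test".
#' @param sweetClass the label of the sweet (positive) class.
#' @return a \linkS4class{ValidationReport}.
#' @export
classMetrics <- function(yTrue, yPred, context = "fitting",
                         sweetClass = "sweet") {
  yTrue <- as.factor(yTrue)
  yPred <- as.character(yPred)
  yPred[yPred %in% "not-assigned"] <- NA_character_
  if (length(yTrue) != length(yPred)) stop("label vectors differ in length")
  if (nlevels(yTrue) != 2L) stop("expected exactly two true classes")
  if (!sweetClass %in% levels(yTrue)) stop("sweet class not present in labels")
  other <- setdiff(levels(yTrue), sweetClass)
  assigned <- !is.na(yPred)
  nSweet <- sum(assigned & yTrue == sweetClass)
  nOther <- sum(assigned & yTrue == other)
  if (nSweet == 0L || nOther == 0L)
    stop("metrics undefined: a class has no assigned molecules")
  conf <- table(factor(as.character(yTrue[assigned]),
                       levels = c(sweetClass, other)),
                factor(yPred[assigned], levels = c(sweetClass, other)))
  sn <- conf[sweetClass, sweetClass] / nSweet
  sp <- conf[other, other] / nOther
  new("ValidationReport", ner = (sn + sp) / 2, snSweet = sn, spSweet = sp,
      pctNotAssigned = 100 * mean(!assigned),
      confusion = unclass(conf), context = context)
}

#' Stratified train/test split
#'
#' Test molecules are drawn at random while maintaining the class
#' proportions: the per-class test counts are \code{nTest * classSize / n}
#' rounded by the largest-remainder rule so that they sum exactly to
#' \code{nTest}.
#'
#' @param labels factor of class labels.
#' @param nTest total test-set size.
#' @param seed integer seed; memberships are deterministic under it.
#' @return list with integer index vectors \code{train} and \code{test}
#'   (disjoint, covering).
#' @export
stratifiedSplit <- function(labels, nTest, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  stopifnot(nTest >= 0L, nTest < n)
  sizes <- table(labels)
  exact <- nTest * as.numeric(sizes) / n
  counts <- floor(exact)
  rem <- exact - counts
  short <- nTest - sum(counts)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  counts <- stats::setNames(as.integer(counts), names(sizes))
  if (any(as.integer(sizes) - counts == 0L & as.integer(sizes) > 0L))
    stop("a class would be emptied from the training set")
  withLocalSeed(seed, {
    test <- integer(0)
    for (cl in names(sizes)) {
      idx <- which(labels == cl)
      test <- c(test, sort(sample(idx, counts[[cl]])))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Monte Carlo (leave-many-out) validation
#'
#' Each iteration draws a stratified 80/20 split, refits on the training
#' fraction and predicts the evaluation fraction; the predictions accumulate
#' across iterations and the metrics are computed once on the cumulative
#' pool. Per-iteration seeds derive deterministically from the master seed.
#'
#' @param labels factor of class labels for the full dataset.
#' @param fitPredict function \code{(trainIdx, testIdx, iterSeed)} returning
#'   a factor (or character) of predicted classes for \code{testIdx}, with
#'   \code{NA} for rejections. See [monteCarloExpert()] for the expert-system
#'   wrapper.
#' @param nIter number of iterations (the reference analysis uses 1000).
#' @param evalFraction fraction of molecules held out per iteration.
#' @param seed master seed.
#' @param maxFailFraction iterations may fail (they are logged and skipped);
#'   more than this fraction aborts.
#' @return a \linkS4class{ValidationReport} with context "monte_carlo"; the
#'   attribute "failures" holds the messages of skipped iterations.
#' @export
monteCarloValidate <- function(labels, fitPredict, nIter = 1000L,
                               evalFraction = 0.2, seed = 1L,
                               maxFailFraction = 0.05) {
  labels <- as.factor(labels)
  n <- length(labels)
  nEval <- max(1L, round(evalFraction * n))
  poolTrue <- character(0); poolPred <- character(0)
  failures <- character(0)
  for (i in seq_len(nIter)) {
    iterSeed <- (seed + 7919 * i) %% 2147483647L
    res <- tryCatch({
      sp <- stratifiedSplit(labels, nEval, seed = iterSeed)
      pred <- fitPredict(sp$train, sp$test, iterSeed)
      if (length(pred) != length(sp$test))
        stop("fitPredict returned the wrong number of predictions")
      list(true = as.character(labels[sp$test]), pred = as.character(pred))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("iteration %d: %s", i, conditionMessage(res)))
      if (length(failures) > maxFailFraction * nIter)
        stop("too many Monte Carlo iterations failed (",
             length(failures), " of ", nIter, ")")
      next
    }
    poolTrue <- c(poolTrue, res$true)
    poolPred <- c(poolPred, res$pred)
  }
  rep <- classMetrics(factor(poolTrue, levels = levels(labels)), poolPred,
                      context = "monte_carlo")
  attr(rep, "failures") <- failures
  rep
}

#' Emit validation reports as a performance table
#'
#' @param reports named list of \linkS4class{ValidationReport}s, e.g.
#'   \code{list(Fitting = ..., `Monte Carlo` = ..., `Test set` = ...)}.
#' @return data.frame with columns NER, Sn, Sp and \code{pct_not_assigned}.
#' @export
performanceTable <- function(reports) {
  data.frame(
    NER = vapply(reports, nonErrorRate, numeric(1)),
    Sn = vapply(reports, sensitivitySweet, numeric(1)),
    Sp = vapply(reports, specificitySweet, numeric(1)),
    pct_not_assigned = vapply(reports, pctNotAssigned, numeric(1)),
    row.names = names(reports))
}
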