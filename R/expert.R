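## The assembled expert system: similarity gate over the S1/S2 references,
## strict consensus of N3 + PLSDA for everything the gate does not catch,
## and the two-branch applicability-domain assessment.

#' Train the similarity-gated expert system
#'
#' Identifies the sweet reference clusters on the training fingerprints
#' (see [findSweetClusters()]), then calibrates the consensus classifiers on
#' the remaining (C3) training molecules: optional correlation-based
#' reduction and GA descriptor selection, hyperparameter optimization of the
#' N3 alpha and the PLSDA latent-variable count by venetian-blind CV, and the
#' final fits. The N3 applicability-domain cutoff (a low percentile of the
#' training molecules' average similarity to each other) is precomputed.
#'
#' @param fps training \linkS4class{FingerprintMatrix}.
#' @param descriptors training \linkS4class{DescriptorTable} (same
#'   molecules).
#' @param labels factor of sweet / non-sweet labels, aligned with \code{fps}.
#' @param gateRule "any" (sweet if either reference gate passes; default) or
#'   "all".
#' @param thresholds gate cutoffs, default \code{c(S1 = 0.6, S2 = 0.8)}.
#' @param deriveThresholds derive cutoffs from the distance distribution
#'   instead.
#' @param doVwsp apply [vwspReduce()] before model calibration.
#' @param vwspThreshold correlation cutoff of the reduction.
#' @param gaCfg optional [gaConfig()]; when supplied, GA-VSS is run once per
#'   classifier (each spec scored by its own CV) and each model is fit on
#'   its selected subset.
#' @param alphaGrid,lvGrid hyperparameter grids.
#' @param adSettings list with \code{simPercentile} (default 5) and
#'   \code{requireBoth} (default TRUE) for the applicability domain.
#' @param clusterArgs extra arguments passed to [findSweetClusters()].
#' @return a fitted \linkS4class{ExpertSystem}; the training cluster
#'   assignment is available in the attribute "clusters".
#' @export
trainExpertSystem <- function(fps, descriptors, labels, gateRule = "any",
                              thresholds = c(S1 = 0.6, S2 = 0.8),
                              deriveThresholds = FALSE, doVwsp = TRUE,
                              vwspThreshold = 0.95, gaCfg = NULL,
                              alphaGrid = seq(0.5, 3, by = 0.5),
                              lvGrid = 1:10,
                              adSettings = list(simPercentile = 5,
                                                requireBoth = TRUE),
                              clusterArgs = list()) {
  stopifnot(identical(moleculeIds(fps), moleculeIds(descriptors)),
            nrow(fps@bits) == length(labels))
  labels <- droplevels(as.factor(labels))
  cl <- do.call(findSweetClusters,
                c(list(fps = fps, labels = labels, thresholds = thresholds,
                       deriveThresholds = deriveThresholds), clusterArgs))
  c3 <- cl$assignment == "C3"
  X <- cleanDescriptors(descriptors)@values[c3, , drop = FALSE]
  yC3 <- droplevels(labels[c3])
  if (nlevels(yC3) != 2L)
    stop("the consensus training set lost a class; gate covers too much")
  keep <- if (doVwsp) vwspReduce(X, threshold = vwspThreshold) else colnames(X)
  X <- X[, keep, drop = FALSE]

  selectFor <- function(spec) {
    if (is.null(gaCfg)) return(colnames(X))
    retainedDescriptors(gaVss(X, yC3, spec, gaCfg))
  }
  n3Cols <- selectFor(n3Spec())
  plsCols <- selectFor(plsdaSpec())

  alpha <- optimizeHyperparameter(X[, n3Cols, drop = FALSE], yC3, n3Spec,
                                  alphaGrid, tie = "high")$best
  maxLv <- min(max(lvGrid), ncol(X[, plsCols, drop = FALSE]),
               nrow(X) - 2L)
  nLv <- optimizeHyperparameter(X[, plsCols, drop = FALSE], yC3, plsdaSpec,
                                lvGrid[lvGrid <= maxLv], tie = "low")$best
  n3 <- fitN3(X[, n3Cols, drop = FALSE], yC3, alpha = alpha)
  pls <- fitPlsda(X[, plsCols, drop = FALSE], yC3, nLv = nLv)

  ## N3 AD branch: distribution of each training molecule's average
  ## similarity to the other training molecules, in N3 descriptor space
  selfSim <- .n3AvgSimilarity(n3, n3@X, exclude_self = TRUE)
  cutoff <- stats::quantile(selfSim, adSettings$simPercentile / 100,
                            names = FALSE)

  sys <- new("ExpertSystem", fpParams = fps@params,
             refS1 = cl$references[["S1"]], refS2 = cl$references[["S2"]],
             gateRule = gateRule, n3 = n3, plsda = pls,
             descriptors = union(n3Cols, plsCols),
             adSettings = adSettings, adSimCutoff = cutoff)
  attr(sys, "clusters") <- cl$assignment
  sys
}

## average N3 similarity (1 - average Euclidean distance on range-scaled
## descriptors) of already-scaled query rows to the model's training rows
.n3AvgSimilarity <- function(m, Qscaled, exclude_self = FALSE) {
  S <- 1 - .avgEuclidean(Qscaled, m@X)
  if (exclude_self) (rowSums(S) - 1) / (ncol(S) - 1) else rowMeans(S)
}

#' Similarity gate of the expert system
#'
#' Computes the average Jaccard-Tanimoto distances of the query
#' fingerprint(s) to the S1 and S2 references and applies the gate rule with
#' strict inequality: under "any", a molecule is sweet when d_S1 < d*_S1 OR
#' d_S2 < d*_S2 (S1 checked first for the reported pathway); under "all",
#' only when every configured gate passes. Everything else is passed to the
#' consensus classifiers.
#'
#' @param fp binary vector, matrix, or \linkS4class{FingerprintMatrix}.
#' @param sys a fitted \linkS4class{ExpertSystem}.
#' @return data.frame with columns dS1, dS2 (NA when a reference is absent),
#'   gateSweet (logical) and pathway ("gate_S1" / "gate_S2" / "consensus").
#' @export
gate <- function(fp, sys) {
  Q <- if (is(fp, "FingerprintMatrix")) fp@bits
       else if (is.matrix(fp)) fp else matrix(fp, nrow = 1L)
  d1 <- if (!is.null(sys@refS1)) averageClusterDistance(Q, sys@refS1)
        else rep(NA_real_, nrow(Q))
  d2 <- if (!is.null(sys@refS2)) averageClusterDistance(Q, sys@refS2)
        else rep(NA_real_, nrow(Q))
  pass1 <- !is.na(d1) & d1 < if (!is.null(sys@refS1)) sys@refS1@threshold else Inf
  pass2 <- !is.na(d2) & d2 < if (!is.null(sys@refS2)) sys@refS2@threshold else Inf
  sweet <- if (sys@gateRule == "any") pass1 | pass2
           else {  # all configured gates must pass
             checks <- cbind(if (!is.null(sys@refS1)) pass1,
                             if (!is.null(sys@refS2)) pass2)
             if (is.null(checks)) rep(FALSE, nrow(Q)) else apply(checks, 1L, all)
           }
  pathway <- ifelse(!sweet, "consensus", ifelse(pass1, "gate_S1", "gate_S2"))
  data.frame(dS1 = unname(d1), dS2 = unname(d2), gateSweet = sweet,
             pathway = pathway, row.names = rownames(Q))
}

#' Strict consensus of two component predictions
#'
#' A molecule is classified only when both components agree; disagreement,
#' or a rejection by either component, yields not-assigned (\code{NA}).
#'
#' @param pN3,pPls factors (or the data.frames returned by the component
#'   \code{predict} methods) of component predictions.
#' @return factor of consensus classes with \code{NA} for not-assigned.
#' @export
consensusPredict <- function(pN3, pPls) {
  getCls <- function(x) if (is.data.frame(x)) x$class else x
  a <- getCls(pN3); b <- getCls(pPls)
  if (length(a) != length(b)) stop("component predictions differ in length")
  agree <- !is.na(a) & !is.na(b) & as.character(a) == as.character(b)
  out <- a
  out[!agree] <- NA
  out
}

#' Applicability-domain assessment
#'
#' Gate-path molecules are inside the AD by definition (they sit in the
#' well-characterized similarity clusters). Consensus-path molecules are
#' assessed on two branches: the PLSDA leverage
#' \eqn{h = t' (T'T)^{-1} t} in latent-variable score space against the
#' cutoff \eqn{h^* = 3 \, nLv / n_{train}}, and the average N3 similarity to
#' the training molecules against the configured percentile of the training
#' self-similarity distribution. By default both branches must pass.
#'
#' @param sys a fitted \linkS4class{ExpertSystem}.
#' @param descriptors descriptor matrix or \linkS4class{DescriptorTable} for
#'   the query molecules.
#' @param gatePath logical vector: TRUE for molecules that took a gate
#'   pathway (default all FALSE).
#' @return data.frame: inAD, leverage, hStar, leverageOk, avgSim, simCutoff,
#'   simOk.
#' @export
assessAd <- function(sys, descriptors, gatePath = NULL) {
  if (is(descriptors, "DescriptorTable")) descriptors <- descriptors@values
  descriptors <- as.matrix(descriptors)
  n <- nrow(descriptors)
  if (is.null(gatePath)) gatePath <- rep(FALSE, n)
  Tt <- sys@plsda@scores
  G <- solve(crossprod(Tt))
  tq <- plsdaScores(sys@plsda, descriptors)
  h <- rowSums((tq %*% G) * tq)
  hStar <- 3 * sys@plsda@nLv / nrow(Tt)
  Qs <- applyScaler(sys@n3@scaler, descriptors)
  avgSim <- .n3AvgSimilarity(sys@n3, Qs)
  leverageOk <- h <= hStar
  simOk <- avgSim >= sys@adSimCutoff
  both <- isTRUE(sys@adSettings$requireBoth)
  inAD <- gatePath | (if (both) leverageOk & simOk else leverageOk | simOk)
  data.frame(inAD = inAD, leverage = unname(h), hStar = hStar,
             leverageOk = unname(leverageOk), avgSim = unname(avgSim),
             simCutoff = sys@adSimCutoff, simOk = unname(simOk),
             row.names = rownames(descriptors))
}

#' Predict sweetness with the expert system
#'
#' Applies the similarity gate first; molecules it does not classify are
#' passed to the strict N3 + PLSDA consensus, and every molecule receives an
#' applicability-domain verdict. A consensus-path molecule whose descriptor
#' row is missing is reported with an error note; the batch continues.
#'
#' @param object a fitted \linkS4class{ExpertSystem}.
#' @param fps \linkS4class{FingerprintMatrix} of the query molecules.
#' @param descriptors descriptor matrix or \linkS4class{DescriptorTable}
#'   covering (at least) the consensus-path molecules.
#' @return data.frame: id, class ("sweet" / "non-sweet" / NA = not
#'   assigned), pathway, dS1, dS2, n3Class, n3ScoreSweet, plsdaClass, inAD,
#'   leverage, hStar, error.
#' @export
setMethod("predict", "ExpertSystem", function(object, fps, descriptors = NULL) {
  Q <- if (is(fps, "FingerprintMatrix")) fps@bits else as.matrix(fps)
  if (nrow(Q) == 0L)
    return(data.frame(id = character(0), class = character(0),
                      pathway = character(0)))
  ids <- rownames(Q)
  g <- gate(Q, object)
  out <- data.frame(id = ids, class = NA_character_, pathway = g$pathway,
                    dS1 = g$dS1, dS2 = g$dS2, n3Class = NA_character_,
                    n3ScoreSweet = NA_real_, plsdaClass = NA_character_,
                    inAD = NA, leverage = NA_real_, hStar = NA_real_,
                    error = NA_character_, stringsAsFactors = FALSE)
  out$class[g$gateSweet] <- "sweet"
  out$inAD[g$gateSweet] <- TRUE
  need <- which(!g$gateSweet)
  if (length(need)) {
    D <- if (is(descriptors, "DescriptorTable")) descriptors@values
         else if (!is.null(descriptors)) as.matrix(descriptors)
    present <- if (is.null(D)) rep(FALSE, length(need))
               else ids[need] %in% rownames(D)
    out$error[need[!present]] <- "descriptor row missing"
    sub <- need[present]
    if (length(sub)) {
      x <- D[ids[sub], object@descriptors, drop = FALSE]
      pN3 <- predict(object@n3, x)
      pPls <- predict(object@plsda, x)
      ad <- assessAd(object, x)
      out$class[sub] <- as.character(consensusPredict(pN3, pPls))
      out$n3Class[sub] <- as.character(pN3$class)
      if ("sweet" %in% colnames(pN3)) out$n3ScoreSweet[sub] <- pN3[, "sweet"]
      out$plsdaClass[sub] <- as.character(pPls$class)
      out$inAD[sub] <- ad$inAD
      out$leverage[sub] <- ad$leverage
      out$hStar[sub] <- ad$hStar
    }
  }
  rownames(out) <- NULL
  out
})

#' Monte Carlo validation of the expert system
#'
#' Wraps [monteCarloValidate()] for a fitted system: the cluster references
#' and gate thresholds stay fixed from the initial full-training analysis
#' while the consensus classifiers are refit in every iteration on the
#' molecules of the training fraction that the gate does not cover
#' (\code{refit = "classifiers"}); \code{refit = "full"} rebuilds the
#' cluster references per iteration as well.
#'
#' @param sys a fitted \linkS4class{ExpertSystem}.
#' @param fps,descriptors,labels the full dataset.
#' @param nIter,evalFraction,seed see [monteCarloValidate()].
#' @param refit refit scope per iteration.
#' @return a \linkS4class{ValidationReport} with context "monte_carlo".
#' @export
monteCarloExpert <- function(sys, fps, descriptors, labels, nIter = 1000L,
                             evalFraction = 0.2, seed = 1L,
                             refit = c("classifiers", "full")) {
  refit <- match.arg(refit)
  stopifnot(identical(moleculeIds(fps), moleculeIds(descriptors)))
  D <- descriptors@values
  fitPredict <- function(trainIdx, testIdx, iterSeed) {
    it <- if (refit == "full") {
      trainExpertSystem(fps[trainIdx], descriptors[trainIdx, ],
                        labels[trainIdx], gateRule = sys@gateRule,
                        doVwsp = FALSE,
                        alphaGrid = sys@n3@alpha, lvGrid = sys@plsda@nLv,
                        adSettings = sys@adSettings)
    } else {
      refitConsensus(sys, fps[trainIdx], D[trainIdx, , drop = FALSE],
                     labels[trainIdx])
    }
    predict(it, fps[testIdx], D[testIdx, , drop = FALSE])$class
  }
  monteCarloValidate(labels, fitPredict, nIter = nIter,
                     evalFraction = evalFraction, seed = seed)
}

#' Refit the consensus classifiers of a fitted system
#'
#' Keeps the gate references, thresholds, descriptor subsets and
#' hyperparameters, and refits the N3 and PLSDA models (and the N3 AD
#' cutoff) on the gate-uncovered molecules of a new training set.
#'
#' @param sys a fitted \linkS4class{ExpertSystem}.
#' @param fps,descriptors,labels the new training data (descriptors as a
#'   matrix or \linkS4class{DescriptorTable}).
#' @return an \linkS4class{ExpertSystem} with refitted classifiers.
#' @export
refitConsensus <- function(sys, fps, descriptors, labels) {
  if (is(descriptors, "DescriptorTable")) descriptors <- descriptors@values
  g <- gate(fps, sys)
  c3 <- !g$gateSweet
  y <- droplevels(as.factor(labels[c3]))
  if (nlevels(y) != 2L) stop("consensus training subset lost a class")
  n3Cols <- names(sys@n3@scaler@shift)
  plsCols <- names(sys@plsda@scaler@shift)
  X <- descriptors[c3, , drop = FALSE]
  n3 <- fitN3(X[, n3Cols, drop = FALSE], y, alpha = sys@n3@alpha)
  pls <- fitPlsda(X[, plsCols, drop = FALSE], y, nLv = sys@plsda@nLv)
  selfSim <- .n3AvgSimilarity(n3, n3@X, exclude_self = TRUE)
  out <- sys
  out@n3 <- n3
  out@plsda <- pls
  out@adSimCutoff <- stats::quantile(selfSim,
                                     sys@adSettings$simPercentile / 100,
                                     names = FALSE)
  out
}
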