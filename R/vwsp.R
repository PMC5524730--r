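## V-WSP unsupervised variable reduction: keep a well-spread subset of
## descriptors in correlation space so that every retained pair correlates
## below the threshold and every removed descriptor is represented by a
## retained one.

#' V-WSP correlation-based descriptor reduction
#'
#' Works on the distance 1 - |r|. Starting from a seed descriptor, all
#' descriptors with |r| >= threshold to the seed are removed; the surviving
#' descriptor nearest to the current seed becomes the next seed, and the
#' walk repeats until no descriptor is left. The retained set is the seed
#' sequence. With \code{threshold = 1} only exact duplicates are removed.
#'
#' Seed rule: by default the descriptor with the highest mean absolute
#' correlation to all others, which removes the densest redundancy first;
#' ties, and ties in the nearest-survivor step, break by lexicographic
#' descriptor name so the result is invariant to column order.
#'
#' @param X numeric matrix or \linkS4class{DescriptorTable}.
#' @param threshold absolute-correlation cutoff, default 0.95.
#' @param seedRule "maxcor" (default) or the name of the descriptor to start
#'   from.
#' @return character vector of retained descriptor names.
#' @export
vwspReduce <- function(X, threshold = 0.95, seedRule = "maxcor") {
  if (is(X, "DescriptorTable")) X <- X@values
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least two descriptors")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ", paste(colnames(X)[sds == 0], collapse = ", "))
  R <- abs(stats::cor(X))
  nm <- colnames(R)
  ord <- order(nm)  # lexicographic tie-break
  alive <- rep(TRUE, ncol(R))
  retained <- character(0)
  seed <- if (identical(seedRule, "maxcor")) {
    mc <- (rowSums(R) - 1) / (ncol(R) - 1)
    ordIdx <- ord[which.max(mc[ord])]
    ordIdx
  } else {
    i <- match(seedRule, nm)
    if (is.na(i)) stop("unknown seed descriptor: ", seedRule)
    i
  }
  while (any(alive)) {
    retained <- c(retained, nm[seed])
    tooClose <- alive & R[seed, ] >= threshold - 1e-12   # includes the seed itself
    alive[tooClose] <- FALSE
    alive[seed] <- FALSE
    if (!any(alive)) break
    dSeed <- 1 - R[seed, ]
    dSeed[!alive] <- Inf
    cand <- ord[alive[ord]]
    seed <- cand[which.min(dSeed[cand])]
  }
  sort(retained)
}
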