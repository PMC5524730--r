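## Genetic-algorithm variable subset selection (GA-VSS). Chromosomes are
## descriptor subsets; fitness is the cross-validated non-error rate under
## the 5-group venetian-blind scheme. Replacement is generational with
## elitism, so the best-so-far fitness is monotone non-decreasing, and the
## whole search is deterministic under the configured seed.

#' GA-VSS configuration
#'
#' Defaults are conservative small-model QSAR conventions; all are exposed.
#'
#' @param populationSize chromosomes per generation (>= 2).
#' @param nGenerations generations to evolve.
#' @param pCrossover probability that a pair of parents recombines.
#' @param pMutation per-gene inclusion/exclusion flip probability.
#' @param maxSize maximum descriptors per chromosome.
#' @param elitism chromosomes copied unchanged into the next generation.
#' @param G cancellation groups for the fitness cross-validation.
#' @param refine apply a greedy backward-elimination pass to the winning
#'   chromosome, dropping descriptors whose removal does not lower the
#'   cross-validated fitness (the classic GA/backward hybrid); counters the
#'   growth bias of per-gene mutation toward the size cap.
#' @param seed integer seed; the search is reproducible under it.
#' @return validated configuration list.
#' @export
gaConfig <- function(populationSize = 30L, nGenerations = 100L,
                     pCrossover = 0.5, pMutation = 0.01, maxSize = 15L,
                     elitism = 1L, G = 5L, refine = TRUE, seed = 1L) {
  stopifnot(populationSize >= 2L, nGenerations >= 1L,
            pCrossover >= 0, pCrossover <= 1,
            pMutation >= 0, pMutation <= 1,
            maxSize >= 1L, elitism >= 0L, elitism < populationSize)
  list(populationSize = as.integer(populationSize),
       nGenerations = as.integer(nGenerations),
       pCrossover = pCrossover, pMutation = pMutation,
       maxSize = as.integer(maxSize), elitism = as.integer(elitism),
       G = as.integer(G), refine = isTRUE(refine), seed = as.integer(seed))
}

.chromKey <- function(chrom) paste(which(chrom), collapse = ",")

.repairChrom <- function(chrom, maxSize) {
  k <- sum(chrom)
  if (k == 0L) chrom[sample.int(length(chrom), 1L)] <- TRUE
  else if (k > maxSize) {
    drop <- sample(which(chrom), k - maxSize)
    chrom[drop] <- FALSE
  }
  chrom
}

#' Genetic-algorithm variable subset selection
#'
#' @param X descriptor matrix or \linkS4class{DescriptorTable} (normally
#'   already reduced by [vwspReduce()]).
#' @param y factor of class labels.
#' @param spec a [classifierSpec()] scored inside the fitness CV.
#' @param cfg a [gaConfig()].
#' @return a \linkS4class{SelectionResult}. Among chromosomes tied on the
#'   final best NER, the one with the most balanced sensitivity/specificity
#'   (smallest |Sn - Sp|) is reported.
#' @export
gaVss <- function(X, y, spec, cfg = gaConfig()) {
  if (is(X, "DescriptorTable")) X <- X@values
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  p <- ncol(X)
  withLocalSeed(cfg$seed, {
    cache <- new.env(parent = emptyenv())
    evalChrom <- function(chrom) {
      key <- .chromKey(chrom)
      if (!is.null(cache[[key]])) return(cache[[key]])
      rep <- tryCatch(
        classMetrics(y, venetianBlindCv(X[, chrom, drop = FALSE], y, spec,
                                        G = cfg$G), context = "cv"),
        error = function(e) NULL)
      val <- if (is.null(rep)) {
        list(fit = -Inf, sn = NA_real_, sp = NA_real_,
             note = "fitness evaluation failed; chromosome discarded")
      } else list(fit = nonErrorRate(rep), sn = sensitivitySweet(rep),
                  sp = specificitySweet(rep), note = NULL)
      cache[[key]] <- val
      val
    }

    pop <- replicate(cfg$populationSize, {
      chrom <- rep(FALSE, p)
      chrom[sample.int(p, sample.int(min(cfg$maxSize, p), 1L))] <- TRUE
      chrom
    }, simplify = FALSE)
    fits <- vapply(pop, function(ch) evalChrom(ch)$fit, numeric(1))
    trace <- numeric(cfg$nGenerations)

    for (gen in seq_len(cfg$nGenerations)) {
      ordFit <- order(fits, decreasing = TRUE)
      newPop <- pop[ordFit[seq_len(cfg$elitism)]]
      while (length(newPop) < cfg$populationSize) {
        pick <- function() {  # binary tournament
          ij <- sample.int(length(pop), 2L)
          pop[[ij[if (fits[ij[1L]] >= fits[ij[2L]]) 1L else 2L]]]
        }
        c1 <- pick(); c2 <- pick()
        if (stats::runif(1) < cfg$pCrossover) {
          mask <- stats::runif(p) < 0.5
          tmp <- c1
          c1[mask] <- c2[mask]; c2[mask] <- tmp[mask]
        }
        mutate <- function(ch) {
          flip <- stats::runif(p) < cfg$pMutation
          .repairChrom(xor(ch, flip), cfg$maxSize)
        }
        newPop <- c(newPop, list(mutate(c1)))
        if (length(newPop) < cfg$populationSize) newPop <- c(newPop, list(mutate(c2)))
      }
      pop <- newPop
      fits <- vapply(pop, function(ch) evalChrom(ch)$fit, numeric(1))
      trace[gen] <- max(fits)
    }

    best <- max(fits)
    tied <- which(fits >= best - 1e-12)
    bal <- vapply(tied, function(i) {
      v <- evalChrom(pop[[i]])
      abs(v$sn - v$sp)
    }, numeric(1))
    winner <- pop[[tied[which.min(bal)]]]
    if (cfg$refine) {
      repeat {
        if (sum(winner) <= 1L) break
        cur <- evalChrom(winner)$fit
        candidates <- which(winner)
        drops <- vapply(candidates, function(j) {
          ch <- winner; ch[j] <- FALSE
          evalChrom(ch)$fit
        }, numeric(1))
        best <- which.max(drops)
        if (drops[best] >= cur) winner[candidates[best]] <- FALSE else break
      }
    }
    v <- evalChrom(winner)
    new("SelectionResult", retained = colnames(X)[winner],
        trace = cummax(trace), ner = v$fit, snSweet = v$sn, spSweet = v$sp,
        perBlock = list())
  })
}

#' Two-stage block-wise GA-VSS
#'
#' Stage 1 runs [gaVss()] separately inside every descriptor block; stage 2
#' reruns it on the union of the stage-1 selections. With a single block the
#' stage-1 result is returned directly, which makes the operation coincide
#' with plain [gaVss()] at the same seed.
#'
#' @param X a \linkS4class{DescriptorTable} whose block map covers all
#'   descriptors.
#' @param y factor of class labels.
#' @param spec a [classifierSpec()].
#' @param cfg a [gaConfig()]; stage-1 runs derive their seeds from it.
#' @return a \linkS4class{SelectionResult} with the per-block stage-1
#'   results in \code{perBlock}.
#' @export
blockwiseSelection <- function(X, y, spec, cfg = gaConfig()) {
  stopifnot(is(X, "DescriptorTable"))
  blocks <- descBlocks(X)
  if (!length(blocks) || !all(descNames(X) %in% names(blocks)))
    stop("block map must cover all descriptors")
  labs <- unique(blocks[descNames(X)])
  perBlock <- list()
  survivors <- character(0)
  for (b in seq_along(labs)) {
    members <- names(blocks)[blocks == labs[b]]
    members <- intersect(descNames(X), members)
    if (length(members) == 0L) { warning("empty block ", labs[b]); next }
    if (length(members) == 1L) {  # nothing to search over
      survivors <- c(survivors, members)
      next
    }
    cfgB <- cfg; cfgB$seed <- cfg$seed + b - 1L
    res <- gaVss(X@values[, members, drop = FALSE], y, spec, cfgB)
    perBlock[[labs[b]]] <- res
    survivors <- c(survivors, retainedDescriptors(res))
  }
  if (length(labs) == 1L && length(perBlock) == 1L) {
    out <- perBlock[[1L]]
    out@perBlock <- perBlock
    return(out)
  }
  final <- gaVss(X@values[, survivors, drop = FALSE], y, spec, cfg)
  final@perBlock <- perBlock
  final
}
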