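## Synthetic fixture generator.
##
## Emulates the structure the expert system exploits in real data: two
## planted sweet clusters whose members share a common scaffold bit block
## (standing in for the aspartyl-like S1 and sugar-like S2 clusters), a
## heterogeneous remainder (C3) of sweet and non-sweet molecules with random
## fingerprints, and a descriptor table in which a few informative
## descriptors carry a class-dependent mean shift while blocks of correlated
## nuisance descriptors carry none.

#' Synthetic dataset configuration
#'
#' Defaults follow the study conditions of the method: a dominant sweet
#' class (roughly 2:1 sweet to non-sweet), two similarity clusters that are
#' recoverable at average-distance thresholds 0.6 / 0.8, six informative
#' descriptors at an effect size of 1.5 standard deviations among a hundred,
#' and correlated nuisance blocks to exercise correlation-based reduction.
#'
#' @param nS1,nS2 members of the two planted sweet clusters.
#' @param nC3Sweet,nC3NonSweet sweet / non-sweet molecules outside the
#'   clusters.
#' @param nBits fingerprint width.
#' @param scaffoldBits shared scaffold bits per planted cluster.
#' @param privateBits random private bits per planted-cluster member.
#' @param c3Bits random bits per C3 molecule.
#' @param nInformative descriptors with a class mean shift.
#' @param effectSize mean shift of the sweet class, in SD units.
#' @param nNuisance descriptors without class signal, generated in
#'   correlated blocks.
#' @param nuisanceRho within-block correlation of nuisance descriptors.
#' @param nuisanceBlockSize nuisance descriptors per correlated block.
#' @return validated configuration list.
#' @export
syntheticConfig <- function(nS1 = 40L, nS2 = 30L, nC3Sweet = 80L,
                            nC3NonSweet = 150L, nBits = 2048L,
                            scaffoldBits = 200L, privateBits = 50L,
                            c3Bits = 250L, nInformative = 6L,
                            effectSize = 1.5, nNuisance = 94L,
                            nuisanceRho = 0.7, nuisanceBlockSize = 10L) {
  cfg <- list(nS1 = as.integer(nS1), nS2 = as.integer(nS2),
              nC3Sweet = as.integer(nC3Sweet),
              nC3NonSweet = as.integer(nC3NonSweet),
              nBits = as.integer(nBits), scaffoldBits = as.integer(scaffoldBits),
              privateBits = as.integer(privateBits), c3Bits = as.integer(c3Bits),
              nInformative = as.integer(nInformative),
              effectSize = as.numeric(effectSize),
              nNuisance = as.integer(nNuisance),
              nuisanceRho = as.numeric(nuisanceRho),
              nuisanceBlockSize = as.integer(nuisanceBlockSize))
  if (2L * cfg$scaffoldBits + cfg$privateBits > cfg$nBits ||
      cfg$c3Bits > cfg$nBits)
    stop("configuration error: requested bits exceed fingerprint width")
  if (cfg$nuisanceRho < 0 || cfg$nuisanceRho >= 1)
    stop("configuration error: nuisanceRho must be in [0, 1)")
  if (any(unlist(cfg[c("nS1", "nS2", "nC3Sweet", "nC3NonSweet")]) < 0L))
    stop("configuration error: negative group size")
  cfg
}

## run expr under a locally seeded RNG, restoring the caller's RNG state
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic fingerprint + descriptor dataset
#'
#' @param config see [syntheticConfig()].
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return list with \code{fingerprints} (\linkS4class{FingerprintMatrix}),
#'   \code{descriptors} (\linkS4class{DescriptorTable}), \code{labels}
#'   (factor sweet / non-sweet) and \code{metadata} (cluster assignment of
#'   every molecule, the scaffold bit positions, and the names of the
#'   informative descriptors).
#' @export
generateSyntheticDataset <- function(config = syntheticConfig(), seed = 1L) {
  withLocalSeed(seed, {
    cfg <- config
    n <- cfg$nS1 + cfg$nS2 + cfg$nC3Sweet + cfg$nC3NonSweet
    ids <- sprintf("mol%04d", seq_len(n))
    cluster <- factor(rep(c("S1", "S2", "C3", "C3"),
                          c(cfg$nS1, cfg$nS2, cfg$nC3Sweet, cfg$nC3NonSweet)),
                      levels = c("S1", "S2", "C3"))
    labels <- factor(rep(c("sweet", "sweet", "sweet", "non-sweet"),
                         c(cfg$nS1, cfg$nS2, cfg$nC3Sweet, cfg$nC3NonSweet)),
                     levels = c("sweet", "non-sweet"))

    scaffoldPool <- sample.int(cfg$nBits, 2L * cfg$scaffoldBits)
    scafS1 <- scaffoldPool[seq_len(cfg$scaffoldBits)]
    scafS2 <- scaffoldPool[cfg$scaffoldBits + seq_len(cfg$scaffoldBits)]
    bits <- matrix(0L, n, cfg$nBits, dimnames = list(ids, NULL))
    for (i in seq_len(n)) {
      on <- switch(as.character(cluster[i]),
        S1 = c(scafS1, sample(setdiff(seq_len(cfg$nBits), scafS1),
                              cfg$privateBits)),
        S2 = c(scafS2, sample(setdiff(seq_len(cfg$nBits), scafS2),
                              cfg$privateBits)),
        C3 = sample.int(cfg$nBits, cfg$c3Bits))
      bits[i, on] <- 1L
    }

    p <- cfg$nInformative + cfg$nNuisance
    descNamesAll <- sprintf("D%03d", seq_len(p))
    informative <- descNamesAll[seq_len(cfg$nInformative)]
    X <- matrix(stats::rnorm(n * p), n, p, dimnames = list(ids, descNamesAll))
    shift <- ifelse(labels == "sweet", cfg$effectSize, 0)
    X[, informative] <- X[, informative] + shift
    blockOf <- stats::setNames(rep("B01", cfg$nInformative), informative)
    if (cfg$nNuisance > 0L) {
      nb <- ceiling(cfg$nNuisance / cfg$nuisanceBlockSize)
      col <- cfg$nInformative
      for (b in seq_len(nb)) {
        size <- min(cfg$nuisanceBlockSize, p - col)
        z <- stats::rnorm(n)
        for (j in seq_len(size)) {
          col <- col + 1L
          X[, col] <- sqrt(cfg$nuisanceRho) * z +
            sqrt(1 - cfg$nuisanceRho) * X[, col]
          blockOf[descNamesAll[col]] <- sprintf("B%02d", b + 1L)
        }
      }
    }

    perm <- sample.int(n)
    list(
      fingerprints = FingerprintMatrix(bits[perm, , drop = FALSE],
                                       fingerprintParams(nBits = cfg$nBits)),
      descriptors = DescriptorTable(X[perm, , drop = FALSE], blockOf),
      labels = stats::setNames(labels[perm], ids[perm]),
      metadata = list(cluster = stats::setNames(cluster[perm], ids[perm]),
                      scaffoldS1 = sort(scafS1), scaffoldS2 = sort(scafS2),
                      informative = informative),
      config = cfg, seed = seed)
  })
}
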