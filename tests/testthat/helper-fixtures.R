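# Fixtures built in code; no stored data files.

# fingerprint row with the given on-bits
fpRow <- function(on, L = 32L) {
  v <- integer(L)
  v[on] <- 1L
  v
}

fpMat <- function(rows, L = 32L, ids = NULL) {
  m <- do.call(rbind, lapply(rows, fpRow, L = L))
  rownames(m) <- if (is.null(ids)) sprintf("q%02d", seq_along(rows)) else ids
  m
}

# perfectly separable dataset: the single descriptor equals the class dummy
separableDescriptors <- function(n = 20L) {
  stopifnot(n %% 2L == 0L)
  y <- factor(rep(c("sweet", "non-sweet"), n / 2L),
              levels = c("sweet", "non-sweet"))
  X <- cbind(dummy = as.numeric(y == "sweet"))
  rownames(X) <- sprintf("m%03d", seq_len(n))
  list(X = X, y = setNames(y, rownames(X)))
}

# class-shifted Gaussian descriptor data
shiftedDescriptors <- function(n = 60L, p = 4L, effect = 2, seed = 1L) {
  set.seed(seed)
  y <- factor(rep(c("sweet", "non-sweet"), length.out = n),
              levels = c("sweet", "non-sweet"))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("m%03d", seq_len(n)),
                              sprintf("D%02d", seq_len(p))))
  X[y == "sweet", seq_len(min(2L, p))] <-
    X[y == "sweet", seq_len(min(2L, p))] + effect
  list(X = X, y = setNames(y, rownames(X)))
}

# hand-built expert system: two single-member references over 32 bits
# (S1 = bits 1..10 at threshold 0.6, S2 = bits 21..30 at threshold 0.8)
# and consensus classifiers on a separable two-descriptor problem
tinyExpertSystem <- function(gateRule = "any") {
  refS1 <- ClusterReference("S1",
    FingerprintMatrix(fpMat(list(1:10), ids = "s1ref")), 0.6)
  refS2 <- ClusterReference("S2",
    FingerprintMatrix(fpMat(list(21:30), ids = "s2ref")), 0.8)
  d <- shiftedDescriptors(n = 40L, effect = 3, seed = 7L)
  n3 <- fitN3(d$X, d$y, alpha = 1.5)
  pls <- fitPlsda(d$X, d$y, nLv = 1L)
  selfSim <- sweetgate:::.n3AvgSimilarity(n3, n3@X, exclude_self = TRUE)
  new("ExpertSystem", fpParams = fingerprintParams(nBits = 32L),
      refS1 = refS1, refS2 = refS2, gateRule = gateRule,
      n3 = n3, plsda = pls, descriptors = colnames(d$X),
      adSettings = list(simPercentile = 5, requireBoth = TRUE),
      adSimCutoff = unname(quantile(selfSim, 0.05)))
}

# independent brute-force computation of the rank-weighted class scores
bruteN3 <- function(Xtrain, y, query, alpha) {
  rng <- apply(Xtrain, 2, range)
  sc <- function(v) pmin(pmax((v - rng[1, ]) / (rng[2, ] - rng[1, ]), 0), 1)
  Zt <- t(apply(Xtrain, 1, sc)); q <- sc(query)
  s <- numeric(nrow(Zt))
  for (i in seq_len(nrow(Zt)))
    s[i] <- 1 - sqrt(mean((q - Zt[i, ])^2))
  r <- rank(-s, ties.method = "average")
  ci <- s / r^alpha
  vapply(levels(y), function(g) sum(ci[y == g]) / sum(ci), numeric(1))
}
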