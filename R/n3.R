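## N3 (N-nearest neighbours): every training molecule contributes to a class
## score, weighted by its similarity to the query divided by its similarity
## rank raised to alpha. Similarity is 1 minus the average Euclidean
## distance, d = sqrt(mean((x - xi)^2)), on range-scaled descriptors, so both
## d and s live in [0, 1]. Rank ties receive the average rank of the tied
## block, which makes predictions independent of training-row order.

#' Fit an N3 classifier
#'
#' @param X numeric descriptor matrix or \linkS4class{DescriptorTable}.
#' @param y factor with two levels.
#' @param alpha rank-weight exponent (> 0); larger values localize the
#'   classifier towards the nearest neighbour.
#' @return an \linkS4class{N3Model}.
#' @export
fitN3 <- function(X, y, alpha = 1.5) {
  if (is(X, "DescriptorTable")) X <- X@values
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 1L) stop("training labels required")
  scaler <- fitScaler(X, "range")
  new("N3Model", X = applyScaler(scaler, X), y = y, alpha = alpha,
      scaler = scaler)
}

## average Euclidean distances between the rows of two scaled matrices,
## computed from the explicit differences (not the inner-product expansion)
## so that exact geometric ties rank identically to a direct computation
.avgEuclidean <- function(Q, X) {
  out <- matrix(0, nrow(Q), nrow(X))
  for (i in seq_len(nrow(Q)))
    out[i, ] <- sqrt(colMeans((t(X) - Q[i, ])^2))
  out
}

#' N3 class scores for query molecules
#'
#' For query similarity \eqn{s_i = 1 - d_i} to training molecule i (ranked
#' \eqn{r_i = 1} for the most similar), the contribution is
#' \eqn{c_i = s_i / r_i^\alpha} and the score of class g is
#' \eqn{\sum_{i \in g} c_i / \sum_i c_i}. Scores are a probability vector.
#'
#' @param m an \linkS4class{N3Model}.
#' @param X query descriptor matrix (raw scale; the model's scaler is
#'   applied) or \linkS4class{DescriptorTable}.
#' @return matrix of class scores, one row per query, one column per class.
#' @export
n3ClassScores <- function(m, X) {
  if (is(X, "DescriptorTable")) X <- X@values
  Q <- applyScaler(m@scaler, as.matrix(X))
  S <- 1 - .avgEuclidean(Q, m@X)
  lev <- levels(m@y)
  out <- matrix(0, nrow(Q), length(lev),
                dimnames = list(rownames(Q), lev))
  for (i in seq_len(nrow(Q))) {
    s <- S[i, ]
    if (all(s <= 1e-12)) {
      warning("query has zero similarity to every training molecule; uniform scores")
      out[i, ] <- 1 / length(lev)
      next
    }
    r <- rank(-s, ties.method = "average")
    ci <- s / r^m@alpha
    tot <- sum(ci)
    for (g in seq_along(lev)) out[i, g] <- sum(ci[m@y == lev[g]]) / tot
  }
  out
}

#' Predict with an N3 classifier
#'
#' Assigns the class with the larger score; an exact tie is a rejection
#' (class \code{NA}).
#'
#' @param object an \linkS4class{N3Model}.
#' @param newdata query descriptor matrix or \linkS4class{DescriptorTable}.
#' @return data.frame with \code{class} (NA = not assigned) and one score
#'   column per class.
#' @export
setMethod("predict", "N3Model", function(object, newdata) {
  sc <- n3ClassScores(object, newdata)
  top <- apply(sc, 1L, function(v) {
    w <- which(v >= max(v) - 1e-15)
    if (length(w) == 1L) colnames(sc)[w] else NA_character_
  })
  cls <- top
  out <- data.frame(class = factor(cls, levels = colnames(sc)), sc,
                    check.names = FALSE)
  rownames(out) <- rownames(sc)
  out
})
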