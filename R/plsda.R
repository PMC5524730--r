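## PLSDA: NIPALS PLS2 regression of a centred two-column class dummy matrix
## on autoscaled descriptors, with class assignment by the larger predicted
## response. For one latent variable the first weight vector reduces to the
## normalized X'y direction, which the tests exploit as a closed-form check.

#' Fit a PLSDA classifier
#'
#' @param X numeric descriptor matrix (molecules x descriptors, named
#'   columns) or a \linkS4class{DescriptorTable}.
#' @param y factor with exactly two levels; the first level is coded as the
#'   first dummy column.
#' @param nLv number of latent variables.
#' @return a \linkS4class{PLSDAModel}.
#' @export
fitPlsda <- function(X, y, nLv = 1L) {
  if (is(X, "DescriptorTable")) X <- X@values
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  nLv <- as.integer(nLv)
  if (nlevels(y) != 2L) stop("both classes must be present")
  if (nrow(X) < nLv + 2L) stop("too few samples for ", nLv, " latent variables")
  scaler <- fitScaler(X, "autoscale")
  E <- applyScaler(scaler, X)
  Yd <- cbind(as.numeric(y == levels(y)[1L]), as.numeric(y == levels(y)[2L]))
  yMeans <- colMeans(Yd)
  F <- sweep(Yd, 2L, yMeans)
  p <- ncol(E); n <- nrow(E)
  W <- matrix(0, p, nLv); P <- matrix(0, p, nLv)
  Q <- matrix(0, 2L, nLv); TT <- matrix(0, n, nLv)
  for (a in seq_len(nLv)) {
    u <- F[, 1L]
    tOld <- rep(Inf, n)
    for (it in seq_len(500L)) {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) stop("nLv exceeds the rank of the descriptor matrix")
      w <- w / nw
      tv <- drop(E %*% w)
      q <- drop(crossprod(F, tv)) / sum(tv^2)
      u <- drop(F %*% q) / sum(q^2)
      if (sqrt(sum((tv - tOld)^2)) < 1e-12 * sqrt(sum(tv^2))) break
      tOld <- tv
    }
    ss <- sum(tv^2)
    if (ss < 1e-12) stop("nLv exceeds the rank of the descriptor matrix")
    pv <- drop(crossprod(E, tv)) / ss
    E <- E - tcrossprod(tv, pv)
    F <- F - tcrossprod(tv, q)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- q; TT[, a] <- tv
  }
  R <- W %*% solve(crossprod(P, W))   # X-rotation: scores = Xs %*% R
  B <- R %*% t(Q)
  dimnames(B) <- list(colnames(X), levels(y))
  rownames(W) <- rownames(P) <- colnames(X)
  new("PLSDAModel", nLv = nLv, weights = W, loadings = P, yLoadings = Q,
      coef = B, scores = TT, yMeans = yMeans, classes = levels(y),
      scaler = scaler)
}

#' Latent-variable scores of new data
#'
#' @param m a \linkS4class{PLSDAModel}.
#' @param X descriptor matrix or \linkS4class{DescriptorTable}.
#' @return n x nLv score matrix in the model's score space.
#' @export
plsdaScores <- function(m, X) {
  if (is(X, "DescriptorTable")) X <- X@values
  Z <- applyScaler(m@scaler, X)
  Z %*% m@weights %*% solve(crossprod(m@loadings, m@weights))
}

#' Predict with a PLSDA classifier
#'
#' Assigns the class with the larger predicted dummy response; an exact tie
#' is a rejection (class \code{NA}).
#'
#' @param object a \linkS4class{PLSDAModel}.
#' @param newdata descriptor matrix or \linkS4class{DescriptorTable}.
#' @return data.frame with the predicted \code{class} (NA = not assigned)
#'   and one response column per class.
#' @export
setMethod("predict", "PLSDAModel", function(object, newdata) {
  if (is(newdata, "DescriptorTable")) newdata <- newdata@values
  Z <- applyScaler(object@scaler, as.matrix(newdata))
  Yhat <- sweep(Z %*% object@coef, 2L, object@yMeans, "+")
  cls <- ifelse(Yhat[, 1L] > Yhat[, 2L], object@classes[1L],
                ifelse(Yhat[, 2L] > Yhat[, 1L], object@classes[2L],
                       NA_character_))
  out <- data.frame(class = factor(cls, levels = object@classes),
                    Yhat, check.names = FALSE)
  rownames(out) <- rownames(newdata)
  out
})
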