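## Venetian-blind cross-validation and hyperparameter optimization over a
## small fit/predict interface shared by the two classifiers.

#' Classifier specification
#'
#' A minimal fit/predict pair used by cross-validation, hyperparameter
#' optimization and genetic descriptor selection. \code{fit(X, y)} returns a
#' model; \code{predict(model, X)} returns a factor of class labels with
#' \code{NA} for rejected molecules.
#'
#' @param fit,predict functions as described above.
#' @param label short description used in messages.
#' @return a classifier spec (list).
#' @export
classifierSpec <- function(fit, predict, label = "classifier") {
  structure(list(fit = fit, predict = predict, label = label),
            class = "classifierSpec")
}

#' @rdname classifierSpec
#' @param alpha N3 rank-weight exponent.
#' @export
n3Spec <- function(alpha = 1.5)
  classifierSpec(function(X, y) fitN3(X, y, alpha = alpha),
                 function(m, X) predict(m, X)$class,
                 sprintf("N3 (alpha = %g)", alpha))

#' @rdname classifierSpec
#' @param nLv number of PLSDA latent variables.
#' @export
plsdaSpec <- function(nLv = 1L)
  classifierSpec(function(X, y) fitPlsda(X, y, nLv = nLv),
                 function(m, X) predict(m, X)$class,
                 sprintf("PLSDA (%d LV)", nLv))

#' Venetian-blind cross-validation
#'
#' Sample i (0-based, in stored order) is held out in cancellation group
#' i mod G, so the folds interleave through the dataset like venetian
#' blinds. Every sample is predicted exactly once.
#'
#' @param X descriptor matrix or \linkS4class{DescriptorTable}.
#' @param y factor of class labels.
#' @param spec a [classifierSpec()].
#' @param G number of cancellation groups (G = n gives leave-one-out).
#' @return factor of out-of-fold predictions aligned with the rows of X
#'   (NA = not assigned).
#' @export
venetianBlindCv <- function(X, y, spec, G = 5L) {
  if (is(X, "DescriptorTable")) X <- X@values
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X)
  stopifnot(n >= G, n == length(y))
  fold <- ((seq_len(n) - 1L) %% G) + 1L
  pred <- factor(rep(NA_character_, n), levels = levels(y))
  for (g in seq_len(G)) {
    test <- fold == g
    if (nlevels(droplevels(y[!test])) < 2L)
      stop("a training fold lost a class; reorder the samples (stratified interleaving)")
    m <- spec$fit(X[!test, , drop = FALSE], y[!test])
    pred[test] <- spec$predict(m, X[test, , drop = FALSE])
  }
  names(pred) <- rownames(X)
  pred
}

#' Optimize a classifier hyperparameter by cross-validated error
#'
#' Evaluates every grid value with [venetianBlindCv()] and returns the value
#' minimizing the classification error rate 1 - NER. Ties are broken toward
#' the simpler model: \code{tie = "low"} prefers the smaller grid value
#' (fewer latent variables), \code{tie = "high"} the larger (stronger N3
#' rank damping).
#'
#' @param X,y data as in [venetianBlindCv()].
#' @param specFactory function mapping a grid value to a [classifierSpec()],
#'   e.g. \code{n3Spec} or \code{plsdaSpec}.
#' @param grid candidate values; the default N3 alpha grid is 0.5 to 3 in
#'   steps of 0.5 and the PLSDA grid 1 to 10 latent variables.
#' @param G cancellation groups.
#' @param tie tie-breaking direction.
#' @return list: \code{best}, \code{errors} (CV error per grid value),
#'   \code{grid}.
#' @export
optimizeHyperparameter <- function(X, y, specFactory, grid,
                                   G = 5L, tie = c("low", "high")) {
  tie <- match.arg(tie)
  if (!length(grid)) stop("empty grid")
  errors <- vapply(grid, function(v) {
    rep <- tryCatch(
      classMetrics(y, venetianBlindCv(X, y, specFactory(v), G = G),
                   context = "cv"),
      error = function(e) NULL)
    if (is.null(rep)) NA_real_ else 1 - nonErrorRate(rep)
  }, numeric(1))
  if (all(is.na(errors))) stop("every grid value failed cross-validation")
  cand <- which(errors <= min(errors, na.rm = TRUE) + 1e-12)
  best <- if (tie == "low") grid[cand[1L]] else grid[cand[length(cand)]]
  list(best = best, errors = stats::setNames(errors, grid), grid = grid)
}
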