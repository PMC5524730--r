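## Column scalers shared by the classifiers: PLSDA autoscales the
## descriptors, N3 range-scales them onto [0, 1].

#' Fit a column scaler on training data
#'
#' Autoscaling uses the sample (n - 1) standard deviation. Range scaling
#' maps the training minimum/maximum onto 0/1.
#'
#' @param X numeric training matrix with descriptor names as colnames.
#' @param method "autoscale" or "range".
#' @return a \linkS4class{Scaler}.
#' @export
fitScaler <- function(X, method = c("autoscale", "range")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in descriptor matrix")
  if (method == "autoscale") {
    shift <- colMeans(X)
    div <- apply(X, 2L, stats::sd)
  } else {
    shift <- apply(X, 2L, min)
    div <- apply(X, 2L, max) - shift
  }
  bad <- div <= 0 | !is.finite(div)
  if (any(bad))
    stop("constant column(s): ", paste(colnames(X)[bad], collapse = ", "))
  new("Scaler", method = method,
      shift = stats::setNames(shift, colnames(X)),
      div = stats::setNames(div, colnames(X)))
}

#' Apply a fitted scaler
#'
#' Columns are matched by name. Under range scaling, values outside the
#' training range are clipped into [0, 1] so that distances stay bounded.
#'
#' @param s a \linkS4class{Scaler}.
#' @param X numeric matrix whose colnames cover the scaler's columns.
#' @return scaled matrix over the scaler's columns, in training column order.
#' @export
applyScaler <- function(s, X) {
  X <- as.matrix(X)
  cols <- names(s@shift)
  if (!all(cols %in% colnames(X)))
    stop("descriptor column mismatch: missing ",
         paste(setdiff(cols, colnames(X)), collapse = ", "))
  Z <- sweep(sweep(X[, cols, drop = FALSE], 2L, s@shift), 2L, s@div, "/")
  if (s@method == "range") Z <- pmin(pmax(Z, 0), 1)
  Z
}
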