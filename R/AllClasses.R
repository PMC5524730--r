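#' @import methods
NULL

#' Binary fingerprint matrix
#'
#' Molecules by bits (0/1) matrix produced by hashed circular fingerprints.
#' Row names are molecule identifiers; the column count equals the hash width
#' recorded in \code{params$nBits}.
#'
#' @slot bits integer matrix of 0/1 entries, one row per molecule.
#' @slot params list with \code{nBits}, \code{bitsPerPattern}, \code{maxOrder}.
#' @export
setClass("FingerprintMatrix",
  representation(bits = "matrix", params = "list"),
  validity = function(object) {
    b <- object@bits
    if (is.null(rownames(b))) return("bits must have molecule ids as rownames")
    if (anyDuplicated(rownames(b))) return("duplicated molecule ids")
    if (length(b) && !all(b %in% c(0L, 1L))) return("entries must be 0/1")
    p <- object@params
    if (!is.null(p$nBits) && ncol(b) != p$nBits)
      return("ncol(bits) must equal params$nBits")
    TRUE
  }
)

#' Molecular descriptor table
#'
#' Molecules by named numeric descriptors, with an optional map from
#' descriptor name to descriptor block (used by block-wise selection).
#'
#' @slot values numeric matrix; rownames are molecule ids, colnames descriptor
#'   names.
#' @slot blockOf named character vector mapping descriptor name to block
#'   label; may be empty.
#' @export
setClass("DescriptorTable",
  representation(values = "matrix", blockOf = "character"),
  validity = function(object) {
    v <- object@values
    if (is.null(rownames(v)) || is.null(colnames(v)))
      return("values must carry molecule ids (rownames) and descriptor names (colnames)")
    if (anyDuplicated(colnames(v))) return("duplicated descriptor names")
    if (anyNA(v)) return("missing values present; clean the table first")
    if (length(object@blockOf) &&
        !all(names(object@blockOf) %in% colnames(v)))
      return("blockOf names must be descriptor names")
    TRUE
  }
)

#' Sweet reference cluster
#'
#' The fingerprints of the members of a sweet reference cluster (S1 or S2)
#' together with the average-distance threshold of its similarity gate.
#'
#' @slot name cluster label, e.g. "S1".
#' @slot members a \linkS4class{FingerprintMatrix} of the cluster members.
#' @slot threshold gate cutoff on the average Jaccard-Tanimoto distance,
#'   strictly between 0 and 1.
#' @export
setClass("ClusterReference",
  representation(name = "character", members = "FingerprintMatrix",
                 threshold = "numeric"),
  validity = function(object) {
    if (nrow(object@members@bits) < 1L) return("reference must have members")
    th <- object@threshold
    if (length(th) != 1L || is.na(th) || th <= 0 || th >= 1)
      return("threshold must lie strictly inside (0, 1)")
    TRUE
  }
)

#' Classical multidimensional scaling result
#'
#' @slot coords n x k coordinate matrix, columns ordered by decreasing
#'   explained variance.
#' @slot explainedVariance fraction of (positive-eigenvalue) variance per
#'   coordinate.
#' @export
setClass("MdsResult",
  representation(coords = "matrix", explainedVariance = "numeric"),
  validity = function(object) {
    ev <- object@explainedVariance
    if (any(ev < -1e-12)) return("explained variance fractions must be >= 0")
    if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-12))
      return("explained variance must be non-increasing")
    if (sum(ev) > 1 + 1e-8) return("explained variance fractions must sum to <= 1")
    if (ncol(object@coords) != length(ev))
      return("one variance fraction per coordinate")
    TRUE
  }
)

#' Column scaler (autoscaling or range scaling)
#'
#' Per-column statistics learned on training data. Autoscaling subtracts the
#' mean and divides by the standard deviation; range scaling maps the training
#' range onto [0, 1] (new values are clipped into [0, 1]).
#'
#' @slot method "autoscale" or "range".
#' @slot shift per-column offset (mean or min).
#' @slot div per-column divisor (sd or max - min), all > 0.
#' @export
setClass("Scaler",
  representation(method = "character", shift = "numeric", div = "numeric"),
  validity = function(object) {
    if (!object@method %in% c("autoscale", "range"))
      return("method must be 'autoscale' or 'range'")
    if (length(object@shift) != length(object@div))
      return("shift and div must align")
    if (any(object@div <= 0)) return("all divisors must be > 0 (constant column?)")
    TRUE
  }
)

#' Fitted PLSDA classifier
#'
#' Partial least squares discriminant analysis: NIPALS PLS2 regression of a
#' two-column class dummy matrix on autoscaled descriptors, with class
#' assignment by the larger predicted response.
#'
#' @slot nLv number of latent variables.
#' @slot weights p x nLv X-weight matrix (W).
#' @slot loadings p x nLv X-loading matrix (P).
#' @slot yLoadings 2 x nLv Y-loading matrix (Q).
#' @slot coef p x 2 regression coefficient matrix on scaled X.
#' @slot scores n x nLv training score matrix (T); mutually orthogonal.
#' @slot yMeans training means of the dummy columns (the class proportions).
#' @slot classes the two class labels, in dummy-column order.
#' @slot scaler the autoscaler fitted on training descriptors.
#' @export
setClass("PLSDAModel",
  representation(nLv = "integer", weights = "matrix", loadings = "matrix",
                 yLoadings = "matrix", coef = "matrix", scores = "matrix",
                 yMeans = "numeric", classes = "character", scaler = "Scaler"),
  validity = function(object) {
    if (object@nLv < 1L) return("nLv must be >= 1")
    TT <- crossprod(object@scores)
    off <- TT - diag(diag(TT), nrow = nrow(TT))
    if (max(abs(off)) > 1e-8 * max(1, max(abs(diag(TT)))))
      return("training score vectors must be mutually orthogonal")
    if (length(object@classes) != 2L) return("exactly two classes")
    TRUE
  }
)

#' Fitted N3 (N-nearest neighbours) classifier
#'
#' Similarity-based classifier in which every training molecule contributes
#' to a class score, weighted by its similarity to the query divided by its
#' similarity rank raised to the exponent alpha. Similarity is 1 minus the
#' average Euclidean distance on range-scaled descriptors.
#'
#' @slot X range-scaled training matrix (columns in [0, 1]).
#' @slot y factor of training class labels.
#' @slot alpha rank-weight exponent, > 0.
#' @slot scaler the range scaler fitted on training descriptors.
#' @export
setClass("N3Model",
  representation(X = "matrix", y = "factor", alpha = "numeric",
                 scaler = "Scaler"),
  validity = function(object) {
    if (object@alpha <= 0) return("alpha must be > 0")
    if (nrow(object@X) != length(object@y)) return("X rows must match labels")
    rng <- range(object@X)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      return("training matrix must be range-scaled to [0, 1]")
    TRUE
  }
)

#' Rejection-aware classification report
#'
#' Sensitivity and specificity of the sweet class are computed over assigned
#' molecules only; the not-assigned fraction is reported separately. The
#' non-error rate is the mean of the two class sensitivities, asserted at
#' construction.
#'
#' @slot ner non-error rate, (Sn + Sp) / 2.
#' @slot snSweet sensitivity of the sweet class.
#' @slot spSweet specificity of the sweet class.
#' @slot pctNotAssigned percentage of molecules left unassigned.
#' @slot confusion 2 x 2 confusion matrix over assigned molecules
#'   (rows: true class; columns: predicted class).
#' @slot context one of "fitting", "cv", "monte_carlo", "test".
#' @export
setClass("ValidationReport",
  representation(ner = "numeric", snSweet = "numeric", spSweet = "numeric",
                 pctNotAssigned = "numeric", confusion = "matrix",
                 context = "character"),
  validity = function(object) {
    if (abs(object@ner - (object@snSweet + object@spSweet) / 2) > 1e-12)
      return("NER must equal (Sn + Sp) / 2")
    if (object@pctNotAssigned < 0 || object@pctNotAssigned > 100)
      return("pctNotAssigned is a percentage")
    if (!object@context %in% c("fitting", "cv", "monte_carlo", "test"))
      return("unknown context")
    TRUE
  }
)

#' Descriptor subset selection result
#'
#' @slot retained selected descriptor names.
#' @slot trace best cross-validated fitness (NER) per generation;
#'   non-decreasing under elitism.
#' @slot ner,snSweet,spSweet cross-validated performance of the final subset.
#' @slot perBlock for block-wise selection, the stage-1 results per block.
#' @export
setClass("SelectionResult",
  representation(retained = "character", trace = "numeric", ner = "numeric",
                 snSweet = "numeric", spSweet = "numeric", perBlock = "list"),
  validity = function(object) {
    if (length(object@trace) > 1L && any(diff(object@trace) < -1e-12))
      return("best-fitness trace must be non-decreasing (elitism)")
    TRUE
  }
)

setClassUnion("ClusterReferenceOrNULL", c("ClusterReference", "NULL"))

#' The similarity-gated expert system
#'
#' A fitted expert system: molecules within the configured average-distance
#' thresholds of reference sweet cluster S1 or S2 are classified sweet on
#' structural similarity alone; all other molecules are passed to a strict
#' consensus of the N3 and PLSDA classifiers trained on the remaining
#' (C3) training molecules, and assessed against a two-branch applicability
#' domain (PLSDA leverage and N3 similarity distribution).
#'
#' @slot fpParams fingerprint parameters used at training time.
#' @slot refS1,refS2 the two \linkS4class{ClusterReference} gates (either may
#'   be NULL, disabling that gate).
#' @slot gateRule "any" (sweet if either gate passes; the default) or "all"
#'   (sweet only if both pass).
#' @slot n3 fitted \linkS4class{N3Model} on the C3 training molecules.
#' @slot plsda fitted \linkS4class{PLSDAModel} on the same molecules.
#' @slot descriptors descriptor names the consensus models use.
#' @slot adSettings list: \code{simPercentile} (percentile of training
#'   self-similarities used as the N3 branch cutoff), \code{requireBoth}
#'   (must both AD branches pass for consensus-path molecules).
#' @slot adSimCutoff precomputed similarity cutoff for the N3 AD branch (the
#'   configured percentile of the training molecules' average similarity to
#'   the other training molecules, in N3 descriptor space).
#' @export
setClass("ExpertSystem",
  representation(fpParams = "list", refS1 = "ClusterReferenceOrNULL",
                 refS2 = "ClusterReferenceOrNULL", gateRule = "character",
                 n3 = "N3Model", plsda = "PLSDAModel",
                 descriptors = "character", adSettings = "list",
                 adSimCutoff = "numeric"),
  validity = function(object) {
    if (!object@gateRule %in% c("any", "all"))
      return("gateRule must be 'any' or 'all'")
    TRUE
  }
)
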