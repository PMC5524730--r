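## Jaccard-Tanimoto similarity, cluster reference distances, data-driven
## gate thresholds, classical MDS and reference-cluster construction.

#' Jaccard-Tanimoto similarity of two binary vectors
#'
#' \eqn{s = |A \cap B| / |A \cup B|} on the on-bit sets. Two all-zero
#' vectors are identical objects and return 1 with a warning.
#'
#' @param a,b binary (0/1 or logical) vectors of equal length.
#' @return similarity in [0, 1].
#' @export
tanimotoSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  a <- as.logical(a); b <- as.logical(b)
  un <- sum(a | b)
  if (un == 0L) {
    warning("both fingerprints are empty; returning similarity 1")
    return(1)
  }
  sum(a & b) / un
}

#' Pairwise Jaccard-Tanimoto distance matrix
#'
#' @param fps a \linkS4class{FingerprintMatrix} or 0/1 matrix (rows =
#'   molecules).
#' @return symmetric n x n matrix of distances 1 - s, zero diagonal.
#' @export
tanimotoDistanceMatrix <- function(fps) {
  M <- if (is(fps, "FingerprintMatrix")) fps@bits else as.matrix(fps)
  if (nrow(M) < 2L) stop("need at least two molecules")
  inter <- tcrossprod(M)
  on <- rowSums(M)
  un <- outer(on, on, "+") - inter
  S <- ifelse(un > 0, inter / un, 1)
  D <- 1 - S
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' Construct a ClusterReference
#'
#' @param name cluster label ("S1", "S2", ...).
#' @param members \linkS4class{FingerprintMatrix} of the member molecules.
#' @param threshold average-distance gate cutoff in (0, 1).
#' @return a \linkS4class{ClusterReference}.
#' @export
ClusterReference <- function(name, members, threshold) {
  new("ClusterReference", name = name, members = members,
      threshold = as.numeric(threshold))
}

#' Average Jaccard-Tanimoto distance to a reference cluster
#'
#' Mean over the reference members of (1 - similarity) between the query
#' fingerprint(s) and each member.
#'
#' @param fp a binary vector, or a \linkS4class{FingerprintMatrix} / matrix
#'   of queries (one per row).
#' @param ref a \linkS4class{ClusterReference}.
#' @return numeric vector of mean distances in [0, 1], one per query.
#' @export
averageClusterDistance <- function(fp, ref) {
  R <- ref@members@bits
  if (nrow(R) == 0L) stop("empty cluster reference")
  Q <- if (is(fp, "FingerprintMatrix")) fp@bits
       else if (is.matrix(fp)) fp
       else matrix(fp, nrow = 1L)
  if (ncol(Q) != ncol(R)) stop("fingerprint length mismatch with reference")
  storage.mode(Q) <- "double"
  inter <- tcrossprod(Q, R)
  un <- outer(rowSums(Q), rowSums(R), "+") - inter
  S <- ifelse(un > 0, inter / un, 1)
  stats::setNames(rowMeans(1 - S), rownames(Q))
}

#' Derive a gate threshold from the distance distribution
#'
#' Computes the average distance of every training molecule to the reference
#' cluster and places the cutoff at the midpoint of the widest empty gap of
#' the distribution that lies at or above the reference members' own
#' distances, mirroring a histogram analysis of average similarities. When
#' no gap of at least \code{gapTol} exists the configured \code{default} is
#' returned with a warning.
#'
#' @param trainFps \linkS4class{FingerprintMatrix} of training molecules.
#' @param ref \linkS4class{ClusterReference} (its threshold slot is ignored).
#' @param default fallback cutoff.
#' @param gapTol minimum width for a gap to be considered real.
#' @return distance cutoff in (0, 1).
#' @export
deriveThreshold <- function(trainFps, ref, default = 0.6, gapTol = 0.1) {
  if (nrow(trainFps@bits) < 2L) stop("need at least two training molecules")
  d <- averageClusterDistance(trainFps, ref)
  if (max(d) - min(d) < 1e-12)
    stop("all average distances are equal; choose a threshold manually")
  memb <- intersect(moleculeIds(trainFps), moleculeIds(ref@members))
  dMax <- if (length(memb)) max(d[memb]) else -Inf
  v <- sort(unique(d))
  lo <- v[-length(v)]; hi <- v[-1L]
  eligible <- lo >= dMax
  if (!any(eligible)) eligible <- rep(TRUE, length(lo))  # members span everything
  gaps <- hi - lo
  gaps[!eligible] <- -Inf
  k <- which.max(gaps)
  if (gaps[k] < gapTol) {
    warning("no clear gap in the distance distribution; using default ", default)
    return(default)
  }
  (lo[k] + hi[k]) / 2
}

#' Classical (metric) multidimensional scaling
#'
#' Eigendecomposition-based MDS of a distance matrix. Negative eigenvalues
#' are clipped to zero for the explained-variance accounting, and the
#' coordinates are ordered by decreasing explained variance.
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param k number of output dimensions.
#' @return an \linkS4class{MdsResult}.
#' @export
classicalMds <- function(D, k = 2L) {
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D), tol = 1e-8), k >= 1L)
  n <- nrow(D)
  fit <- suppressWarnings(stats::cmdscale(D, k = min(k, n - 1L), eig = TRUE))
  ev <- pmax(fit$eig, 0)
  ev[ev <= max(ev) * 1e-8] <- 0          # numerically-zero directions
  rank <- sum(ev > 0)
  pts <- fit$points
  if (is.null(pts) || length(pts) == 0L) pts <- matrix(0, n, 0L)
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) > k) pts <- pts[, seq_len(k), drop = FALSE]
  if (k > rank) {
    if (rank > 0L)
      warning("requested ", k, " dimensions but the configuration has rank ",
              rank, "; remaining coordinates are zero")
    if (ncol(pts) > rank) pts[, seq(rank + 1L, ncol(pts))] <- 0
  }
  if (ncol(pts) < k) pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  expl <- if (sum(ev) > 0) c(ev, rep(0, k))[seq_len(k)] / sum(ev)
          else rep(0, k)
  rownames(pts) <- rownames(D)
  new("MdsResult", coords = pts, explainedVariance = expl)
}

#' Identify sweet reference clusters on training fingerprints
#'
#' Embeds the training molecules by classical MDS of the Jaccard-Tanimoto
#' distance matrix, partitions the embedding by k-medoids with k chosen by
#' the average silhouette width, and promotes clusters that are sufficiently
#' large and sweet-pure to gate references (the purest first, as S1).
#'
#' @param fps training \linkS4class{FingerprintMatrix}.
#' @param labels factor of sweet / non-sweet training labels.
#' @param thresholds named numeric, gate cutoffs assigned to the references
#'   in order (default \code{c(S1 = 0.6, S2 = 0.8)}); the shipped defaults
#'   reproduce the published configuration.
#' @param deriveThresholds derive data-driven cutoffs with
#'   [deriveThreshold()] instead of using \code{thresholds} (which then
#'   serve as fallbacks).
#' @param kRange candidate numbers of medoids.
#' @param mdsDims MDS dimensions used for clustering.
#' @param purityMin minimum sweet fraction for a cluster to gate.
#' @param minSize minimum cluster size to gate.
#' @return list: \code{references} (list of \linkS4class{ClusterReference},
#'   at most \code{length(thresholds)}), \code{assignment} (cluster id per
#'   molecule, "C3" for non-gating molecules), \code{mds}, \code{k}.
#' @export
findSweetClusters <- function(fps, labels, thresholds = c(S1 = 0.6, S2 = 0.8),
                              deriveThresholds = FALSE, kRange = 2:6,
                              mdsDims = 2L, purityMin = 0.8, minSize = 10L) {
  stopifnot(nrow(fps@bits) == length(labels))
  D <- tanimotoDistanceMatrix(fps)
  mds <- classicalMds(D, mdsDims)
  co <- mdsCoords(mds)
  best <- NULL; bestSil <- -Inf; bestK <- NA_integer_
  for (k in kRange) {
    if (k >= nrow(co)) next
    pm <- cluster::pam(co, k = k, pamonce = 5)
    sil <- mean(cluster::silhouette(pm$clustering, dist(co))[, "sil_width"])
    if (sil > bestSil) { bestSil <- sil; best <- pm$clustering; bestK <- k }
  }
  if (is.null(best)) stop("could not cluster the embedding")
  sweet <- labels == "sweet"
  stats <- data.frame(
    cluster = sort(unique(best)),
    size = as.vector(table(best)),
    purity = as.vector(tapply(sweet, best, mean)))
  gating <- stats[stats$purity >= purityMin & stats$size >= minSize, , drop = FALSE]
  gating <- gating[order(-gating$purity, -gating$size), , drop = FALSE]
  gating <- utils::head(gating, length(thresholds))
  assignment <- rep("C3", length(best))
  refs <- list()
  ids <- rownames(co)
  for (i in seq_len(nrow(gating))) {
    nm <- names(thresholds)[i]
    memberIdx <- which(best == gating$cluster[i])
    assignment[memberIdx] <- nm
    members <- FingerprintMatrix(fps@bits[memberIdx, , drop = FALSE], fps@params)
    th <- thresholds[[i]]
    ref <- ClusterReference(nm, members, th)
    if (deriveThresholds) {
      th <- tryCatch(deriveThreshold(fps, ref, default = thresholds[[i]]),
                     warning = function(w) thresholds[[i]])
      ref@threshold <- th
    }
    refs[[nm]] <- ref
  }
  list(references = refs,
       assignment = stats::setNames(factor(assignment,
                                           levels = c(names(thresholds), "C3")),
                                    ids),
       mds = mds, k = bestK, silhouette = bestSil)
}
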