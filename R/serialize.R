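## JSON serialization of a fitted expert system: scaler statistics, PLSDA
## weights/coefficients, the N3 training matrix, gate reference bit sets and
## thresholds, versioned with the package version string. JSON keeps the
## model files text-only and diffable.

.mat2list <- function(m)
  list(values = as.numeric(m), nrow = nrow(m),
       rownames = rownames(m), colnames = colnames(m))

.list2mat <- function(l) {
  m <- matrix(as.numeric(l$values), nrow = l$nrow)
  rownames(m) <- l$rownames
  colnames(m) <- l$colnames
  m
}

.scaler2list <- function(s)
  list(method = s@method, columns = names(s@shift),
       shift = as.numeric(s@shift), div = as.numeric(s@div))

.list2scaler <- function(l)
  new("Scaler", method = l$method,
      shift = stats::setNames(as.numeric(l$shift), l$columns),
      div = stats::setNames(as.numeric(l$div), l$columns))

.ref2list <- function(ref) {
  if (is.null(ref)) return(NULL)
  bits <- ref@members@bits
  list(name = ref@name, threshold = ref@threshold, nBits = ncol(bits),
       ids = rownames(bits),
       onBits = lapply(seq_len(nrow(bits)), function(i) which(bits[i, ] == 1L)))
}

.list2ref <- function(l, params) {
  if (is.null(l) || !length(l)) return(NULL)
  bits <- matrix(0L, length(l$ids), l$nBits,
                 dimnames = list(unlist(l$ids), NULL))
  for (i in seq_along(l$onBits)) bits[i, unlist(l$onBits[[i]])] <- 1L
  ClusterReference(l$name, FingerprintMatrix(bits, params), l$threshold)
}

#' Serialize a fitted expert system to JSON
#'
#' @param sys a fitted \linkS4class{ExpertSystem}.
#' @param path destination JSON file.
#' @return invisibly, the path.
#' @export
writeExpertSystem <- function(sys, path) {
  obj <- list(
    package = "sweetgate",
    version = as.character(utils::packageVersion("sweetgate")),
    fpParams = sys@fpParams,
    gateRule = sys@gateRule,
    adSettings = sys@adSettings,
    adSimCutoff = sys@adSimCutoff,
    descriptors = sys@descriptors,
    refS1 = .ref2list(sys@refS1),
    refS2 = .ref2list(sys@refS2),
    n3 = list(alpha = sys@n3@alpha,
              levels = levels(sys@n3@y),
              y = as.character(sys@n3@y),
              X = .mat2list(sys@n3@X),
              scaler = .scaler2list(sys@n3@scaler)),
    plsda = list(nLv = sys@plsda@nLv,
                 weights = .mat2list(sys@plsda@weights),
                 loadings = .mat2list(sys@plsda@loadings),
                 yLoadings = .mat2list(sys@plsda@yLoadings),
                 coef = .mat2list(sys@plsda@coef),
                 scores = .mat2list(sys@plsda@scores),
                 yMeans = as.numeric(sys@plsda@yMeans),
                 classes = sys@plsda@classes,
                 scaler = .scaler2list(sys@plsda@scaler)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Restore an expert system from JSON
#'
#' @param path JSON file written by [writeExpertSystem()].
#' @return an \linkS4class{ExpertSystem}.
#' @export
readExpertSystem <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(l$package, "sweetgate"))
    stop("not a serialized sweetgate model: ", path)
  params <- fingerprintParams(l$fpParams$nBits, l$fpParams$bitsPerPattern,
                              l$fpParams$maxOrder)
  n3 <- new("N3Model", X = .list2mat(l$n3$X),
            y = factor(l$n3$y, levels = l$n3$levels),
            alpha = l$n3$alpha, scaler = .list2scaler(l$n3$scaler))
  pls <- new("PLSDAModel", nLv = as.integer(l$plsda$nLv),
             weights = .list2mat(l$plsda$weights),
             loadings = .list2mat(l$plsda$loadings),
             yLoadings = .list2mat(l$plsda$yLoadings),
             coef = .list2mat(l$plsda$coef),
             scores = .list2mat(l$plsda$scores),
             yMeans = as.numeric(l$plsda$yMeans),
             classes = l$plsda$classes,
             scaler = .list2scaler(l$plsda$scaler))
  new("ExpertSystem", fpParams = params,
      refS1 = .list2ref(l$refS1, params), refS2 = .list2ref(l$refS2, params),
      gateRule = l$gateRule, n3 = n3, plsda = pls,
      descriptors = l$descriptors,
      adSettings = as.list(l$adSettings), adSimCutoff = l$adSimCutoff)
}
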