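#' @rdname FingerprintMatrix-class
#' @param object,x an object.
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname FingerprintMatrix-class
#' @export
setGeneric("fpParams", function(x) standardGeneric("fpParams"))

#' @rdname DescriptorTable-class
#' @export
setGeneric("descValues", function(x) standardGeneric("descValues"))

#' @rdname DescriptorTable-class
#' @export
setGeneric("descNames", function(x) standardGeneric("descNames"))

#' @rdname DescriptorTable-class
#' @export
setGeneric("descBlocks", function(x) standardGeneric("descBlocks"))

#' @rdname ClusterReference-class
#' @export
setGeneric("refMembers", function(x) standardGeneric("refMembers"))

#' @rdname ClusterReference-class
#' @export
setGeneric("refThreshold", function(x) standardGeneric("refThreshold"))

#' @rdname MdsResult-class
#' @export
setGeneric("mdsCoords", function(x) standardGeneric("mdsCoords"))

#' @rdname MdsResult-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname ValidationReport-class
#' @export
setGeneric("nonErrorRate", function(x) standardGeneric("nonErrorRate"))

#' @rdname ValidationReport-class
#' @export
setGeneric("sensitivitySweet", function(x) standardGeneric("sensitivitySweet"))

#' @rdname ValidationReport-class
#' @export
setGeneric("specificitySweet", function(x) standardGeneric("specificitySweet"))

#' @rdname ValidationReport-class
#' @export
setGeneric("pctNotAssigned", function(x) standardGeneric("pctNotAssigned"))

#' @rdname SelectionResult-class
#' @export
setGeneric("retainedDescriptors", function(x) standardGeneric("retainedDescriptors"))

#' @rdname SelectionResult-class
#' @export
setGeneric("fitnessTrace", function(x) standardGeneric("fitnessTrace"))

## ---- accessor methods ----

#' @rdname FingerprintMatrix-class
#' @export
setMethod("moleculeIds", "FingerprintMatrix", function(x) rownames(x@bits))

#' @rdname DescriptorTable-class
#' @export
setMethod("moleculeIds", "DescriptorTable", function(x) rownames(x@values))

#' @rdname FingerprintMatrix-class
#' @export
setMethod("fpBits", "FingerprintMatrix", function(x) x@bits)

#' @rdname FingerprintMatrix-class
#' @export
setMethod("fpParams", "FingerprintMatrix", function(x) x@params)

#' @rdname FingerprintMatrix-class
#' @export
setMethod("dim", "FingerprintMatrix", function(x) dim(x@bits))

#' @rdname FingerprintMatrix-class
#' @param i,j,...,drop subsetting arguments; rows select molecules.
#' @export
setMethod("[", "FingerprintMatrix", function(x, i, j, ..., drop = FALSE) {
  newFingerprintMatrix(x@bits[i, , drop = FALSE], x@params)
})

#' @rdname DescriptorTable-class
#' @export
setMethod("descValues", "DescriptorTable", function(x) x@values)

#' @rdname DescriptorTable-class
#' @export
setMethod("descNames", "DescriptorTable", function(x) colnames(x@values))

#' @rdname DescriptorTable-class
#' @export
setMethod("descBlocks", "DescriptorTable", function(x) x@blockOf)

#' @rdname DescriptorTable-class
#' @export
setMethod("dim", "DescriptorTable", function(x) dim(x@values))

#' @rdname DescriptorTable-class
#' @param i,j,...,drop subsetting arguments (molecules x descriptors).
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values[i, j, drop = FALSE]
  b <- x@blockOf[names(x@blockOf) %in% colnames(v)]
  new("DescriptorTable", values = v, blockOf = b)
})

#' @rdname ClusterReference-class
#' @export
setMethod("refMembers", "ClusterReference", function(x) x@members)

#' @rdname ClusterReference-class
#' @export
setMethod("refThreshold", "ClusterReference", function(x) x@threshold)

#' @rdname MdsResult-class
#' @export
setMethod("mdsCoords", "MdsResult", function(x) x@coords)

#' @rdname MdsResult-class
#' @export
setMethod("explainedVariance", "MdsResult", function(x) x@explainedVariance)

#' @rdname ValidationReport-class
#' @export
setMethod("nonErrorRate", "ValidationReport", function(x) x@ner)

#' @rdname ValidationReport-class
#' @export
setMethod("sensitivitySweet", "ValidationReport", function(x) x@snSweet)

#' @rdname ValidationReport-class
#' @export
setMethod("specificitySweet", "ValidationReport", function(x) x@spSweet)

#' @rdname ValidationReport-class
#' @export
setMethod("pctNotAssigned", "ValidationReport", function(x) x@pctNotAssigned)

#' @rdname SelectionResult-class
#' @export
setMethod("retainedDescriptors", "SelectionResult", function(x) x@retained)

#' @rdname SelectionResult-class
#' @export
setMethod("fitnessTrace", "SelectionResult", function(x) x@trace)

## ---- show methods ----

setMethod("show", "FingerprintMatrix", function(object) {
  d <- dim(object@bits)
  cat(sprintf("FingerprintMatrix: %d molecules x %d bits (density %.3f)\n",
              d[1], d[2], if (prod(d)) mean(object@bits) else NA_real_))
})

setMethod("show", "DescriptorTable", function(object) {
  d <- dim(object@values)
  nb <- length(unique(object@blockOf))
  cat(sprintf("DescriptorTable: %d molecules x %d descriptors%s\n", d[1], d[2],
              if (nb) sprintf(" in %d blocks", nb) else ""))
})

setMethod("show", "ClusterReference", function(object) {
  cat(sprintf("ClusterReference '%s': %d members, distance threshold %.3g\n",
              object@name, nrow(object@members@bits), object@threshold))
})

setMethod("show", "MdsResult", function(object) {
  cat(sprintf("MdsResult: %d points in %d dimensions; explained variance %s\n",
              nrow(object@coords), ncol(object@coords),
              paste(sprintf("%.1f%%", 100 * object@explainedVariance),
                    collapse = ", ")))
})

setMethod("show", "PLSDAModel", function(object) {
  cat(sprintf("PLSDAModel: %d latent variable(s), %d descriptors, classes %s\n",
              object@nLv, nrow(object@coef),
              paste(object@classes, collapse = " / ")))
})

setMethod("show", "N3Model", function(object) {
  cat(sprintf("N3Model: %d training molecules, %d descriptors, alpha = %.2g\n",
              nrow(object@X), ncol(object@X), object@alpha))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport [%s]: NER %.3f, Sn(sweet) %.3f, Sp(sweet) %.3f, not assigned %.1f%%\n",
              object@context, object@ner, object@snSweet, object@spSweet,
              object@pctNotAssigned))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d descriptors retained, CV NER %.3f (Sn %.3f, Sp %.3f)\n",
              length(object@retained), object@ner, object@snSweet, object@spSweet))
})

setMethod("show", "ExpertSystem", function(object) {
  gates <- c(if (!is.null(object@refS1))
               sprintf("S1 (n=%d, d*=%.2f)", nrow(object@refS1@members@bits),
                       object@refS1@threshold),
             if (!is.null(object@refS2))
               sprintf("S2 (n=%d, d*=%.2f)", nrow(object@refS2@members@bits),
                       object@refS2@threshold))
  cat("Similarity-gated sweetness expert system\n")
  cat(sprintf("  gate: %s, rule '%s'\n",
              if (length(gates)) paste(gates, collapse = " + ") else "disabled",
              object@gateRule))
  cat(sprintf("  consensus: N3 (alpha %.2g) + PLSDA (%d LV) on %d descriptors, %d training molecules\n",
              object@n3@alpha, object@plsda@nLv, length(object@descriptors),
              nrow(object@n3@X)))
})
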