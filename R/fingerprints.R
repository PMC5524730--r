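## Circular (Morgan-style) fingerprints.
##
## Features are circular atom neighbourhoods of radius 0..maxOrder, encoded
## as canonical strings built from iterated atom invariants on the heavy-atom
## connection table, then hashed onto a fixed-width bit vector with
## bitsPerPattern independent hash positions per feature. The feature strings
## themselves are exposed (circularFeatures) so hashing-free properties can
## be checked. Disconnected structures (salts) contribute the union of their
## fragments' features.

#' Fingerprint parameters
#'
#' @param nBits hash width (bits per molecule), default 2048.
#' @param bitsPerPattern independent hash positions set per feature, default 2.
#' @param maxOrder circular neighbourhood radius, default 2.
#' @return validated parameter list.
#' @export
fingerprintParams <- function(nBits = 2048L, bitsPerPattern = 2L, maxOrder = 2L) {
  nBits <- as.integer(nBits); bitsPerPattern <- as.integer(bitsPerPattern)
  maxOrder <- as.integer(maxOrder)
  stopifnot(nBits > 0L, bitsPerPattern >= 1L, maxOrder >= 0L)
  list(nBits = nBits, bitsPerPattern = bitsPerPattern, maxOrder = maxOrder)
}

## V2000 old-style charge codes
.CHARGE_CODE <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)

## Heavy-atom connection table from a (canonical) SMILES: OpenBabel emits a
## V2000 molfile whose fixed-width atom/bond blocks are read directly (the
## higher-level SDF container classes drop dimensions on single-atom
## fragments, so the text block is the robust interface).
.connectionTable <- function(smiles) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", smiles)),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  cnt <- grep(" V2000\\s*$", lines)[1L]
  if (is.na(cnt)) stop("could not build a structure for: ", smiles)
  nA <- as.integer(substr(lines[cnt], 1L, 3L))
  nB <- as.integer(substr(lines[cnt], 4L, 6L))
  if (is.na(nA) || nA < 1L) stop("molecule has no atoms: ", smiles)
  atomLines <- lines[cnt + seq_len(nA)]
  sym <- trimws(substr(atomLines, 32L, 34L))
  code <- as.character(as.integer(substr(atomLines, 37L, 39L)))
  charge <- unname(.CHARGE_CODE[ifelse(code %in% names(.CHARGE_CODE),
                                       code, "0")])
  for (chg in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(chg, 7L, nchar(chg))),
                             "\\s+")[[1L]])
    for (k in seq_len(f[1L]))
      charge[f[2L * k]] <- f[2L * k + 1L]
  }
  bonds <- matrix(integer(0), 0L, 3L)
  if (nB > 0L) {
    bondLines <- lines[cnt + nA + seq_len(nB)]
    bonds <- cbind(as.integer(substr(bondLines, 1L, 3L)),
                   as.integer(substr(bondLines, 4L, 6L)),
                   as.integer(substr(bondLines, 7L, 9L)))
  }
  list(symbol = sym, charge = charge, bonds = bonds)
}

#' Circular substructure features of a molecule
#'
#' Enumerates the circular atom neighbourhoods of radius 0 to
#' \code{maxOrder} as canonical identifier strings (unhashed). The radius-0
#' identifier of an atom encodes its element, heavy-atom degree, bond-order
#' sum and formal charge; the radius-r identifier folds in the sorted
#' radius-(r-1) identifiers of the bonded neighbours together with the bond
#' orders. The returned set is the union over all atoms and radii, so the
#' feature set at a smaller radius is always a subset of the set at a larger
#' radius.
#'
#' @param smiles a single SMILES string.
#' @param maxOrder neighbourhood radius.
#' @return character vector: the molecule's feature set.
#' @export
circularFeatures <- function(smiles, maxOrder = 2L) {
  ct <- .connectionTable(smiles)
  nA <- length(ct$symbol)
  if (nA == 0L) stop("molecule has no heavy atoms: ", smiles)
  nbr <- vector("list", nA)  # list of (neighbour index, bond order)
  deg <- integer(nA); bos <- integer(nA)
  if (nrow(ct$bonds)) {
    for (k in seq_len(nrow(ct$bonds))) {
      a <- ct$bonds[k, 1L]; b <- ct$bonds[k, 2L]; o <- ct$bonds[k, 3L]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o)); nbr[[b]] <- rbind(nbr[[b]], c(a, o))
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bos[a] <- bos[a] + o; bos[b] <- bos[b] + o
    }
  }
  id <- sprintf("(%s;d%d;b%d;c%+d)", ct$symbol, deg, bos, ct$charge)
  feats <- unique(id)
  if (maxOrder >= 1L) {
    for (r in seq_len(maxOrder)) {
      id <- vapply(seq_len(nA), function(a) {
        env <- if (is.null(nbr[[a]])) character(0)
               else sort(sprintf("%d~%s", nbr[[a]][, 2L], id[nbr[[a]][, 1L]]))
        sprintf("r%d{%s|%s}", r, id[a], paste(env, collapse = ","))
      }, character(1))
      feats <- unique(c(feats, id))
    }
  }
  feats
}

## deterministic polynomial string hash mod 2^31 - 1; exact in doubles
.hashString <- function(s, mult) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * mult + b) %% 2147483647
  h
}

.HASH_MULT <- c(31, 131, 257, 523, 1031, 2053)

#' Compute hashed circular fingerprints
#'
#' Canonicalizes each SMILES, enumerates its circular features (see
#' [circularFeatures()]) and hashes every feature onto
#' \code{params$bitsPerPattern} positions of an \code{params$nBits}-wide
#' binary vector. The result is a pure function of the canonical SMILES and
#' the parameters: equivalent SMILES dialects give identical rows.
#'
#' @param x named character vector of SMILES, or a records data.frame with
#'   columns id and smiles (e.g. from [parseMoleculeTable()]).
#' @param params see [fingerprintParams()].
#' @return a \linkS4class{FingerprintMatrix}; molecules whose structure could
#'   not be processed are omitted and reported in the "errors" attribute
#'   (named character vector of messages).
#' @export
computeFingerprints <- function(x, params = fingerprintParams()) {
  if (is.data.frame(x)) x <- stats::setNames(x$smiles, x$id)
  if (is.null(names(x))) names(x) <- sprintf("mol%0*d", nchar(length(x)), seq_along(x))
  if (params$bitsPerPattern > length(.HASH_MULT))
    stop("bitsPerPattern supports at most ", length(.HASH_MULT), " hash positions")
  can <- canonicalizeSmiles(x)
  bits <- matrix(0L, length(x), params$nBits,
                 dimnames = list(names(x), NULL))
  errors <- character(0)
  ok <- rep(TRUE, length(x))
  for (i in seq_along(x)) {
    row <- tryCatch({
      if (is.na(can[i])) stop("unparseable SMILES")
      feats <- circularFeatures(can[i], params$maxOrder)
      pos <- unlist(lapply(feats, function(f)
        vapply(.HASH_MULT[seq_len(params$bitsPerPattern)],
               function(m) .hashString(f, m) %% params$nBits + 1, numeric(1))))
      v <- integer(params$nBits); v[unique(as.integer(pos))] <- 1L
      v
    }, error = function(e) e)
    if (inherits(row, "error")) {
      errors[names(x)[i]] <- conditionMessage(row)
      ok[i] <- FALSE
    } else bits[i, ] <- row
  }
  res <- FingerprintMatrix(bits[ok, , drop = FALSE], params)
  attr(res, "errors") <- errors
  res
}
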