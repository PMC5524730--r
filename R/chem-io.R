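## Molecule table ingestion and curation.
##
## Molecule tables are CSV/TSV with id / SMILES / taste-label columns. SMILES
## are canonicalized through OpenBabel (ChemmineOB) on ingest so that
## duplicate detection and fingerprinting operate on a single dialect.

.TASTE_LEVELS <- c("sweet", "tasteless", "bitter")
.CLASS_LEVELS <- c("sweet", "non-sweet")

#' Construct a FingerprintMatrix
#'
#' @param bits 0/1 matrix with molecule ids as rownames.
#' @param params fingerprint parameter list, see [fingerprintParams()].
#' @return a \linkS4class{FingerprintMatrix}.
#' @export
FingerprintMatrix <- function(bits, params = fingerprintParams(nBits = ncol(bits))) {
  storage.mode(bits) <- "integer"
  new("FingerprintMatrix", bits = bits, params = params)
}

newFingerprintMatrix <- function(bits, params) FingerprintMatrix(bits, params)

#' Construct a DescriptorTable
#'
#' @param values numeric matrix, molecule ids as rownames, descriptor names
#'   as colnames.
#' @param blockOf optional named character vector mapping descriptor names to
#'   block labels.
#' @return a \linkS4class{DescriptorTable}.
#' @export
DescriptorTable <- function(values, blockOf = character(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("DescriptorTable", values = values, blockOf = blockOf)
}

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the OpenBabel canonical dialect. Strings OpenBabel
#' cannot parse yield \code{NA}.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, \code{NA} where parsing
#'   failed.
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", trimws(s))),
      error = function(e) "")
    can <- sub("[ \t].*$", "", sub("\n$", "", out))
    if (!nzchar(can)) NA_character_ else can
  }, character(1), USE.NAMES = FALSE)
}

#' Read and canonicalize a molecule table
#'
#' Reads a CSV/TSV table with one molecule per row, canonicalizes the SMILES
#' and maps the raw taste label to the binary sweet / non-sweet class.
#' Unparseable rows are reported in the \code{rejects} element, never dropped
#' silently.
#'
#' @param path path to the table.
#' @param format "csv" or "tsv".
#' @param idCol,smilesCol,labelCol column names (case-insensitive);
#'   \code{labelCol = NULL} reads an unlabelled table (for prediction).
#' @return list with \code{records} (data.frame: id, smiles, rawLabel,
#'   classLabel) and \code{rejects} (data.frame: id, smiles, reason).
#' @export
parseMoleculeTable <- function(path, format = c("csv", "tsv"),
                               idCol = "id", smilesCol = "smiles",
                               labelCol = "label") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("molecule table not found: ", path)
  tab <- if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
         else utils::read.delim(path, stringsAsFactors = FALSE)
  lc <- tolower(names(tab))
  pick <- function(col) {
    i <- match(tolower(col), lc)
    if (is.na(i))
      stop("configuration error: required column '", col, "' missing from ", path)
    tab[[i]]
  }
  ids <- as.character(pick(idCol))
  smi <- as.character(pick(smilesCol))
  lab <- if (is.null(labelCol)) rep(NA_character_, length(ids))
         else tolower(trimws(as.character(pick(labelCol))))
  can <- canonicalizeSmiles(smi)
  badLabel <- if (is.null(labelCol)) rep(FALSE, length(ids))
              else !lab %in% .TASTE_LEVELS
  badSmiles <- is.na(can)
  ok <- !badLabel & !badSmiles
  rejects <- data.frame(
    id = ids[!ok], smiles = smi[!ok],
    reason = ifelse(badSmiles[!ok], "unparseable SMILES", "unknown taste label"),
    stringsAsFactors = FALSE)
  if (!any(ok)) stop("input error: no valid molecule rows in ", path)
  records <- data.frame(
    id = ids[ok], smiles = can[ok],
    rawLabel = factor(lab[ok], levels = .TASTE_LEVELS),
    stringsAsFactors = FALSE)
  records$classLabel <- factor(
    ifelse(records$rawLabel == "sweet", "sweet", "non-sweet"),
    levels = .CLASS_LEVELS)
  if (is.null(labelCol)) records$rawLabel <- records$classLabel <- NULL
  list(records = records, rejects = rejects)
}

#' Curate a molecule record set
#'
#' Applies the dataset curation rules: tasteless and bitter labels collapse
#' into the non-sweet class; records that share a canonical SMILES and class
#' are merged into one (the first is retained); canonical-SMILES groups that
#' contain both a sweet and a non-sweet member are ambiguous and removed
#' entirely. Every action is written to the curation log, and the operation
#' is idempotent.
#'
#' @param records data.frame with columns id, smiles (canonical), rawLabel;
#'   e.g. the \code{records} element of [parseMoleculeTable()].
#' @return list with \code{records} (curated data.frame) and \code{log}
#'   (data.frame of actions: action, id, smiles, detail).
#' @export
curateDataset <- function(records) {
  stopifnot(all(c("id", "smiles", "rawLabel") %in% names(records)))
  rec <- records
  rec$rawLabel <- factor(as.character(rec$rawLabel), levels = .TASTE_LEVELS)
  rec$classLabel <- factor(
    ifelse(rec$rawLabel == "sweet", "sweet", "non-sweet"),
    levels = .CLASS_LEVELS)
  log <- list()
  note <- function(action, id, smiles, detail)
    log[[length(log) + 1L]] <<- data.frame(
      action = action, id = id, smiles = smiles, detail = detail,
      stringsAsFactors = FALSE)

  keep <- rep(TRUE, nrow(rec))
  for (s in unique(rec$smiles)) {
    g <- which(rec$smiles == s)
    if (length(g) < 2L && length(unique(rec$classLabel[g])) == 1L) next
    cls <- unique(as.character(rec$classLabel[g]))
    if (length(cls) > 1L) {
      keep[g] <- FALSE
      note("remove_ambiguous", paste(rec$id[g], collapse = ";"), s,
           "same structure annotated with conflicting taste classes")
    } else if (length(g) > 1L) {
      keep[g[-1L]] <- FALSE
      note("merge_duplicates", paste(rec$id[g], collapse = ";"), s,
           sprintf("retained '%s'", rec$id[g[1L]]))
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  logDf <- if (length(log)) do.call(rbind, log) else
    data.frame(action = character(0), id = character(0),
               smiles = character(0), detail = character(0))
  list(records = out, log = logDf)
}

#' Write a curated set to disk
#'
#' @param curated result of [curateDataset()].
#' @param csvPath destination for the record CSV.
#' @param logPath destination for the JSON curation log.
#' @return invisibly, the paths written.
#' @export
writeCuratedSet <- function(curated, csvPath, logPath = sub("\\.csv$", "_log.json", csvPath)) {
  utils::write.csv(curated$records, csvPath, row.names = FALSE)
  jsonlite::write_json(curated$log, logPath, dataframe = "rows")
  invisible(c(csvPath, logPath))
}

#' Clean a descriptor matrix
#'
#' Drops descriptors affected by missing values and descriptors with
#' constant or near-constant values (most frequent value occupying more than
#' \code{nearConstantProp} of the rows).
#'
#' @param values numeric matrix or \linkS4class{DescriptorTable}.
#' @param nearConstantProp near-constant cutoff; a column is dropped when one
#'   value occupies more than this proportion of rows. Default 0.95.
#' @param blockOf optional block map carried into the result.
#' @return a cleaned \linkS4class{DescriptorTable}.
#' @export
cleanDescriptors <- function(values, nearConstantProp = 0.95,
                             blockOf = character(0)) {
  if (is(values, "DescriptorTable")) {
    blockOf <- values@blockOf
    values <- values@values
  }
  values <- as.matrix(values)
  hasNA <- apply(values, 2L, anyNA)
  modal <- apply(values, 2L, function(col) max(table(col)) / length(col))
  drop <- hasNA | modal > nearConstantProp
  if (all(drop)) stop("all descriptors removed by cleaning")
  kept <- values[, !drop, drop = FALSE]
  DescriptorTable(kept, blockOf[names(blockOf) %in% colnames(kept)])
}

#' Read a descriptor table from CSV
#'
#' First column molecule id, remaining columns named numeric descriptors.
#'
#' @param path CSV path.
#' @param blockMap optional path to a two-column CSV (descriptor, block).
#' @param clean apply [cleanDescriptors()] (default TRUE).
#' @param nearConstantProp passed to [cleanDescriptors()].
#' @return a \linkS4class{DescriptorTable}.
#' @export
readDescriptorTable <- function(path, blockMap = NULL, clean = TRUE,
                                nearConstantProp = 0.95) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("descriptor table needs an id column plus descriptors")
  ids <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  blocks <- character(0)
  if (!is.null(blockMap)) {
    bm <- utils::read.csv(blockMap, stringsAsFactors = FALSE)
    blocks <- stats::setNames(as.character(bm[[2L]]), as.character(bm[[1L]]))
  }
  if (clean) cleanDescriptors(vals, nearConstantProp, blocks)
  else DescriptorTable(vals, blocks[names(blocks) %in% colnames(vals)])
}
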