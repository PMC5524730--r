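# Molecule table ingestion, curation rules and descriptor cleaning.

writeMoleculeCsv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c("id,smiles,label", rows), path)
  path
}

test_that("parsing canonicalizes SMILES and reports unparseable rows", {
  path <- writeMoleculeCsv(c(
    "m1,OC(=O)C,sweet",         # acetic acid written backwards
    "m2,CCO,tasteless",
    "m3,c1ccccc1,bitter",
    "m4,C1CC,sweet"))           # unclosed ring
  res <- parseMoleculeTable(path)
  expect_equal(nrow(res$records), 3L)
  expect_equal(nrow(res$rejects), 1L)
  expect_equal(res$rejects$id, "m4")
  expect_match(res$rejects$reason, "SMILES")
  expect_equal(res$records$smiles[res$records$id == "m1"], "CC(=O)O")
  expect_equal(as.character(res$records$classLabel),
               c("sweet", "non-sweet", "non-sweet"))
})

test_that("missing columns and empty tables are input errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,structure,label", "m1,CCO,sweet"), path)
  expect_error(parseMoleculeTable(path), "configuration error")
  bad <- writeMoleculeCsv("m1,C1CC,sweet")
  expect_error(parseMoleculeTable(bad), "no valid molecule rows")
})

test_that("curation merges duplicates, drops ambiguous groups and maps classes", {
  rec <- data.frame(
    id = c("a1", "a2", "b1", "b2", "c1"),
    smiles = c("S_A", "S_A", "S_B", "S_B", "S_C"),
    rawLabel = c("sweet", "sweet", "sweet", "bitter", "tasteless"),
    stringsAsFactors = FALSE)
  cur <- curateDataset(rec)
  expect_equal(cur$records$id, c("a1", "c1"))
  expect_equal(as.character(cur$records$classLabel), c("sweet", "non-sweet"))
  expect_setequal(cur$log$action, c("merge_duplicates", "remove_ambiguous"))

  # tasteless + bitter merge into one non-sweet class at the printed counts
  many <- data.frame(
    id = sprintf("t%03d", 1:214),
    smiles = sprintf("S%03d", 1:214),
    rawLabel = rep(c("tasteless", "bitter"), c(133, 81)),
    stringsAsFactors = FALSE)
  curMany <- curateDataset(many)
  expect_equal(sum(curMany$records$classLabel == "non-sweet"), 214L)
})

test_that("curation is idempotent", {
  rec <- data.frame(
    id = sprintf("m%d", 1:6),
    smiles = c("A", "A", "B", "C", "C", "D"),
    rawLabel = c("sweet", "sweet", "bitter", "sweet", "bitter", "tasteless"),
    stringsAsFactors = FALSE)
  once <- curateDataset(rec)
  twice <- curateDataset(once$records)
  expect_equal(twice$records, once$records)
  expect_equal(nrow(twice$log), 0L)
})

test_that("descriptor cleaning removes NA and near-constant columns", {
  set.seed(3)
  X <- cbind(ok = rnorm(40), hasNA = c(NA, rnorm(39)),
             constant = rep(1, 40),
             nearConst = c(rep(0, 39), 1),   # modal value on 97.5% of rows
             ok2 = runif(40))
  rownames(X) <- sprintf("m%02d", 1:40)
  dt <- cleanDescriptors(X)
  expect_setequal(descNames(dt), c("ok", "ok2"))
  # the near-constant cutoff is configurable
  dt2 <- cleanDescriptors(X, nearConstantProp = 0.99)
  expect_true("nearConst" %in% descNames(dt2))
})

test_that("descriptor tables round-trip through CSV with a block map", {
  dir <- withr::local_tempdir()
  X <- matrix(rnorm(20), 5, 4,
              dimnames = list(sprintf("m%d", 1:5), c("A", "B", "C", "D")))
  csv <- file.path(dir, "desc.csv")
  write.csv(data.frame(id = rownames(X), X, check.names = FALSE), csv,
            row.names = FALSE)
  bm <- file.path(dir, "blocks.csv")
  write.csv(data.frame(descriptor = c("A", "B", "C", "D"),
                       block = c("b1", "b1", "b2", "b2")), bm,
            row.names = FALSE)
  dt <- readDescriptorTable(csv, blockMap = bm)
  expect_equal(descValues(dt), X)
  expect_equal(unname(descBlocks(dt)[c("A", "D")]), c("b1", "b2"))
})
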