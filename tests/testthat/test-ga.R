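# GA-VSS descriptor selection.

test_that("reported fitness equals an independent CV run of the subset", {
  d <- shiftedDescriptors(n = 40, p = 6, effect = 1.5, seed = 61)
  cfg <- gaConfig(populationSize = 8, nGenerations = 4, maxSize = 6, seed = 3)
  res <- gaVss(d$X, d$y, plsdaSpec(1L), cfg)
  direct <- classMetrics(
    d$y,
    venetianBlindCv(d$X[, retainedDescriptors(res), drop = FALSE], d$y,
                    plsdaSpec(1L), G = 5L),
    context = "cv")
  expect_equal(res@ner, nonErrorRate(direct))
  expect_equal(res@snSweet, sensitivitySweet(direct))
})

test_that("without crossover or mutation the elitist search is static", {
  d <- shiftedDescriptors(n = 30, p = 5, seed = 62)
  cfg <- gaConfig(populationSize = 6, nGenerations = 6, pCrossover = 0,
                  pMutation = 0, seed = 4)
  res <- gaVss(d$X, d$y, n3Spec(1.5), cfg)
  tr <- fitnessTrace(res)
  expect_true(all(tr == tr[1]))
})

test_that("the search is deterministic under its seed", {
  d <- shiftedDescriptors(n = 30, p = 8, seed = 63)
  cfg <- gaConfig(populationSize = 6, nGenerations = 5, seed = 11)
  r1 <- gaVss(d$X, d$y, plsdaSpec(1L), cfg)
  r2 <- gaVss(d$X, d$y, plsdaSpec(1L), cfg)
  expect_identical(retainedDescriptors(r1), retainedDescriptors(r2))
  expect_identical(fitnessTrace(r1), fitnessTrace(r2))
})

test_that("informative descriptors are recovered from a small pool", {
  cfg <- syntheticConfig(nS1 = 0, nS2 = 0, nC3Sweet = 75, nC3NonSweet = 75,
                         nInformative = 4, nNuisance = 16)
  ds <- generateSyntheticDataset(cfg, seed = 64)
  res <- gaVss(ds$descriptors, ds$labels, plsdaSpec(1L),
               gaConfig(populationSize = 20, nGenerations = 12, maxSize = 8,
                        seed = 7))
  truth <- ds$metadata$informative
  sel <- retainedDescriptors(res)
  overlap <- length(intersect(sel, truth)) / length(union(sel, truth))
  expect_gte(overlap, 0.5)
  expect_true(all(diff(fitnessTrace(res)) >= 0))
})

test_that("block-wise selection degenerates to a plain run on one block", {
  d <- shiftedDescriptors(n = 30, p = 6, seed = 65)
  blockOf <- setNames(rep("B1", 6), colnames(d$X))
  dt <- DescriptorTable(d$X, blockOf)
  cfg <- gaConfig(populationSize = 6, nGenerations = 4, seed = 9)
  one <- blockwiseSelection(dt, d$y, plsdaSpec(1L), cfg)
  plain <- gaVss(d$X, d$y, plsdaSpec(1L), cfg)
  expect_equal(retainedDescriptors(one), retainedDescriptors(plain))
})

test_that("two-stage selection finds the informative block", {
  cfg <- syntheticConfig(nS1 = 0, nS2 = 0, nC3Sweet = 60, nC3NonSweet = 60,
                         nInformative = 4, nNuisance = 20,
                         nuisanceBlockSize = 10)
  ds <- generateSyntheticDataset(cfg, seed = 66)
  res <- blockwiseSelection(ds$descriptors, ds$labels, plsdaSpec(1L),
                            gaConfig(populationSize = 14, nGenerations = 8,
                                     maxSize = 8, seed = 5))
  truth <- ds$metadata$informative
  sel <- retainedDescriptors(res)
  overlap <- length(intersect(sel, truth)) / length(union(sel, truth))
  expect_gte(overlap, 0.5)
  expect_named(res@perBlock)
})
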