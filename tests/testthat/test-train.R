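test_that("a zero learning rate leaves parameters unchanged", {
  ds <- smallTrainedFixture()
  mcfg <- modelConfig(dModel = 16L, nLayers = 1L, nHeads = 2L, seed = 51)
  fit <- trainModel(ds, mcfg, trainConfig(epochs = 1L, lr = 0, seed = 51))
  init <- riboModel(mcfg)
  expect_identical(fit$model@params, init@params)
})

test_that("training is reproducible and improves the validation score", {
  ds <- smallTrainedFixture()
  mcfg <- modelConfig(dModel = 16L, nLayers = 1L, nHeads = 2L, seed = 52)
  tcfg <- trainConfig(epochs = 2L, lr = 2e-3, seed = 52)
  f1 <- trainModel(ds, mcfg, tcfg)
  f2 <- trainModel(ds, mcfg, tcfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model@params, f2$model@params)
  # learning happened: beats the untrained model on validation
  init <- riboModel(mcfg)
  expect_gt(macroDcPcc(f1$model, subsetSplit(ds, "val")),
            macroDcPcc(init, subsetSplit(ds, "val")))
  expect_named(f1$history, c("epoch", "trainLoss", "valDcPcc"))
})

test_that("ensemble prediction is the member mean and preserves the head sum", {
  set.seed(53)
  cs <- randomCodons(10)
  s <- riboSample(codonSequence("g", cs), "VAL", yCtrl = runif(10),
                  yDc = runif(10))
  ms <- lapply(61:63, function(sd) tinyModel(seed = sd))
  # single member: identity
  e1 <- ensemblePredict(ms[1], s)
  expect_equal(e1, predictProfiles(ms[[1]], s))
  # member mean, head by head (independent oracle)
  e3 <- ensemblePredict(ms, s)
  prs <- lapply(ms, predictProfiles, x = s)
  expect_equal(e3$yCtrl, Reduce(`+`, lapply(prs, `[[`, "yCtrl")) / 3)
  expect_equal(e3$yDelta, Reduce(`+`, lapply(prs, `[[`, "yDelta")) / 3)
  expect_equal(e3$yDc, e3$yCtrl + e3$yDelta)
  # averaging across independently initialized members damps variation:
  # the ensemble profile varies less over positions than any member
  set.seed(530)
  cs40 <- randomCodons(40)
  ms5 <- lapply(1:5, function(sd)
    riboModel(modelConfig(dModel = 16L, nLayers = 1L, nHeads = 2L,
                          seed = sd)))
  outs <- sapply(ms5, function(m) predictProfiles(m, cs40, "VAL")$yDc)
  expect_lte(var(rowMeans(outs)), min(apply(outs, 2, var)))
  # mismatched architectures are refused
  mBad <- tinyModel(dModel = 8L, nHeads = 2L, seed = 1)
  expect_error(ensemblePredict(list(ms[[1]], mBad), s), "mismatched")
})

test_that("imputation changes exactly the missing positions and nothing else", {
  set.seed(54)
  ds <- smallTrainedFixture()
  models <- lapply(71:72, function(sd)
    tinyModel(dModel = 16L, nLayers = 1L, seed = sd))
  train <- subsetSplit(ds, "train")
  before <- samples(train)
  res <- imputeMissing(train, models)
  after <- samples(res$dataset)
  totMiss <- 0L
  for (i in seq_along(before)) {
    miss <- which(is.na(yDc(before[[i]])))
    totMiss <- totMiss + length(miss)
    ann <- which(!is.na(yDc(before[[i]])))
    # annotated positions bit-identical
    expect_identical(yDc(after[[i]])[ann], yDc(before[[i]])[ann])
    # imputed values equal the independent member-mean computation
    if (length(miss)) {
      em <- ensemblePredict(models, before[[i]])
      expect_equal(yDc(after[[i]])[miss], em$yDc[miss])
      expect_false(anyNA(yDc(after[[i]])))
    }
    # difference targets rederived; missing control keeps missing delta
    if (condition(before[[i]]) != "CTRL") {
      ctrlNA <- is.na(yCtrl(before[[i]]))
      expect_true(all(is.na(yDelta(after[[i]])[ctrlNA])))
    }
  }
  expect_equal(res$nImputed, totMiss)
  expect_gt(totMiss, 0L)

  # fully annotated sample passes through unchanged
  full <- makeSample(n = 10L, split = "train")
  resF <- imputeSample(full, models)
  expect_identical(resF$sample, full)
  expect_equal(resF$nImputed, 0L)

  # guard: refusing to touch evaluation splits
  sv <- makeSample(n = 10L, split = "val")
  sv@yDc[2] <- NA
  expect_error(imputeSample(sv, models), "refusing")
})

test_that("the pseudo-label pipeline is deterministic end to end", {
  set.seed(55)
  cfg <- simulationConfig(nGenes = 10L, lenRange = c(60L, 90L),
                          missingRate = 0.3, seed = 56L)
  run <- function() {
    ds <- preprocessPipeline(simulateDataset(cfg))$dataset
    mcfg <- modelConfig(dModel = 16L, nLayers = 1L, nHeads = 2L, seed = 1)
    tcfg <- trainConfig(epochs = 1L, lr = 1e-3, seed = 1,
                        ensembleSeeds = 11:12)
    ens <- trainEnsemble(ds, mcfg, tcfg)
    imp <- imputeMissing(ds, ens)
    stud <- retrainPseudolabeled(imp$dataset, modelConfig(dModel = 16L,
                                                          nLayers = 1L,
                                                          nHeads = 2L,
                                                          seed = 2),
                                 trainConfig(epochs = 1L, lr = 1e-3, seed = 2))
    list(imp = vapply(samples(imp$dataset), function(s) sum(yDc(s)),
                      numeric(1)),
         w = stud$model@params$wCtrl)
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1, r2)
})

test_that("imputing a dataset with no missing values reduces to a no-op", {
  set.seed(57)
  cfg <- simulationConfig(nGenes = 6L, lenRange = c(60L, 80L),
                          missingRate = 0, seed = 58L)
  ds <- preprocessPipeline(simulateDataset(cfg))$dataset
  models <- list(tinyModel(seed = 5))
  res <- imputeMissing(ds, models)
  expect_equal(res$nImputed, 0L)
  expect_identical(lapply(samples(res$dataset), yDc),
                   lapply(samples(ds), yDc))
})
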