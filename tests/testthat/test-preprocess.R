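test_that("replicate merging scales, averages, and unions annotations", {
  # single replicate: merged equals its mean-scaled self
  p <- c(2, 4, NA)
  expect_equal(mergeReplicates(list(p)), p / 3)
  # complementary annotations: union after merge
  m <- mergeReplicates(list(c(2, NA), c(NA, 4)))
  expect_equal(m, c(1, 1))  # each replicate scaled by its own mean
  # identical replicates: idempotent after scaling
  p2 <- c(1, 3, 0, 4)
  expect_equal(mergeReplicates(list(p2, p2)), p2 / mean(p2))
  # all-missing replicate dropped with a warning
  expect_warning(m2 <- mergeReplicates(list(p2, rep(NA_real_, 4))), "dropping")
  expect_equal(m2, p2 / mean(p2))
  # missing only where all replicates are missing
  m3 <- mergeReplicates(list(c(1, NA, NA), c(2, NA, 6)))
  expect_equal(is.na(m3), c(FALSE, TRUE, FALSE))
})

test_that("normalization divides by the annotated mean and log-transforms", {
  expect_equal(normalizeProfile(c(5, 5, 5)), rep(log(2), 3))
  expect_equal(normalizeProfile(c(0, 2)), c(log(1), log(3)))
  expect_equal(normalizeProfile(c(NA, 4)), c(NA, log(2)))
  expect_error(normalizeProfile(c(NA_real_, NA_real_)), "all-missing")
  # scale invariance: any k > 0 leaves the output unchanged
  set.seed(21)
  p <- runif(50, 0, 10); p[sample(50, 5)] <- NA
  for (k in c(0.01, 3, 1e4))
    expect_equal(normalizeProfile(k * p), normalizeProfile(p))
})

test_that("coverage is the non-zero fraction of annotated positions", {
  expect_equal(computeCoverage(c(1, 0, NA, 2)), 2 / 3)
  expect_equal(computeCoverage(c(1, 2, 3)), 1)
  expect_equal(computeCoverage(c(0, 0)), 0)
  expect_error(computeCoverage(rep(NA_real_, 3)), "no annotated")
})

test_that("the three quality filters reject exactly the planted violations", {
  cfg <- preprocessConfig()
  mk <- function(y) riboSample(makeSeq("g", length(y)), "VAL",
                               yCtrl = rep(1, length(y)), yDc = y)
  set.seed(22)
  # run of 21 observed zeros: rejected; run of 20: kept
  y <- runif(100, 1, 2)
  y[10:30] <- 0  # 21 zeros
  expect_equal(filterSample(mk(y), cfg)$reason, "zero_run")
  y[10] <- 1.5   # now 20 zeros
  expect_equal(filterSample(mk(y), cfg)$reason, "pass")
  # missing values break a zero run
  y2 <- runif(100, 1, 2)
  y2[10:30] <- 0; y2[20] <- NA
  expect_equal(filterSample(mk(y2), cfg)$reason, "pass")
  # length 2001 rejected, 2000 kept
  expect_equal(filterSample(mk(runif(2001, 1, 2)), cfg)$reason, "length")
  expect_equal(filterSample(mk(runif(2000, 1, 2)), cfg)$reason, "pass")
  # coverage exactly 0.30 rejected (strictly greater required)
  y3 <- rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 10)  # coverage 0.10
  expect_equal(filterSample(mk(y3), cfg)$reason, "coverage")
  y3b <- rep(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0), 10) # coverage 0.40
  expect_equal(filterSample(mk(y3b), cfg)$reason, "pass")
  # boundary: coverage exactly 0.30 is rejected (strictly greater required)
  y4 <- rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 10)
  expect_equal(computeCoverage(y4), 0.30)
  expect_equal(filterSample(mk(y4), cfg)$reason, "coverage")
})

test_that("filter decisions are order-independent and reported per rule", {
  # a sample violating all three rules reports the fixed first rule
  y <- c(rep(0, 30), rep(1, 10), rep(0, 1970))
  s <- riboSample(makeSeq("g", 2010L), "VAL", yCtrl = rep(1, 2010), yDc = y)
  expect_equal(filterSample(s)$reason, "zero_run")
  expect_false(filterSample(s)$keep)
})

test_that("coverage-sorted split matches an independently hand-walked rule", {
  set.seed(23)
  mkGene <- function(id, cov) {
    n <- 50L
    y <- c(runif(round(cov * n), 0.5, 2), rep(0, n - round(cov * n)))
    riboSample(makeSeq(id, n), "VAL", yCtrl = runif(n, 0.5, 2), yDc = sample(y))
  }
  covs <- round(seq(0.95, 0.40, length.out = 20), 2)
  ds <- riboDataset(lapply(1:20, function(i) mkGene(sprintf("g%02d", i), covs[i])))
  cfg <- preprocessConfig(valFrac = 0.05, testFrac = 0.20)
  res <- splitDataset(ds, cfg)

  # independent simulation of the stated rule (sort by coverage desc,
  # cycle train->val->test, skip quota-filled val/test)
  cov <- vapply(samples(ds), function(s) computeCoverage(yDc(s)), numeric(1))
  ids <- vapply(samples(ds), geneId, character(1))
  ord <- order(-cov, ids)
  want <- character(20); names(want) <- ids[ord]
  quotaV <- 0.05 * 20; quotaT <- 0.20 * 20
  nv <- 0; nt <- 0; slot <- 0
  for (g in ids[ord]) {
    repeat {
      tgt <- c("train", "val", "test")[slot %% 3 + 1]
      if (tgt == "val" && nv >= quotaV) { slot <- slot + 1; next }
      if (tgt == "test" && nt >= quotaT) { slot <- slot + 1; next }
      break
    }
    want[g] <- tgt
    if (tgt == "val") nv <- nv + 1
    if (tgt == "test") nt <- nt + 1
    slot <- slot + 1
  }
  got <- setNames(res$manifest$split, res$manifest$gene_id)
  expect_equal(got[names(want)], want)
  # realized quotas: 1 val, 4 test of 20 single-sample genes
  expect_equal(sum(got == "val"), 1L)
  expect_equal(sum(got == "test"), 4L)
})

test_that("split keeps all of a gene's samples together and fills quotas", {
  set.seed(24)
  ds <- simulateDataset(simulationConfig(nGenes = 25L, lenRange = c(60L, 90L),
                                         seed = 3L))
  pp <- preprocessPipeline(ds)
  sp <- splits(pp$dataset)
  gid <- geneId(pp$dataset)
  expect_true(all(tapply(sp, gid, function(v) length(unique(v))) == 1L))
  n <- nSamples(pp$dataset)
  # realized shares within one gene's worth (6 samples) of the quotas
  expect_lte(abs(sum(sp == "val") - 0.05 * n), 6)
  expect_lte(abs(sum(sp == "test") - 0.20 * n), 6)
  # degenerate quota: valFrac ~ 0 collapses the alternation to train/test
  res0 <- splitDataset(pp$dataset, preprocessConfig(valFrac = 1e-9,
                                                    testFrac = 0.2))
  expect_lte(sum(res0$manifest$split == "val"), 1L)
})

test_that("deprivation LRT behaves under null, alternative, and degenerate data", {
  set.seed(25)
  mkLrt <- function(delta, codonsVec) {
    seqq <- codonSequence("g", codonsVec)
    yc <- runif(length(delta), 0.5, 1.5)
    riboSample(seqq, "VAL", yCtrl = yc, yDc = yc + delta)
  }
  dep <- deprivedCodons("VAL")
  oth <- setdiff(senseCodons(), dep)
  cods <- c(sample(dep, 100, TRUE), sample(oth, 100, TRUE))

  # identical group means exactly -> statistic 0, p = 1
  s0 <- mkLrt(rep(0.5, 200), cods)
  r0 <- deprivationLrt(s0)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # strong planted shift -> overwhelming significance
  sh <- mkLrt(c(rnorm(100, 2, 1), rnorm(100, 0, 1)), cods)
  expect_lt(deprivationLrt(sh)$p.value, 1e-6)

  # null: p approximately uniform (Kolmogorov-Smirnov sanity check)
  ps <- replicate(200, {
    s <- mkLrt(rnorm(200), cods)
    deprivationLrt(s)$p.value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)

  # guards
  expect_error(deprivationLrt(makeSample(condition = "CTRL")), "CTRL")
  few <- mkLrt(rnorm(5), c(sample(dep, 2, TRUE), sample(oth, 3, TRUE)))
  expect_error(deprivationLrt(few), ">= 3")
})
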