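test_that("embedding is additive in codon and condition and position-independent", {
  m <- tinyModel()
  set.seed(31)
  cs <- randomCodons(8)
  X1 <- rsNs$embedInput(m, cs, "VAL")
  X2 <- rsNs$embedInput(m, cs, "LEU")
  # condition change shifts every position by the same vector
  d <- X2 - X1
  expect_true(all(abs(sweep(d, 2, d[1, ])) < 1e-12))
  # permuting codons permutes rows identically
  perm <- sample(8)
  expect_equal(rsNs$embedInput(m, cs[perm], "VAL"), X1[perm, ])
  # zeroed embeddings give all-zero inputs
  m0 <- m; m0@params$Ecod[] <- 0; m0@params$Econd[] <- 0
  expect_true(all(rsNs$embedInput(m0, cs, "VAL") == 0))
  expect_error(rsNs$embedInput(m, c("AT"), "VAL"), "unknown codon")
})

test_that("one-layer one-head attention equals the dense equation oracle", {
  cfgs <- list(modelConfig(dModel = 8L, nLayers = 1L, nHeads = 1L, seed = 31,
                           engine = "R"),
               modelConfig(dModel = 8L, nLayers = 1L, nHeads = 1L, seed = 31,
                           engine = "cpp"))
  for (cfg in cfgs) {
    m <- riboModel(cfg)
    set.seed(32)
    for (n in c(1L, 3L, 7L)) {
      X <- matrix(rnorm(n * 8), n, 8)
      got <- rsNs$nnForward(m, X)$out
      want <- denseOracleLayer(m@params, X, rsNs$relEncoding(n, 8L),
                               1 / sqrt(8))
      expect_equal(got, want, tolerance = 1e-5, ignore_attr = TRUE)
    }
  }
})

test_that("single-position attention is the value projection passed through the sublayers", {
  # with one token the softmax has one element: alpha_11 = 1, h_1 = x_1 Wv
  m <- riboModel(modelConfig(dModel = 8L, nLayers = 1L, nHeads = 1L,
                             seed = 33, engine = "R"))
  X <- matrix(rnorm(8), 1, 8)
  cache <- rsNs$tfForward(m@params, m@config, X)
  expect_equal(cache$layers[[1]]$A[[1]], matrix(1, 1, 1))
  expect_equal(cache$layers[[1]]$O, X %*% m@params$`L1.Wv`)
})

test_that("attention weights are row-normalized", {
  m <- riboModel(modelConfig(dModel = 16L, nLayers = 2L, nHeads = 4L,
                             seed = 34, engine = "R"))
  set.seed(34)
  X <- matrix(rnorm(12 * 16), 12, 16)
  cache <- rsNs$tfForward(m@params, m@config, X)
  for (l in 1:2)
    for (h in 1:4)
      expect_true(all(abs(rowSums(cache$layers[[l]]$A[[h]]) - 1) < 1e-6))
})

test_that("the DC prediction is exactly the sum of the two heads", {
  set.seed(35)
  for (backbone in c("transformer", "birnn")) {
    m <- tinyModel(backbone = backbone, seed = 36)
    pr <- predictProfiles(m, randomCodons(15), "LEU_ILE")
    expect_identical(pr$yDc, pr$yCtrl + pr$yDelta)
    expect_length(pr$yDc, 15L)
  }
  # zeroed read-outs give all-zero heads
  m0 <- tinyModel()
  m0@params$wCtrl[] <- 0; m0@params$bCtrl <- 0
  m0@params$wDelta[] <- 0; m0@params$bDelta <- 0
  pr0 <- predictProfiles(m0, randomCodons(5), "CTRL")
  expect_true(all(pr0$yDc == 0))
  expect_error(predictProfiles(m0, character(0), "CTRL"))
})

test_that("compiled and reference engines agree to machine precision", {
  set.seed(37)
  toks <- sample(61, 30, replace = TRUE)
  s <- riboSample(codonSequence("g", allCodons()[toks]), "VAL",
                  yCtrl = runif(30), yDc = runif(30))
  mR <- riboModel(modelConfig(dModel = 32L, seed = 38, engine = "R"))
  mC <- riboModel(modelConfig(dModel = 32L, seed = 38, engine = "cpp"))
  expect_identical(mR@params, mC@params)
  X <- rsNs$embedInput(mC, toks, "VAL")
  cR <- rsNs$nnForward(mR, X); cC <- rsNs$nnForward(mC, X)
  expect_equal(cR$yCtrl, cC$yCtrl, tolerance = 1e-12)
  lg <- rsNs$lossWithGrad(s, cC$yCtrl, cC$yDelta)
  gR <- rsNs$nnBackward(mR, cR, lg$gCtrl, lg$gDelta, tokensIdx = toks,
                        condIdx = 4L)
  gC <- rsNs$nnBackward(mC, cC, lg$gCtrl, lg$gDelta, tokensIdx = toks,
                        condIdx = 4L)
  for (nm in names(gR$grads))
    expect_equal(gR$grads[[nm]], gC$grads[[nm]], tolerance = 1e-10,
                 ignore_attr = TRUE)
  # batched and single-sequence inference agree, incl. the scored-row path
  tm <- matrix(sample(61, 6 * 21, replace = TRUE), 6, 21)
  pR <- rsNs$nnForwardBatch(mR, tm, 2L)
  pC <- rsNs$nnForwardBatch(mC, tm, 2L)
  expect_equal(pR$yDc, pC$yDc, tolerance = 1e-12)
  sc <- rsNs$nnScoreWindows(mC, tm, 2L, 10L)
  expect_equal(sc$yCtrl, pC$yCtrl[, 11L], tolerance = 1e-12)
  for (b in 1:6) {
    pr <- predictProfiles(mC, allCodons()[tm[b, ]], "LEU")
    expect_equal(pr$yDc, pC$yDc[b, ], tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  # directional finite-difference check along the analytic gradient, on a
  # 10-position fixture; per-entry checks on the larger components
  for (engine in c("cpp", "R")) {
    m <- riboModel(modelConfig(dModel = 16L, nLayers = 2L, nHeads = 2L,
                               seed = 39, engine = engine))
    set.seed(40)
    toks <- sample(61, 10, replace = TRUE)
    s <- riboSample(codonSequence("g", allCodons()[toks]), "ILE",
                    yCtrl = runif(10), yDc = runif(10))
    f <- function(params) {
      m2 <- m; m2@params <- params
      X <- rsNs$embedInput(m2, toks, "ILE")
      cc <- rsNs$nnForward(m2, X)
      rsNs$lossWithGrad(s, cc$yCtrl, cc$yDelta)$loss
    }
    X <- rsNs$embedInput(m, toks, "ILE")
    cc <- rsNs$nnForward(m, X)
    lg <- rsNs$lossWithGrad(s, cc$yCtrl, cc$yDelta)
    res <- rsNs$nnBackward(m, cc, lg$gCtrl, lg$gDelta, tokensIdx = toks,
                           condIdx = 3L)
    g <- res$grads
    gnorm2 <- sum(vapply(names(g), function(nm) sum(g[[nm]]^2), numeric(1)))
    h <- 1e-4 / sqrt(gnorm2)
    pp <- m@params; pm <- m@params
    for (nm in names(g)) {
      pp[[nm]] <- pp[[nm]] + h * g[[nm]]
      pm[[nm]] <- pm[[nm]] - h * g[[nm]]
    }
    fd <- (f(pp) - f(pm)) / (2 * h)
    expect_equal(fd, gnorm2, tolerance = 1e-4)
  }
})

test_that("the recurrent backbone honors the shared input/output contract", {
  m <- tinyModel(backbone = "birnn", seed = 41)
  set.seed(41)
  cs <- randomCodons(12)
  pr1 <- predictProfiles(m, cs, "VAL")
  pr2 <- predictProfiles(m, cs, "VAL")
  expect_identical(pr1, pr2)                   # deterministic
  expect_length(pr1$yCtrl, 12L)
  # conditioning changes the output
  pr3 <- predictProfiles(m, cs, "CTRL")
  expect_false(isTRUE(all.equal(pr1$yDelta, pr3$yDelta)))
})
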