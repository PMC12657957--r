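mkWindow <- function(model, condition = "VAL", w = 21L, seed = 81L) {
  set.seed(seed)
  cs <- randomCodons(w)
  off <- as.integer((w - 1) %/% 2)
  new("MutationWindow", geneId = "g1", condition = condition, codons = cs,
      start = 100L, aSiteOffset = off,
      baseline = rsNs$windowBaseline(model, cs, condition, off))
}

test_that("mutation scores are signed arctan percentage changes", {
  expect_equal(mutationScore(1, 1), 0)
  expect_equal(mutationScore(0, 1), 100 * atan(1 / 1e-6))
  expect_lt(abs(mutationScore(0, 1) - 100 * pi / 2), 1e-2)
  # sign antisymmetry: swapping the pair flips the direction of the call
  expect_equal(sign(mutationScore(2, 1)), -sign(mutationScore(1, 2)))
  expect_equal(mutationScore(1, 3), 100 * atan(2))
})

test_that("beam search emits the exact level cardinalities for any width", {
  m <- tinyModel(dModel = 16L, nLayers = 1L, seed = 82)
  win <- mkWindow(m)
  for (width in c(1L, 2L, 3L)) {
    mo <- beamSearchMotifs(win, m, width = width, maxSize = 3L)
    sizes <- vapply(mo, function(x) length(x@positions), integer(1))
    expect_equal(sum(sizes == 1), width)
    expect_equal(sum(sizes == 2), width^2)
    expect_equal(sum(sizes == 3), width^3)
    expect_length(mo, width + width^2 + width^3)
  }
})

test_that("level-1 beam equals an exhaustive substitution scan", {
  m <- tinyModel(dModel = 16L, nLayers = 1L, seed = 83)
  win <- mkWindow(m, seed = 84L)
  w <- length(win@codons)
  head <- "yDelta"
  # brute force: score every (position, codon) substitution individually
  rows <- list()
  for (p in seq_len(w)) {
    for (cod in setdiff(senseCodons(), win@codons[p])) {
      mut <- win@codons; mut[p] <- cod
      pred <- predictProfiles(m, mut, win@condition)[[head]][win@aSiteOffset + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        pos = p - (win@aSiteOffset + 1L), codon = cod,
        score = mutationScore(win@baseline, pred))
    }
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, df$pos, df$codon), ]
  mo <- beamSearchMotifs(win, m, width = 5L, maxSize = 1L)
  expect_length(mo, 5L)
  for (k in 1:5) {
    expect_equal(mo[[k]]@positions, df$pos[k])
    expect_equal(mo[[k]]@codons, df$codon[k])
    expect_equal(mo[[k]]@score, df$score[k], tolerance = 1e-9)
  }
})

test_that("frozen positions are never re-mutated and motifs stay within the window", {
  m <- tinyModel(dModel = 16L, nLayers = 1L, seed = 85)
  win <- mkWindow(m, seed = 86L)
  mo <- beamSearchMotifs(win, m, width = 3L, maxSize = 3L)
  for (x in mo) {
    expect_false(anyDuplicated(x@positions) > 0)
    expect_true(all(x@positions >= -win@aSiteOffset))
    expect_true(all(x@positions <= length(win@codons) - 1L - win@aSiteOffset))
    expect_equal(x@positions, sort(x@positions))
    # a mutation to the resident codon is not a perturbation
    orig <- win@codons[x@positions + win@aSiteOffset + 1L]
    expect_false(any(orig == x@codons))
  }
})

test_that("a constant-output model yields all-zero scores with a deterministic tie rule", {
  m <- tinyModel(dModel = 16L, nLayers = 0L, seed = 87)
  m@params$wCtrl[] <- 0; m@params$wDelta[] <- 0
  m@params$bCtrl <- 0.5; m@params$bDelta <- 0.5
  win <- mkWindow(m, seed = 88L)
  mo1 <- beamSearchMotifs(win, m, width = 2L, maxSize = 2L)
  mo2 <- beamSearchMotifs(win, m, width = 2L, maxSize = 2L)
  expect_true(all(vapply(mo1, function(x) x@score, numeric(1)) == 0))
  expect_identical(lapply(mo1, function(x) x@canonical),
                   lapply(mo2, function(x) x@canonical))
  # ties resolve to the smallest relative position, then codon order
  expect_equal(mo1[[1]]@positions, -win@aSiteOffset)
  expect_equal(mo1[[1]]@codons, setdiff(senseCodons(),
                                        win@codons[1])[1])
})

test_that("canonicalization inserts one SKIP per gap codon and round-trips", {
  c1 <- canonicalizeMotif(c(-1, 1), c("CTG", "CTT"))
  expect_equal(c1$canonical, "CTG [SKIP] CTT")
  expect_equal(c1$anchor, -1L)
  c2 <- canonicalizeMotif(0, "GTC")
  expect_equal(c2$canonical, "GTC")
  c3 <- canonicalizeMotif(c(-3, -1), c("GTC", "GTC"))
  expect_equal(c3$canonical, "GTC [SKIP] GTC")
  expect_equal(c3$anchor, -3L)
  expect_error(canonicalizeMotif(c(1, 1), c("AAA", "CCC")), "distinct")
  # round trip over random motifs
  set.seed(89)
  for (k in 1:30) {
    sz <- sample(1:3, 1)
    pos <- sort(sample(-10:10, sz))
    cod <- sample(senseCodons(), sz, replace = TRUE)
    cc <- canonicalizeMotif(pos, cod)
    back <- parseMotif(cc$canonical, cc$anchor)
    expect_equal(back$positions, pos)
    expect_equal(back$codons, cod)
  }
})

test_that("fast-window selection matches an exhaustive trough scan", {
  set.seed(90)
  ds <- smallTrainedFixture()
  m <- tinyModel(dModel = 16L, nLayers = 1L, seed = 91)
  suppressWarnings(
    wins <- selectFastWindows(ds, m, perCondition = 1000L, seed = 4L,
                              conditions = "VAL"))
  # oracle: every (gene, position) with stalling value < mean - sd
  want <- list()
  for (s in samples(ds)) {
    if (condition(s) != "VAL") next
    y <- stallingProfile(s)
    ann <- which(!is.na(y))
    mu <- mean(y[ann]); sd0 <- sqrt(mean((y[ann] - mu)^2))
    for (p in ann[y[ann] < mu - sd0])
      want[[paste(geneId(s), p - 1L)]] <- TRUE
  }
  got <- vapply(wins, function(w) paste(w@geneId, w@start + w@aSiteOffset),
                character(1))
  expect_setequal(got, names(want))
  # requesting zero windows yields none; constant profiles qualify nowhere
  expect_length(selectFastWindows(ds, m, perCondition = 0L, seed = 1L,
                                  conditions = "VAL"), 0L)
  flat <- riboDataset(list(riboSample(makeSeq("gf", 30L), "VAL",
                                      yCtrl = rep(1, 30), yDc = rep(1, 30))))
  expect_warning(w0 <- selectFastWindows(flat, m, perCondition = 5L,
                                         seed = 1L, conditions = "VAL"),
                 "no qualifying")
  expect_length(w0, 0L)
  # reproducibility by seed
  suppressWarnings({
    wa <- selectFastWindows(ds, m, perCondition = 10L, seed = 7L,
                            conditions = "VAL")
    wb <- selectFastWindows(ds, m, perCondition = 10L, seed = 7L,
                            conditions = "VAL")
  })
  expect_identical(lapply(wa, function(w) w@codons),
                   lapply(wb, function(w) w@codons))
})

test_that("enrichment tables match a hypergeometric oracle and BH is monotone", {
  # balanced table: odds ratio 1, p = 1
  mkMotif <- function(canonical, anchor = 0L) {
    pm <- parseMotif(canonical, anchor)
    new("Motif", positions = pm$positions, codons = pm$codons,
        canonical = canonical, anchor = anchor, score = 1,
        geneId = "g", condition = "VAL", aSite = 0L)
  }
  # construct a dataset with a planted peak region rich in GTC
  set.seed(92)
  n <- 200L
  cs <- sample(setdiff(senseCodons(), "GTC"), n, replace = TRUE)
  cs[90:110] <- "GTC"
  delta <- rep(0.01, n) + rnorm(n, 0, 0.001)
  delta[95:105] <- 2   # strong peak -> SW covers ~85..115
  yc <- runif(n, 0.5, 1.5)
  s <- riboSample(codonSequence("gE", cs), "VAL", yCtrl = yc,
                  yDc = yc + delta)
  ds <- riboDataset(list(s))
  motifs <- c(replicate(5, mkMotif("GTC")), replicate(3, mkMotif("AAA")))
  res <- motifEnrichment(motifs, ds, "VAL", topN = 10L)
  gtc <- res[res$motif == "GTC", ]
  # oracle: two-sided Fisher p from hypergeometric sums
  fisherOracle <- function(kIn, nIn, kOut, nOut) {
    k <- kIn + kOut
    support <- max(0, k - nOut):min(nIn, k)
    pr <- stats::dhyper(support, nIn, nOut, k)
    sum(pr[pr <= stats::dhyper(kIn, nIn, nOut, k) * (1 + 1e-7)])
  }
  expect_equal(gtc$p,
               fisherOracle(gtc$countIn, gtc$totalIn, gtc$countOut,
                            gtc$totalOut), tolerance = 1e-9)
  expect_lt(gtc$p, 0.01)
  aaa <- res[res$motif == "AAA", ]
  expect_gt(aaa$p, 0.05)
  # BH q-values never fall below their p and are monotone in p-rank
  expect_true(all(res$q >= res$p - 1e-12))
  oo <- order(res$p)
  expect_true(all(diff(res$q[oo]) >= -1e-12))
  # a motif longer than every region simply never occurs
  long <- mkMotif(paste(c("GTC", rep("[SKIP]", 198), "GTC"), collapse = " "),
                  anchor = 0L)
  resL <- motifEnrichment(list(long), ds, "VAL", topN = 1L)
  expect_equal(resL$countIn + resL$countOut, 0L)
})
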