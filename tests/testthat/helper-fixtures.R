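# shared fixture builders; all randomness seeded by the caller

rsNs <- asNamespace("ribostall")

randomCodons <- function(n) sample(senseCodons(), n, replace = TRUE)

makeSeq <- function(id = "g1", n = 20L) codonSequence(id, randomCodons(n))

makeSample <- function(id = "g1", n = 20L, condition = "VAL",
                       split = "unassigned") {
  riboSample(makeSeq(id, n), condition, yCtrl = runif(n, 0.1, 2),
             yDc = runif(n, 0.1, 2), split = split)
}

tinyModel <- function(dModel = 16L, nLayers = 1L, nHeads = 2L, seed = 7L,
                      engine = "cpp", backbone = "transformer") {
  riboModel(modelConfig(dModel = dModel, nLayers = nLayers, nHeads = nHeads,
                        backbone = backbone, seed = seed, engine = engine))
}

# independent textbook Pearson correlation (used as metric oracle)
refPearson <- function(a, b) {
  num <- sum((a - mean(a)) * (b - mean(b)))
  num / (sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2)))
}

# a tiny preprocessed synthetic dataset shared by training-level tests
smallTrainedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulateDataset(simulationConfig(nGenes = 30L,
                                             lenRange = c(80L, 140L),
                                             seed = 77L))
      cache <<- preprocessPipeline(ds)$dataset
    }
    cache
  }
})

# dense, literal implementation of the relative-attention equations for a
# single layer / single head: e_ij = (x_i Wq + u)(x_j Wk)^T +
# (x_i Wq + v)(r_{i-j} Wr)^T, alpha = row-softmax(e), h_i = sum_j alpha_ij x_j Wv,
# followed by the same output projection / residual / normalization sublayers.
denseOracleLayer <- function(p, X, Rrel, scale) {
  n <- nrow(X)
  E <- matrix(0, n, n)
  for (i in 1:n) {
    for (j in 1:n) {
      qi <- X[i, ] %*% p$`L1.Wq`
      ac <- (qi + p$`L1.u`) %*% t(X[j, ] %*% p$`L1.Wk`)
      r <- Rrel[n + (i - j), , drop = FALSE]
      bd <- (qi + p$`L1.v`) %*% t(r %*% p$`L1.Wr`)
      E[i, j] <- (ac + bd) * scale
    }
  }
  A <- t(apply(E, 1, function(e) exp(e - max(e)) / sum(exp(e - max(e)))))
  H <- matrix(0, n, ncol(X))
  for (i in 1:n)
    for (j in 1:n)
      H[i, ] <- H[i, ] + A[i, j] * (X[j, ] %*% p$`L1.Wv`)
  att <- H %*% p$`L1.Wo` + matrix(p$`L1.bo`, n, ncol(X), byrow = TRUE)
  ln <- function(S, g, b) {
    t(apply(S, 1, function(r) {
      g * (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) + b
    }))
  }
  X1 <- ln(X + att, p$`L1.g1`, p$`L1.b1`)
  Hf <- pmax(X1 %*% p$`L1.W1` + matrix(p$`L1.b1f`, n, length(p$`L1.b1f`),
                                       byrow = TRUE), 0)
  F2 <- Hf %*% p$`L1.W2` + matrix(p$`L1.b2f`, n, ncol(X), byrow = TRUE)
  ln(X1 + F2, p$`L1.g2`, p$`L1.b2`)
}

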