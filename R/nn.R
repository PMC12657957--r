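#' Model configuration
#'
#' The backbone consumes one embedding vector per codon position (the sum
#' of a learnable codon embedding and a learnable condition embedding,
#' so conditioning is injected additively at every position and the
#' output length always equals the codon count). Two position-wise
#' linear heads read out the control profile and the deprivation
#' difference; their sum is the deprivation-condition prediction.
#'
#' @param dModel Embedding width `D` (divisible by `nHeads` for the
#'   transformer backbone).
#' @param nLayers Number of backbone layers (0 gives a purely linear
#'   model, useful as an attribution reference).
#' @param nHeads Attention heads (transformer backbone).
#' @param dFf Feed-forward hidden width (default `2 * dModel`).
#' @param backbone `"transformer"` (relative multi-head attention) or
#'   `"birnn"` (bidirectional tanh recurrence, same input/output
#'   contract).
#' @param dropout Dropout rate on the attention output and feed-forward
#'   hidden layer during training (0 disables).
#' @param seed Seed for parameter initialization.
#' @param engine `"cpp"` (compiled, default) or `"R"` (pure-R reference
#'   implementation of the identical arithmetic; the two are
#'   cross-checked in the test suite). The recurrent backbone and
#'   dropout > 0 always run the R path.
#' @return A configuration list.
#' @export
#' @useDynLib ribostall, .registration = TRUE
#' @importFrom Rcpp sourceCpp
modelConfig <- function(dModel = 64L, nLayers = 2L, nHeads = 4L,
                        dFf = 2L * dModel, backbone = "transformer",
                        dropout = 0, seed = 42L, engine = "cpp") {
  backbone <- match.arg(backbone, c("transformer", "birnn"))
  engine <- match.arg(engine, c("cpp", "R"))
  if (backbone == "transformer" && dModel %% nHeads != 0L)
    stop("dModel must be divisible by nHeads", call. = FALSE)
  if (backbone == "birnn" && dModel %% 2L != 0L)
    stop("dModel must be even for the birnn backbone", call. = FALSE)
  list(dModel = as.integer(dModel), nLayers = as.integer(nLayers),
       nHeads = as.integer(nHeads), dFf = as.integer(dFf),
       backbone = backbone, dropout = dropout, seed = as.integer(seed),
       engine = engine)
}

rmat <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

#' Initialize a model
#'
#' @param config A [modelConfig()].
#' @return A [RiboModel-class] with freshly initialized parameters
#'   (deterministic given `config$seed`).
#' @export
riboModel <- function(config = modelConfig()) {
  set.seed(config$seed)
  D <- config$dModel; Fw <- config$dFf
  p <- list(Ecod = rmat(64L, D), Econd = rmat(length(conditionIds()), D))
  for (l in seq_len(config$nLayers)) {
    pre <- paste0("L", l, ".")
    if (config$backbone == "transformer") {
      p[[paste0(pre, "Wq")]] <- rmat(D, D)
      p[[paste0(pre, "Wk")]] <- rmat(D, D)
      p[[paste0(pre, "Wv")]] <- rmat(D, D)
      p[[paste0(pre, "Wr")]] <- rmat(D, D)
      p[[paste0(pre, "u")]] <- stats::rnorm(D, 0, 0.02)
      p[[paste0(pre, "v")]] <- stats::rnorm(D, 0, 0.02)
      p[[paste0(pre, "Wo")]] <- rmat(D, D)
      p[[paste0(pre, "bo")]] <- numeric(D)
    } else {
      K <- D %/% 2L
      for (dir in c("f", "b")) {
        p[[paste0(pre, "Wx", dir)]] <- rmat(D, K, sd = sqrt(1 / D))
        p[[paste0(pre, "Wh", dir)]] <- rmat(K, K, sd = sqrt(1 / K))
        p[[paste0(pre, "bh", dir)]] <- numeric(K)
      }
      p[[paste0(pre, "Wo")]] <- rmat(D, D, sd = sqrt(1 / D))
      p[[paste0(pre, "bo")]] <- numeric(D)
    }
    p[[paste0(pre, "g1")]] <- rep(1, D)
    p[[paste0(pre, "b1")]] <- numeric(D)
    p[[paste0(pre, "W1")]] <- rmat(D, Fw, sd = sqrt(2 / (D + Fw)))
    p[[paste0(pre, "b1f")]] <- numeric(Fw)
    p[[paste0(pre, "W2")]] <- rmat(Fw, D, sd = sqrt(2 / (D + Fw)))
    p[[paste0(pre, "b2f")]] <- numeric(D)
    p[[paste0(pre, "g2")]] <- rep(1, D)
    p[[paste0(pre, "b2")]] <- numeric(D)
  }
  p$wCtrl <- stats::rnorm(D, 0, 0.02); p$bCtrl <- 0
  p$wDelta <- stats::rnorm(D, 0, 0.02); p$bDelta <- 0
  new("RiboModel", config = config, params = p)
}

# fixed sinusoidal relative positional encodings for offsets -(n-1)..(n-1);
# row (offset + n) encodes offset. Cached per (n, D).
.relCache <- new.env(parent = emptyenv())

relEncoding <- function(n, D) {
  key <- paste0(n, "_", D)
  hit <- .relCache[[key]]
  if (!is.null(hit)) return(hit)
  off <- seq.int(-(n - 1L), n - 1L)
  half <- D %/% 2L
  inv <- 1 / 10000^((seq_len(half) - 1L) * 2 / D)
  ang <- outer(off, inv)
  R <- cbind(sin(ang), cos(ang))
  if (ncol(R) < D) R <- cbind(R, 0)  # odd D padding
  .relCache[[key]] <- R
  R
}

.LN_EPS <- 1e-5

lnForward <- function(S, g, b) {
  mu <- rowMeans(S)
  Xc <- S - mu
  varr <- rowMeans(Xc^2)
  inv <- 1 / sqrt(varr + .LN_EPS)
  xhat <- Xc * inv
  list(out = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(S)),
       xhat = xhat, inv = inv)
}

lnBackward <- function(dY, ln, g) {
  D <- ncol(dY)
  dxhat <- sweep(dY, 2L, g, "*")
  t1 <- rowSums(dxhat)
  t2 <- rowSums(dxhat * ln$xhat)
  dS <- ln$inv * (dxhat - (t1 + ln$xhat * t2) / D)
  list(dS = dS, dg = colSums(dY * ln$xhat), db = colSums(dY))
}

rowSoftmax <- function(E) {
  m <- E[cbind(seq_len(nrow(E)), max.col(E, ties.method = "first"))]
  W <- exp(E - m)
  W / rowSums(W)
}

#' Embed a sample
#'
#' Per-position input vectors: `codonEmbedding[c_i] + conditionEmbedding[d]`.
#'
#' @param model A [RiboModel-class].
#' @param codonTokens Character vector of codon tokens (or integer
#'   indices into [allCodons()]).
#' @param condition One of [conditionIds()].
#' @return An `n x D` matrix.
#' @export
embedInput <- function(model, codonTokens, condition) {
  idx <- if (is.numeric(codonTokens)) as.integer(codonTokens)
         else codonIndex(codonTokens)
  ci <- match(matchCondition(condition), conditionIds())
  model@params$Ecod[idx, , drop = FALSE] +
    rep(model@params$Econd[ci, ], each = length(idx))
}

# ---- transformer forward (single sequence, optional cache for backprop) ----

tfForward <- function(params, cfg, X, train = FALSE) {
  n <- nrow(X); D <- cfg$dModel; H <- cfg$nHeads; dh <- D %/% H
  if (n == 0L) stop("cannot run the backbone on an empty sequence",
                    call. = FALSE)
  R <- relEncoding(n, D)
  idx <- outer(seq_len(n), seq_len(n), function(i, j) n + i - j)
  gRows <- as.vector(row(idx)); gCols <- as.vector(idx)
  scale <- 1 / sqrt(dh)
  layers <- vector("list", cfg$nLayers)
  for (l in seq_len(cfg$nLayers)) {
    P <- function(nm) params[[paste0("L", l, ".", nm)]]
    Xin <- X
    Q <- X %*% P("Wq"); KE <- X %*% P("Wk"); V <- X %*% P("Wv")
    KR <- R %*% P("Wr")
    O <- matrix(0, n, D)
    A <- vector("list", H)
    for (h in seq_len(H)) {
      hs <- ((h - 1L) * dh + 1L):(h * dh)
      Qh <- Q[, hs, drop = FALSE]
      ACu <- Qh + rep(P("u")[hs], each = n)
      Qv <- Qh + rep(P("v")[hs], each = n)
      AC <- ACu %*% t(KE[, hs, drop = FALSE])
      BDfull <- Qv %*% t(KR[, hs, drop = FALSE])
      BD <- matrix(BDfull[cbind(gRows, gCols)], n, n)
      A[[h]] <- rowSoftmax((AC + BD) * scale)
      O[, hs] <- A[[h]] %*% V[, hs, drop = FALSE]
    }
    attnOut <- O %*% P("Wo") + rep(P("bo"), each = n)
    dropA <- NULL
    if (train && cfg$dropout > 0) {
      dropA <- matrix(stats::rbinom(n * D, 1L, 1 - cfg$dropout), n, D) /
        (1 - cfg$dropout)
      attnOut <- attnOut * dropA
    }
    ln1 <- lnForward(Xin + attnOut, P("g1"), P("b1"))
    X1 <- ln1$out
    Hpre <- X1 %*% P("W1") + rep(P("b1f"), each = n)
    Hf <- pmax(Hpre, 0)
    dropF <- NULL
    if (train && cfg$dropout > 0) {
      dropF <- matrix(stats::rbinom(n * cfg$dFf, 1L, 1 - cfg$dropout),
                      n, cfg$dFf) / (1 - cfg$dropout)
      Hf <- Hf * dropF
    }
    F2 <- Hf %*% P("W2") + rep(P("b2f"), each = n)
    ln2 <- lnForward(X1 + F2, P("g2"), P("b2"))
    layers[[l]] <- list(Xin = Xin, Q = Q, KE = KE, V = V, KR = KR, A = A,
                        O = O, ln1 = ln1, X1 = X1, Hpre = Hpre, Hf = Hf,
                        ln2 = ln2, dropA = dropA, dropF = dropF)
    X <- ln2$out
  }
  list(out = X, layers = layers, R = R, gRows = gRows, gCols = gCols,
       scale = scale, n = n)
}

tfBackward <- function(params, cfg, cache, dX, grads) {
  n <- cache$n; D <- cfg$dModel; H <- cfg$nHeads; dh <- D %/% H
  for (l in rev(seq_len(cfg$nLayers))) {
    P <- function(nm) params[[paste0("L", l, ".", nm)]]
    nm <- function(x) paste0("L", l, ".", x)
    cc <- cache$layers[[l]]
    b2 <- lnBackward(dX, cc$ln2, P("g2"))
    grads[[nm("g2")]] <- grads[[nm("g2")]] + b2$dg
    grads[[nm("b2")]] <- grads[[nm("b2")]] + b2$db
    dX1 <- b2$dS; dF2 <- b2$dS
    grads[[nm("W2")]] <- grads[[nm("W2")]] + crossprod(cc$Hf, dF2)
    grads[[nm("b2f")]] <- grads[[nm("b2f")]] + colSums(dF2)
    dHf <- dF2 %*% t(P("W2"))
    if (!is.null(cc$dropF)) dHf <- dHf * cc$dropF
    dHpre <- dHf * (cc$Hpre > 0)
    grads[[nm("W1")]] <- grads[[nm("W1")]] + crossprod(cc$X1, dHpre)
    grads[[nm("b1f")]] <- grads[[nm("b1f")]] + colSums(dHpre)
    dX1 <- dX1 + dHpre %*% t(P("W1"))
    b1 <- lnBackward(dX1, cc$ln1, P("g1"))
    grads[[nm("g1")]] <- grads[[nm("g1")]] + b1$dg
    grads[[nm("b1")]] <- grads[[nm("b1")]] + b1$db
    dXin <- b1$dS
    dAttnOut <- b1$dS
    if (!is.null(cc$dropA)) dAttnOut <- dAttnOut * cc$dropA
    grads[[nm("Wo")]] <- grads[[nm("Wo")]] + crossprod(cc$O, dAttnOut)
    grads[[nm("bo")]] <- grads[[nm("bo")]] + colSums(dAttnOut)
    dO <- dAttnOut %*% t(P("Wo"))
    dQ <- matrix(0, n, D); dKE <- matrix(0, n, D); dV <- matrix(0, n, D)
    dKR <- matrix(0, 2L * n - 1L, D)
    for (h in seq_len(H)) {
      hs <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      Vh <- cc$V[, hs, drop = FALSE]
      dOh <- dO[, hs, drop = FALSE]
      dA <- dOh %*% t(Vh)
      dV[, hs] <- crossprod(A, dOh)
      dZ <- A * (dA - rowSums(dA * A)) * cache$scale
      KEh <- cc$KE[, hs, drop = FALSE]
      KRh <- cc$KR[, hs, drop = FALSE]
      Qh <- cc$Q[, hs, drop = FALSE]
      ACu <- Qh + rep(P("u")[hs], each = n)
      Qv <- Qh + rep(P("v")[hs], each = n)
      G1 <- dZ %*% KEh
      dKE[, hs] <- crossprod(dZ, ACu)
      dBDfull <- matrix(0, n, 2L * n - 1L)
      dBDfull[cbind(cache$gRows, cache$gCols)] <- as.vector(dZ)
      G2 <- dBDfull %*% KRh
      dKR[, hs] <- dKR[, hs, drop = FALSE] + crossprod(dBDfull, Qv)
      dQ[, hs] <- G1 + G2
      gu <- grads[[nm("u")]]; gu[hs] <- gu[hs] + colSums(G1)
      grads[[nm("u")]] <- gu
      gv <- grads[[nm("v")]]; gv[hs] <- gv[hs] + colSums(G2)
      grads[[nm("v")]] <- gv
    }
    Xin <- cc$Xin
    grads[[nm("Wq")]] <- grads[[nm("Wq")]] + crossprod(Xin, dQ)
    grads[[nm("Wk")]] <- grads[[nm("Wk")]] + crossprod(Xin, dKE)
    grads[[nm("Wv")]] <- grads[[nm("Wv")]] + crossprod(Xin, dV)
    grads[[nm("Wr")]] <- grads[[nm("Wr")]] + crossprod(cache$R, dKR)
    dX <- dXin + dQ %*% t(P("Wq")) + dKE %*% t(P("Wk")) + dV %*% t(P("Wv"))
  }
  list(grads = grads, dX = dX)
}

# ---- bidirectional recurrent backbone (same sublayer contract) ----

rnnDirForward <- function(X, Wx, Wh, b, reverse) {
  n <- nrow(X); K <- ncol(Wx)
  ord <- if (reverse) rev(seq_len(n)) else seq_len(n)
  Hs <- matrix(0, n, K)
  XW <- X %*% Wx + rep(b, each = n)
  h <- numeric(K)
  for (t in ord) {
    h <- tanh(XW[t, ] + as.vector(h %*% Wh))
    Hs[t, ] <- h
  }
  Hs
}

rnnDirBackward <- function(X, Hs, dHs, Wx, Wh, reverse) {
  n <- nrow(X); K <- ncol(Hs)
  ord <- if (reverse) seq_len(n) else rev(seq_len(n))
  dWx <- matrix(0, ncol(X), K); dWh <- matrix(0, K, K); db <- numeric(K)
  dX <- matrix(0, n, ncol(X))
  carry <- numeric(K)
  for (t in ord) {
    dh <- dHs[t, ] + carry
    da <- dh * (1 - Hs[t, ]^2)
    prevIdx <- if (reverse) t + 1L else t - 1L
    hPrev <- if (prevIdx >= 1L && prevIdx <= n) Hs[prevIdx, ] else numeric(K)
    dWx <- dWx + outer(X[t, ], da)
    dWh <- dWh + outer(hPrev, da)
    db <- db + da
    dX[t, ] <- as.vector(da %*% t(Wx))
    carry <- as.vector(da %*% t(Wh))
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

rnnForward <- function(params, cfg, X, train = FALSE) {
  n <- nrow(X); D <- cfg$dModel
  if (n == 0L) stop("cannot run the backbone on an empty sequence",
                    call. = FALSE)
  layers <- vector("list", cfg$nLayers)
  for (l in seq_len(cfg$nLayers)) {
    P <- function(nmx) params[[paste0("L", l, ".", nmx)]]
    Xin <- X
    Hf <- rnnDirForward(X, P("Wxf"), P("Whf"), P("bhf"), reverse = FALSE)
    Hb <- rnnDirForward(X, P("Wxb"), P("Whb"), P("bhb"), reverse = TRUE)
    O <- cbind(Hf, Hb)
    attnOut <- O %*% P("Wo") + rep(P("bo"), each = n)
    ln1 <- lnForward(Xin + attnOut, P("g1"), P("b1"))
    X1 <- ln1$out
    Hpre <- X1 %*% P("W1") + rep(P("b1f"), each = n)
    Hrelu <- pmax(Hpre, 0)
    F2 <- Hrelu %*% P("W2") + rep(P("b2f"), each = n)
    ln2 <- lnForward(X1 + F2, P("g2"), P("b2"))
    layers[[l]] <- list(Xin = Xin, Hf = Hf, Hb = Hb, O = O, ln1 = ln1,
                        X1 = X1, Hpre = Hpre, Hrelu = Hrelu, ln2 = ln2)
    X <- ln2$out
  }
  list(out = X, layers = layers, n = n)
}

rnnBackward <- function(params, cfg, cache, dX, grads) {
  n <- cache$n; D <- cfg$dModel; K <- D %/% 2L
  for (l in rev(seq_len(cfg$nLayers))) {
    P <- function(nmx) params[[paste0("L", l, ".", nmx)]]
    nm <- function(x) paste0("L", l, ".", x)
    cc <- cache$layers[[l]]
    b2 <- lnBackward(dX, cc$ln2, P("g2"))
    grads[[nm("g2")]] <- grads[[nm("g2")]] + b2$dg
    grads[[nm("b2")]] <- grads[[nm("b2")]] + b2$db
    dX1 <- b2$dS; dF2 <- b2$dS
    grads[[nm("W2")]] <- grads[[nm("W2")]] + crossprod(cc$Hrelu, dF2)
    grads[[nm("b2f")]] <- grads[[nm("b2f")]] + colSums(dF2)
    dHpre <- (dF2 %*% t(P("W2"))) * (cc$Hpre > 0)
    grads[[nm("W1")]] <- grads[[nm("W1")]] + crossprod(cc$X1, dHpre)
    grads[[nm("b1f")]] <- grads[[nm("b1f")]] + colSums(dHpre)
    dX1 <- dX1 + dHpre %*% t(P("W1"))
    b1 <- lnBackward(dX1, cc$ln1, P("g1"))
    grads[[nm("g1")]] <- grads[[nm("g1")]] + b1$dg
    grads[[nm("b1")]] <- grads[[nm("b1")]] + b1$db
    dXin <- b1$dS
    grads[[nm("Wo")]] <- grads[[nm("Wo")]] + crossprod(cc$O, b1$dS)
    grads[[nm("bo")]] <- grads[[nm("bo")]] + colSums(b1$dS)
    dO <- b1$dS %*% t(P("Wo"))
    bf <- rnnDirBackward(cc$Xin, cc$Hf, dO[, seq_len(K), drop = FALSE],
                         P("Wxf"), P("Whf"), reverse = FALSE)
    bb <- rnnDirBackward(cc$Xin, cc$Hb, dO[, K + seq_len(K), drop = FALSE],
                         P("Wxb"), P("Whb"), reverse = TRUE)
    grads[[nm("Wxf")]] <- grads[[nm("Wxf")]] + bf$dWx
    grads[[nm("Whf")]] <- grads[[nm("Whf")]] + bf$dWh
    grads[[nm("bhf")]] <- grads[[nm("bhf")]] + bf$db
    grads[[nm("Wxb")]] <- grads[[nm("Wxb")]] + bb$dWx
    grads[[nm("Whb")]] <- grads[[nm("Whb")]] + bb$dWh
    grads[[nm("bhb")]] <- grads[[nm("bhb")]] + bb$db
    dX <- dXin + bf$dX + bb$dX
  }
  list(grads = grads, dX = dX)
}

# ---- shared forward/backward entry points ----

useCppEngine <- function(cfg, train) {
  !identical(cfg$engine, "R") && cfg$backbone == "transformer" &&
    cfg$nLayers > 0L && !(train && cfg$dropout > 0)
}

nnForward <- function(model, X, train = FALSE, needCache = TRUE) {
  cfg <- model@config; p <- model@params
  if (nrow(X) == 0L) stop("cannot run the backbone on an empty sequence",
                          call. = FALSE)
  if (cfg$nLayers == 0L) {
    cache <- list(out = X, layers = list(), n = nrow(X), engine = "none")
  } else if (useCppEngine(cfg, train)) {
    res <- cpp_tf_forward(p, cfg$nLayers, cfg$nHeads, X,
                          relEncoding(nrow(X), cfg$dModel), needCache)
    cache <- list(out = res$out, cppCache = res$cache, n = nrow(X),
                  engine = "cpp")
  } else if (cfg$backbone == "transformer") {
    cache <- tfForward(p, cfg, X, train)
    cache$engine <- "Rtf"
  } else {
    cache <- rnnForward(p, cfg, X, train)
    cache$engine <- "Rrnn"
  }
  cache$X0 <- X
  cache$yCtrl <- as.vector(cache$out %*% p$wCtrl) + p$bCtrl
  cache$yDelta <- as.vector(cache$out %*% p$wDelta) + p$bDelta
  cache
}

zeroGrads <- function(params) lapply(params, function(p) p * 0)

# gYc/gYd: gradients of the scalar objective wrt the two head outputs.
# Returns parameter gradients (embedding grads included) and dX0, the
# gradient wrt the input embedding matrix (used by integrated gradients).
nnBackward <- function(model, cache, gYc, gYd, grads = NULL,
                       tokensIdx = NULL, condIdx = NULL) {
  cfg <- model@config; p <- model@params
  if (is.null(grads)) grads <- zeroGrads(p)
  out <- cache$out
  grads$wCtrl <- grads$wCtrl + as.vector(crossprod(out, gYc))
  grads$bCtrl <- grads$bCtrl + sum(gYc)
  grads$wDelta <- grads$wDelta + as.vector(crossprod(out, gYd))
  grads$bDelta <- grads$bDelta + sum(gYd)
  dX <- outer(gYc, p$wCtrl) + outer(gYd, p$wDelta)
  res <- if (cache$engine == "none") {
    list(grads = grads, dX = dX)
  } else if (cache$engine == "cpp") {
    cg <- cpp_tf_backward(p, cfg$nLayers, cfg$nHeads, cache$cppCache, dX,
                          relEncoding(cache$n, cfg$dModel))
    for (nm in setdiff(names(cg), "dX0")) {
      g <- cg[[nm]]
      if (is.matrix(grads[[nm]])) grads[[nm]] <- grads[[nm]] + g
      else grads[[nm]] <- grads[[nm]] + as.vector(g)
    }
    list(grads = grads, dX = cg$dX0)
  } else if (cache$engine == "Rtf") {
    tfBackward(p, cfg, cache, dX, grads)
  } else {
    rnnBackward(p, cfg, cache, dX, grads)
  }
  if (!is.null(tokensIdx)) {
    gE <- rowsum(res$dX, tokensIdx)
    ri <- as.integer(rownames(gE))
    res$grads$Ecod[ri, ] <- res$grads$Ecod[ri, , drop = FALSE] + gE
    res$grads$Econd[condIdx, ] <- res$grads$Econd[condIdx, ] + colSums(res$dX)
  }
  res
}

#' Predict profiles for one sequence and condition
#'
#' Runs the backbone and both heads. The deprivation-condition
#' prediction is the exact position-wise sum of the two heads.
#'
#' @param model A [RiboModel-class].
#' @param x A [CodonSequence-class], [RiboSample-class], or character
#'   vector of codon tokens.
#' @param condition One of [conditionIds()] (taken from the sample if
#'   `x` is a [RiboSample-class]).
#' @return List with `yCtrl`, `yDelta`, `yDc` numeric vectors of length
#'   `n`.
#' @export
predictProfiles <- function(model, x, condition = NULL) {
  if (is(x, "RiboSample")) {
    if (is.null(condition)) condition <- condition(x)
    x <- codons(x)
  } else if (is(x, "CodonSequence")) x <- codons(x)
  X <- embedInput(model, x, condition)
  cache <- nnForward(model, X)
  list(yCtrl = cache$yCtrl, yDelta = cache$yDelta,
       yDc = cache$yCtrl + cache$yDelta)
}

# ---- batched transformer inference over equal-length windows ----
# tokenMat: B x w integer codon indices; condIdx: length-B condition
# indices. Row-major flattening: flat row r = (b-1)*w + i.
nnForwardBatch <- function(model, tokenMat, condIdx) {
  cfg <- model@config; p <- model@params
  stopifnot(cfg$backbone == "transformer" || cfg$nLayers == 0L)
  B <- nrow(tokenMat); w <- ncol(tokenMat)
  D <- cfg$dModel; H <- cfg$nHeads; dh <- D %/% H
  flatTok <- as.vector(t(tokenMat))
  if (length(condIdx) == 1L) condIdx <- rep(condIdx, B)
  X <- p$Ecod[flatTok, , drop = FALSE] +
    p$Econd[rep(condIdx, each = w), , drop = FALSE]
  if (cfg$nLayers > 0L && useCppEngine(cfg, train = FALSE)) {
    out <- cpp_tf_forward_batch(p, cfg$nLayers, cfg$nHeads, X,
                                relEncoding(w, D), w, -1L)
    yc <- matrix(as.vector(out %*% p$wCtrl) + p$bCtrl, B, w, byrow = TRUE)
    yd <- matrix(as.vector(out %*% p$wDelta) + p$bDelta, B, w, byrow = TRUE)
    return(list(yCtrl = yc, yDelta = yd, yDc = yc + yd))
  }
  n <- B * w
  imap <- rep(seq_len(w), B)                 # window position of each flat row
  posRows <- function(j) seq.int(j, by = w, length.out = B)
  expIdx <- rep(seq.int(0L, by = w, length.out = B), each = w)  # (b-1)*w
  scale <- 1 / sqrt(dh)
  if (cfg$nLayers > 0L) {
    R <- relEncoding(w, D)
    for (l in seq_len(cfg$nLayers)) {
      P <- function(nmx) p[[paste0("L", l, ".", nmx)]]
      Xin <- X
      Q <- X %*% P("Wq"); KE <- X %*% P("Wk"); V <- X %*% P("Wv")
      KR <- R %*% P("Wr")
      O <- matrix(0, n, D)
      for (h in seq_len(H)) {
        hs <- ((h - 1L) * dh + 1L):(h * dh)
        Qh <- Q[, hs, drop = FALSE]
        ACu <- Qh + rep(P("u")[hs], each = n)
        Qv <- Qh + rep(P("v")[hs], each = n)
        KEh <- KE[, hs, drop = FALSE]
        KRh <- KR[, hs, drop = FALSE]
        S <- matrix(0, n, w)
        Tmat <- Qv %*% t(KRh)                # n x (2w-1)
        for (j in seq_len(w)) {
          KEexp <- KEh[posRows(j)[rep(seq_len(B), each = w)], , drop = FALSE]
          S[, j] <- rowSums(ACu * KEexp) + Tmat[cbind(seq_len(n), w + imap - j)]
        }
        A <- rowSoftmax(S * scale)
        Vh <- V[, hs, drop = FALSE]
        Oh <- matrix(0, n, dh)
        for (j in seq_len(w)) {
          Vexp <- Vh[expIdx + j, , drop = FALSE]
          Oh <- Oh + A[, j] * Vexp
        }
        O[, hs] <- Oh
      }
      attnOut <- O %*% P("Wo") + rep(P("bo"), each = n)
      ln1 <- lnForward(Xin + attnOut, P("g1"), P("b1"))
      X1 <- ln1$out
      Hf <- pmax(X1 %*% P("W1") + rep(P("b1f"), each = n), 0)
      F2 <- Hf %*% P("W2") + rep(P("b2f"), each = n)
      X <- lnForward(X1 + F2, P("g2"), P("b2"))$out
    }
  }
  yc <- matrix(as.vector(X %*% p$wCtrl) + p$bCtrl, B, w, byrow = TRUE)
  yd <- matrix(as.vector(X %*% p$wDelta) + p$bDelta, B, w, byrow = TRUE)
  list(yCtrl = yc, yDelta = yd, yDc = yc + yd)
}

# score many equal-length windows at a single window position (0-based
# aOff); returns per-window yCtrl/yDelta at that position only.
# Processed in chunks to bound peak memory.
nnScoreWindows <- function(model, tokenMat, condIdx, aOff,
                           chunk = 2000L) {
  cfg <- model@config; p <- model@params
  B <- nrow(tokenMat); w <- ncol(tokenMat)
  if (length(condIdx) == 1L) condIdx <- rep(condIdx, B)
  if (cfg$nLayers > 0L && useCppEngine(cfg, train = FALSE)) {
    yc <- numeric(B); yd <- numeric(B)
    Rw <- relEncoding(w, cfg$dModel)
    for (s0 in seq.int(1L, B, by = chunk)) {
      s1 <- min(B, s0 + chunk - 1L)
      ix <- s0:s1
      flatTok <- as.vector(t(tokenMat[ix, , drop = FALSE]))
      X <- p$Ecod[flatTok, , drop = FALSE] +
        p$Econd[rep(condIdx[ix], each = w), , drop = FALSE]
      out <- cpp_tf_forward_batch(p, cfg$nLayers, cfg$nHeads, X, Rw, w,
                                  as.integer(aOff))
      yc[ix] <- as.vector(out %*% p$wCtrl) + p$bCtrl
      yd[ix] <- as.vector(out %*% p$wDelta) + p$bDelta
    }
    return(list(yCtrl = yc, yDelta = yd))
  }
  pr <- nnForwardBatch(model, tokenMat, condIdx)
  list(yCtrl = pr$yCtrl[, aOff + 1L], yDelta = pr$yDelta[, aOff + 1L])
}
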