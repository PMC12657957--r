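#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param lr Peak Adam learning rate (cosine-decayed over `epochs`).
#' @param batchSize Gradient-accumulation batch size (samples are
#'   processed individually, so no padding enters attention, loss, or
#'   metrics; gradients are averaged over the batch before each step).
#' @param optimizer Only `"adam"` is provided.
#' @param patience Early-stopping patience, in epochs without
#'   improvement of the macro-averaged validation DC Pearson
#'   correlation.
#' @param seed Seed controlling shuffling (and dropout, if enabled).
#' @param ensembleSeeds Distinct seeds of the teacher ensemble members
#'   (default 5 members).
#' @return A list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 20L, lr = 2e-3, batchSize = 8L,
                        optimizer = "adam", patience = 5L, seed = 1L,
                        ensembleSeeds = 101:105) {
  stopifnot(optimizer == "adam", length(ensembleSeeds) >= 1L,
            !anyDuplicated(ensembleSeeds))
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batchSize = as.integer(batchSize), optimizer = optimizer,
                 patience = as.integer(patience), seed = as.integer(seed),
                 ensembleSeeds = as.integer(ensembleSeeds)),
            class = "TrainConfig")
}

tokenizeSample <- function(s) {
  list(tok = codonIndex(codons(s)),
       cond = match(condition(s), conditionIds()))
}

adamInit <- function(params) {
  list(m = zeroGrads(params), v = zeroGrads(params), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Macro-averaged deprivation-condition Pearson correlation
#'
#' Per-sample Pearson correlation between the annotated DC target and
#' the summed-head prediction, averaged within each condition and then
#' across conditions.
#'
#' @param model A [RiboModel-class].
#' @param dataset A [RiboDataset-class] (all its samples are used).
#' @return The macro-average (numeric scalar; `NA` if nothing is
#'   evaluable).
#' @export
macroDcPcc <- function(model, dataset) {
  ss <- samples(dataset)
  if (length(ss) == 0L) return(NA_real_)
  conds <- vapply(ss, condition, character(1))
  r <- vapply(ss, function(s) {
    pr <- predictProfiles(model, s)
    pcc(yDc(s), pr$yDc)
  }, numeric(1))
  mean(tapply(r, conds, mean, na.rm = TRUE), na.rm = TRUE)
}

#' Train the dual-headed model
#'
#' Minimizes the correlation + MAE loss (see [computeLoss()]) over the
#' `train` split with Adam and a cosine learning-rate decay, evaluating
#' the macro-averaged DC Pearson correlation on the `val` split after
#' each epoch. Returns the checkpoint with the best validation score.
#' Fully reproducible given the configuration seeds.
#'
#' @param dataset A normalized, split [RiboDataset-class].
#' @param mcfg A [modelConfig()] (its `seed` initializes parameters).
#' @param tcfg A [trainConfig()].
#' @param verbose Print per-epoch progress.
#' @return List with `model` (best checkpoint, a [RiboModel-class]) and
#'   `history` (data.frame: epoch, trainLoss, valDcPcc).
#' @export
trainModel <- function(dataset, mcfg = modelConfig(), tcfg = trainConfig(),
                       verbose = FALSE) {
  trainSet <- subsetSplit(dataset, "train")
  valSet <- subsetSplit(dataset, "val")
  if (nSamples(trainSet) == 0L) stop("empty train split", call. = FALSE)
  if (nSamples(valSet) == 0L) stop("empty val split", call. = FALSE)
  model <- riboModel(mcfg)
  set.seed(tcfg$seed)
  ss <- samples(trainSet)
  toks <- lapply(ss, tokenizeSample)
  state <- adamInit(model@params)
  bestVal <- -Inf; bestParams <- model@params; wait <- 0L
  history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                        valDcPcc = numeric(0))
  for (ep in seq_len(tcfg$epochs)) {
    lr <- tcfg$lr * 0.5 * (1 + cos(pi * (ep - 1L) / tcfg$epochs))
    ord <- sample.int(length(ss))
    epLoss <- 0
    acc <- NULL; accN <- 0L
    for (k in seq_along(ord)) {
      i <- ord[k]
      s <- ss[[i]]
      X <- model@params$Ecod[toks[[i]]$tok, , drop = FALSE] +
        rep(model@params$Econd[toks[[i]]$cond, ], each = nCodons(s))
      cache <- nnForward(model, X, train = TRUE)
      lg <- lossWithGrad(s, cache$yCtrl, cache$yDelta)
      if (!is.finite(lg$loss))
        stop("non-finite loss at epoch ", ep, ", sample ", geneId(s), "/",
             condition(s), call. = FALSE)
      epLoss <- epLoss + lg$loss
      res <- nnBackward(model, cache, lg$gCtrl, lg$gDelta, grads = acc,
                        tokensIdx = toks[[i]]$tok, condIdx = toks[[i]]$cond)
      acc <- res$grads; accN <- accN + 1L
      if (accN == tcfg$batchSize || k == length(ord)) {
        grads <- lapply(acc, function(g) g / accN)
        upd <- adamStep(model@params, grads, state, lr)
        model@params <- upd$params
        state <- upd$state
        acc <- NULL; accN <- 0L
      }
    }
    valPcc <- macroDcPcc(model, valSet)
    history <- rbind(history, data.frame(epoch = ep,
                                         trainLoss = epLoss / length(ss),
                                         valDcPcc = valPcc))
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val DC-PCC %.4f", ep,
                      epLoss / length(ss), valPcc))
    if (is.finite(valPcc) && valPcc > bestVal) {
      bestVal <- valPcc; bestParams <- model@params; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$patience) break
    }
  }
  model@params <- bestParams
  list(model = model, history = history)
}

#' Per-condition evaluation report
#'
#' Computes PCC, SCC, MSE, and MAAPE between the annotated DC targets
#' and the summed-head predictions, averaged per condition, plus a
#' macro-average row.
#'
#' @param model A [RiboModel-class].
#' @param dataset A [RiboDataset-class].
#' @param split Which split tag(s) to evaluate.
#' @return data.frame with one row per condition and a `MacroAvg` row.
#' @export
evaluateModel <- function(model, dataset, split = "test") {
  ss <- samples(subsetSplit(dataset, split))
  if (length(ss) == 0L) stop("no samples in split ", split, call. = FALSE)
  rows <- lapply(ss, function(s) {
    pr <- predictProfiles(model, s)
    data.frame(condition = condition(s), pcc = pcc(yDc(s), pr$yDc),
               scc = scc(yDc(s), pr$yDc), mse = mse(yDc(s), pr$yDc),
               maape = maape(yDc(s), pr$yDc), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(df[, -1], by = list(condition = df$condition),
                          FUN = mean, na.rm = TRUE)
  macro <- data.frame(condition = "MacroAvg", t(colMeans(agg[, -1],
                                                         na.rm = TRUE)))
  rbind(agg, macro)
}

#' Train a seed ensemble
#'
#' Trains one model per seed in `tcfg$ensembleSeeds` (identical
#' architecture and data; seeds differ in parameter initialization and
#' shuffling), the teacher of the pseudo-labeling stage.
#'
#' @inheritParams trainModel
#' @return List of [RiboModel-class] objects.
#' @export
trainEnsemble <- function(dataset, mcfg = modelConfig(), tcfg = trainConfig(),
                          verbose = FALSE) {
  lapply(tcfg$ensembleSeeds, function(sd) {
    m <- mcfg; m$seed <- as.integer(sd)
    t <- tcfg; t$seed <- as.integer(sd)
    trainModel(dataset, m, t, verbose = verbose)$model
  })
}

checkEnsemble <- function(models) {
  stopifnot(length(models) >= 1L)
  ref <- models[[1]]@config
  for (m in models[-1]) {
    cfg <- m@config
    same <- identical(cfg[c("dModel", "nLayers", "nHeads", "dFf", "backbone")],
                      ref[c("dModel", "nLayers", "nHeads", "dFf", "backbone")])
    if (!same) stop("ensemble members have mismatched architectures",
                    call. = FALSE)
  }
}

#' Ensemble prediction
#'
#' Position-wise arithmetic mean of each head across the members; the DC
#' identity (sum of heads) is preserved by linearity.
#'
#' @param models List of [RiboModel-class] with identical architecture.
#' @param sample A [RiboSample-class] (or anything [predictProfiles()]
#'   accepts, with `condition` supplied).
#' @param condition Condition identifier if `sample` is not a
#'   [RiboSample-class].
#' @return List with `yCtrl`, `yDelta`, `yDc`.
#' @export
ensemblePredict <- function(models, sample, condition = NULL) {
  checkEnsemble(models)
  preds <- lapply(models, predictProfiles, x = sample, condition = condition)
  yc <- rowMeans(do.call(cbind, lapply(preds, `[[`, "yCtrl")))
  yd <- rowMeans(do.call(cbind, lapply(preds, `[[`, "yDelta")))
  list(yCtrl = yc, yDelta = yd, yDc = yc + yd)
}

#' Impute missing training targets with ensemble predictions
#'
#' For every sample in the `train` split, missing DC values are replaced
#' by the ensemble-mean DC prediction; annotated positions are never
#' altered, and the difference target is rederived (positions whose
#' control value is itself missing keep a missing difference). The
#' validation and test splits are untouched.
#'
#' @param dataset A split [RiboDataset-class].
#' @param models The teacher ensemble (list of [RiboModel-class]).
#' @return List with `dataset` (imputed) and `nImputed` (total imputed
#'   positions).
#' @export
imputeMissing <- function(dataset, models) {
  checkEnsemble(models)
  nImputed <- 0L
  out <- lapply(samples(dataset), function(s) {
    if (s@split != "train") return(s)
    imp <- imputeSample(s, models)
    nImputed <<- nImputed + imp$nImputed
    imp$sample
  })
  list(dataset = riboDataset(out), nImputed = nImputed)
}

#' @rdname imputeMissing
#' @param sample A `train`-split [RiboSample-class]; imputing validation
#'   or test samples is refused.
#' @export
imputeSample <- function(sample, models) {
  if (sample@split %in% c("val", "test"))
    stop("refusing to impute a ", sample@split, " sample", call. = FALSE)
  y <- yDc(sample)
  miss <- which(is.na(y))
  if (length(miss) == 0L)
    return(list(sample = sample, nImputed = 0L))
  pr <- ensemblePredict(models, sample)
  y[miss] <- pr$yDc[miss]
  # for CTRL samples the DC profile *is* the control profile
  s2 <- if (condition(sample) == "CTRL")
    riboSample(sample@seq, "CTRL", yCtrl = y, split = sample@split)
  else
    riboSample(sample@seq, condition(sample), yCtrl = yCtrl(sample),
               yDc = y, split = sample@split)
  list(sample = s2, nImputed = length(miss))
}

#' Retrain on the pseudo-labeled dataset
#'
#' Runs a fresh training run (new seed) on the imputed train split,
#' evaluated on the untouched validation/test splits.
#'
#' @param imputedDataset Output `dataset` of [imputeMissing()].
#' @param mcfg,tcfg Model and training configuration for the student
#'   (give a seed different from the teachers').
#' @param verbose Print progress.
#' @return As [trainModel()].
#' @export
retrainPseudolabeled <- function(imputedDataset, mcfg = modelConfig(),
                                 tcfg = trainConfig(), verbose = FALSE) {
  trainModel(imputedDataset, mcfg, tcfg, verbose = verbose)
}
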