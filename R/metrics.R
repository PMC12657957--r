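#' Profile evaluation metrics
#'
#' All metrics operate on the pairwise-annotated mask: positions where
#' either vector is `NA` are excluded.
#'
#' `pcc()` is the Pearson correlation coefficient; with fewer than two
#' annotated pairs or zero variance in either vector the result is
#' undefined and `NA` is returned (never a number). `scc()` is the
#' Spearman correlation (Pearson on midranks, the standard tie
#' extension). `mse()` is the mean squared error. `maape()` is the Mean
#' Arc-tangent Absolute Percentage Error,
#' \deqn{\mathrm{MAAPE} = \frac{100}{N}\sum_i
#'   \arctan\!\left(\frac{|y_i-\hat y_i|}{\max(|y_i|,\epsilon)}\right),}
#' bounded by \eqn{100\pi/2} per position; the \eqn{\epsilon} guard
#' (default 1e-6) keeps zero targets finite.
#'
#' @param y,yHat Numeric vectors of equal length; `NA` = missing.
#' @param eps Denominator guard for `maape()`.
#' @return A single numeric value (or `NA` for degenerate correlations).
#' @name metrics
#' @examples
#' pcc(c(1, 2, 3), c(1, 2, 4))
#' maape(c(1, 1), c(2, 2))  # 100 * atan(1)
NULL

pairMask <- function(y, yHat) which(!is.na(y) & !is.na(yHat))

#' @rdname metrics
#' @export
pcc <- function(y, yHat) {
  m <- pairMask(y, yHat)
  if (length(m) < 2L) return(NA_real_)
  a <- y[m]; b <- yHat[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' @rdname metrics
#' @export
scc <- function(y, yHat) {
  m <- pairMask(y, yHat)
  if (length(m) < 2L) return(NA_real_)
  a <- y[m]; b <- yHat[m]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' @rdname metrics
#' @export
mse <- function(y, yHat) {
  m <- pairMask(y, yHat)
  if (length(m) == 0L) return(NA_real_)
  mean((y[m] - yHat[m])^2)
}

#' @rdname metrics
#' @export
maape <- function(y, yHat, eps = 1e-6) {
  m <- pairMask(y, yHat)
  if (length(m) == 0L) return(NA_real_)
  mean(100 * atan(abs(y[m] - yHat[m]) / pmax(abs(y[m]), eps)))
}

#' Training loss for the dual-headed model
#'
#' The loss combines a Pearson-correlation term for each of the three
#' targets (control, difference, and their sum) with the mean absolute
#' error on the deprivation-condition profile:
#' \deqn{L = \sum_{k \in \{\mathrm{CTRL},\,\Delta,\,\mathrm{DC}\}}
#'   \bigl(1 - r(y_k, \hat y_k)\bigr) +
#'   \mathrm{MAE}(y_{\mathrm{DC}}, \hat y_{\mathrm{DC}}).}
#' Every term is computed on the pairwise-annotated mask. A correlation
#' term whose target or prediction has zero variance (e.g. the constant
#' all-zero difference target of a control sample) is undefined and
#' contributes 0 to the sum, so a perfect prediction always attains
#' `L = 0`.
#'
#' @param sample A [RiboSample-class] carrying the targets.
#' @param yHatCtrl,yHatDelta Numeric predictions from the two heads; the
#'   DC prediction is their sum by construction.
#' @return The scalar loss.
#' @export
computeLoss <- function(sample, yHatCtrl, yHatDelta) {
  lossWithGrad(sample, yHatCtrl, yHatDelta)$loss
}

# Pearson term value + gradient wrt yHat on the mask.
# r = <t, c> / (|t| |c|) with t, c the centred target/prediction;
# dr/dyhat = t/(|t||c|) - r c/|c|^2 (centred inputs absorb the projector).
pccTermGrad <- function(y, yHat) {
  m <- pairMask(y, yHat)
  g <- numeric(length(yHat))
  if (length(m) < 2L) return(list(r = NA_real_, grad = g))
  t <- y[m] - mean(y[m])
  c <- yHat[m] - mean(yHat[m])
  nt <- sqrt(sum(t^2)); nc <- sqrt(sum(c^2))
  if (nt == 0 || nc == 0) return(list(r = NA_real_, grad = g))
  r <- sum(t * c) / (nt * nc)
  gm <- t / (nt * nc) - r * c / nc^2
  g[m] <- gm
  list(r = r, grad = g)
}

# loss + analytic gradients wrt the two head outputs
lossWithGrad <- function(sample, yHatCtrl, yHatDelta) {
  yHatDc <- yHatCtrl + yHatDelta
  tC <- pccTermGrad(yCtrl(sample), yHatCtrl)
  tD <- pccTermGrad(yDelta(sample), yHatDelta)
  tS <- pccTermGrad(yDc(sample), yHatDc)
  loss <- 0
  gCtrl <- numeric(length(yHatCtrl))
  gDelta <- numeric(length(yHatDelta))
  if (!is.na(tC$r)) { loss <- loss + (1 - tC$r); gCtrl <- gCtrl - tC$grad }
  if (!is.na(tD$r)) { loss <- loss + (1 - tD$r); gDelta <- gDelta - tD$grad }
  if (!is.na(tS$r)) {
    loss <- loss + (1 - tS$r)
    gCtrl <- gCtrl - tS$grad
    gDelta <- gDelta - tS$grad
  }
  m <- pairMask(yDc(sample), yHatDc)
  if (length(m) > 0L) {
    d <- yHatDc[m] - yDc(sample)[m]
    loss <- loss + mean(abs(d))
    gm <- sign(d) / length(m)
    gCtrl[m] <- gCtrl[m] + gm
    gDelta[m] <- gDelta[m] + gm
  }
  list(loss = loss, gCtrl = gCtrl, gDelta = gDelta)
}
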