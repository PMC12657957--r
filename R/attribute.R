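#' Integrated-gradients codon attribution
#'
#' Computes the integrated-gradients attribution of one head's scalar
#' output at a chosen A-site with respect to the combined per-position
#' input embeddings, along the straight path from the all-zero embedding
#' baseline. The line integral is evaluated with a midpoint rule under
#' the substitution `alpha = t^10`, which concentrates the `steps`
#' quadrature points near the baseline: every layer-normalization stage
#' in the backbone pushes the region where the output actually changes
#' another few decades closer to `alpha = 0`, so uniform (or mildly
#' stretched) sampling misses it entirely. The `[n, D]`
#' attribution is summed over the embedding axis to give one value per
#' codon. By the completeness axiom the values sum to
#' `f(x) - f(baseline)`; the realized completeness gap is returned for
#' diagnostics.
#'
#' @param model A [RiboModel-class].
#' @param sample A [RiboSample-class] (or [CodonSequence-class] with
#'   `condition` given).
#' @param aSite 0-based output position.
#' @param head `"ctrl"` or `"delta"`.
#' @param steps Number of path points (>= 8; default 64).
#' @param condition Condition if `sample` is a bare sequence.
#' @return An [AttributionVector-class]; attributes `fx`, `f0`, and
#'   `completenessGap` (relative) are attached to `values`' environment
#'   via the `diagnostics` attribute.
#' @export
integratedGradients <- function(model, sample, aSite, head = c("delta", "ctrl"),
                                steps = 64L, condition = NULL) {
  head <- match.arg(head)
  if (is(sample, "RiboSample")) {
    condition <- condition(sample)
    seq <- sample@seq
  } else seq <- sample
  n <- length(seq)
  if (aSite < 0L || aSite >= n) stop("aSite out of range", call. = FALSE)
  if (steps < 8L) stop("steps must be >= 8", call. = FALSE)
  X <- embedInput(model, codons(seq), condition)
  headOut <- function(cache)
    if (head == "ctrl") cache$yCtrl[aSite + 1L] else cache$yDelta[aSite + 1L]
  gSel <- numeric(n); gSel[aSite + 1L] <- 1
  zero <- numeric(n)
  gradSum <- matrix(0, n, ncol(X))
  tt <- (seq_len(steps) - 0.5) / steps
  alphas <- tt^10
  wgts <- 10 * tt^9 / steps      # d(alpha)/dt / steps
  wgts <- wgts / sum(wgts)       # exact unit mass: linear f stays exact
  for (k in seq_len(steps)) {
    alpha <- alphas[k]
    wgt <- wgts[k]
    cache <- nnForward(model, alpha * X)
    res <- if (head == "ctrl") nnBackward(model, cache, gSel, zero)
           else nnBackward(model, cache, zero, gSel)
    if (any(!is.finite(res$dX)))
      stop("non-finite gradient at path point ", k, " (gene ", geneId(seq),
           ", a-site ", aSite, ")", call. = FALSE)
    gradSum <- gradSum + wgt * res$dX
  }
  attrMat <- X * gradSum
  values <- rowSums(attrMat)
  fx <- headOut(nnForward(model, X))
  f0 <- headOut(nnForward(model, 0 * X))
  gap <- abs(sum(values) - (fx - f0)) / max(abs(fx - f0), 1e-12)
  av <- new("AttributionVector", geneId = geneId(seq),
            aSite = as.integer(aSite), head = head, values = values)
  attr(av@values, "diagnostics") <- list(fx = fx, f0 = f0,
                                         completenessGap = gap)
  av
}

popSd <- function(x) sqrt(mean((x - mean(x))^2))

#' The profile that defines stalling for a sample
#'
#' Control samples are assessed on their footprint profile, deprivation
#' samples on the difference profile.
#'
#' @param sample A [RiboSample-class].
#' @return Numeric profile.
#' @export
stallingProfile <- function(sample) {
  if (condition(sample) == "CTRL") yCtrl(sample) else yDelta(sample)
}

#' Peak and trough detection
#'
#' Peaks are annotated positions whose value is strictly greater than
#' the profile mean plus one standard deviation (population sd,
#' denominator n, over annotated values); troughs are strictly below
#' mean minus one sd. Missing positions are never peaks or troughs; a
#' constant profile has neither.
#'
#' @param profile Numeric profile (`NA` = missing), >= 2 annotated
#'   positions.
#' @return `findPeaks()`: list with `peaks`, `troughs` (0-based
#'   positions), `mean`, `sd`. `findTroughs()`: 0-based trough
#'   positions.
#' @export
#' @examples
#' findPeaks(c(0, 0, 0, 0, 10))$peaks  # position 4
findPeaks <- function(profile) {
  ann <- which(!is.na(profile))
  if (length(ann) < 2L) stop("need >= 2 annotated positions", call. = FALSE)
  m <- mean(profile[ann]); s <- popSd(profile[ann])
  list(peaks = ann[profile[ann] > m + s] - 1L,
       troughs = ann[profile[ann] < m - s] - 1L,
       mean = m, sd = s)
}

#' @rdname findPeaks
#' @export
findTroughs <- function(profile) findPeaks(profile)$troughs

#' Significance window around an A-site
#'
#' The region from 10 codons upstream to 10 codons downstream of the
#' A-site, truncated at the CDS bounds; an untruncated window spans 21
#' codons.
#'
#' @param aSite 0-based A-site position.
#' @param n Gene length in codons.
#' @param halfWidth Codons on each side (default 10).
#' @return Integer vector of 0-based positions (inclusive range).
#' @export
significanceWindow <- function(aSite, n, halfWidth = 10L) {
  seq.int(max(0L, aSite - halfWidth), min(n - 1L, aSite + halfWidth))
}

# max-normalize attribution values within the SW (signs preserved)
swNormalized <- function(attr, halfWidth = 10L) {
  n <- length(attr@values)
  sw <- significanceWindow(attr@aSite, n, halfWidth)
  v <- attr@values[sw + 1L]
  mx <- max(abs(v))
  if (mx == 0) mx <- 1
  list(sw = sw, norm = v / mx)
}

#' Top-k salient positions within the significance window
#'
#' Attributions are max-normalized within the window (divided by the
#' maximum absolute value, signs preserved) and the `k` positions with
#' the largest signed value are reported relative to the A-site (A-site
#' = 0, P-site = -1). If the window holds fewer than `k` positions all
#' are returned with a `truncated` flag.
#'
#' @param attr An [AttributionVector-class].
#' @param k Number of positions (default 5).
#' @param halfWidth Window half-width.
#' @return List with `positions` (relative, ranked) and `truncated`.
#' @export
topSalientPositions <- function(attr, k = 5L, halfWidth = 10L) {
  swn <- swNormalized(attr, halfWidth)
  rel <- swn$sw - attr@aSite
  ord <- order(-swn$norm, abs(rel), rel)
  kk <- min(k, length(rel))
  list(positions = rel[ord[seq_len(kk)]], truncated = kk < k)
}

#' Codon-wise mean attribution over peak significance windows
#'
#' For every codon, the mean of the window-max-normalized attribution
#' values over all occurrences of that codon inside the analyzed
#' significance windows. Positive values mark codons whose presence
#' increases the expected (difference) count at the A-site, i.e.
#' stalling-promoting codons. Codons never observed get `NA`.
#'
#' @param attrs List of [AttributionVector-class].
#' @param seqs Named list of [CodonSequence-class] covering the
#'   attributions' genes.
#' @param halfWidth Window half-width.
#' @return Named numeric vector over the 64 codons.
#' @export
codonwiseAttributionSummary <- function(attrs, seqs, halfWidth = 10L) {
  tot <- stats::setNames(numeric(64L), allCodons())
  cnt <- stats::setNames(numeric(64L), allCodons())
  for (a in attrs) {
    cs <- codons(seqs[[a@geneId]])
    swn <- swNormalized(a, halfWidth)
    cod <- cs[swn$sw + 1L]
    agg <- tapply(swn$norm, cod, sum)
    tot[names(agg)] <- tot[names(agg)] + agg
    nn <- table(cod)
    cnt[names(nn)] <- cnt[names(nn)] + nn
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Per-codon mean observed signal
#'
#' Mean of the stalling profile (footprint counts for control,
#' difference counts for deprivations) over all annotated occurrences of
#' each codon.
#'
#' @param dataset A [RiboDataset-class].
#' @param cond Condition to aggregate.
#' @return Named numeric vector over the 64 codons (`NA` where never
#'   observed).
#' @export
meanCodonSignal <- function(dataset, cond) {
  tot <- stats::setNames(numeric(64L), allCodons())
  cnt <- stats::setNames(numeric(64L), allCodons())
  for (s in samples(dataset)) {
    if (condition(s) != cond) next
    y <- stallingProfile(s)
    ann <- !is.na(y)
    agg <- tapply(y[ann], codons(s)[ann], sum)
    tot[names(agg)] <- tot[names(agg)] + agg
    nn <- table(codons(s)[ann])
    cnt[names(nn)] <- cnt[names(nn)] + nn
  }
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Correlation between codon-wise attributions and observed counts
#'
#' Pearson correlation across codons between the mean attribution and
#' the mean observed (difference) count; requires at least 3 codons with
#' both summaries.
#'
#' @param attrMeans Output of [codonwiseAttributionSummary()].
#' @param countMeans Output of [meanCodonSignal()].
#' @return Pearson correlation (NA if degenerate).
#' @export
attributionCountCorrelation <- function(attrMeans, countMeans) {
  ok <- !is.na(attrMeans) & !is.na(countMeans)
  if (sum(ok) < 3L) stop("need >= 3 codons with both summaries",
                         call. = FALSE)
  pcc(attrMeans[ok], countMeans[ok])
}

#' Attribution analysis over the peaks of a dataset
#'
#' Finds stalling peaks (on the profile [stallingProfile()] defines for
#' the sample's condition), computes integrated-gradients attributions
#' at each peak A-site (control head for control samples, difference
#' head otherwise), and returns the attribution vectors.
#'
#' @param model A [RiboModel-class].
#' @param dataset A [RiboDataset-class].
#' @param cond Condition to analyze.
#' @param maxPeaks Cap on the number of analyzed peaks (first come, in
#'   dataset order), to bound runtime.
#' @param steps Integrated-gradients path points.
#' @return List of [AttributionVector-class].
#' @export
peakAttributions <- function(model, dataset, cond, maxPeaks = 100L,
                             steps = 32L) {
  head <- if (cond == "CTRL") "ctrl" else "delta"
  out <- list()
  for (s in samples(dataset)) {
    if (condition(s) != cond) next
    pk <- findPeaks(stallingProfile(s))$peaks
    for (p in pk) {
      if (length(out) >= maxPeaks) return(out)
      out[[length(out) + 1L]] <-
        integratedGradients(model, s, p, head = head, steps = steps)
    }
  }
  out
}
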