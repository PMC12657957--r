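#' Pre-processing configuration
#'
#' Defaults encode the pipeline's quality rules: genes with a run of more
#' than 20 consecutive observed zero counts, longer than 2000 codons, or
#' with coverage of at most 30% are discarded; the coverage-sorted split
#' reserves 5% of samples for validation and 20% for testing.
#'
#' @param maxZeroRun Longest tolerated run of consecutive zero-valued
#'   annotated positions (codons).
#' @param maxLen Maximum gene length (codons).
#' @param minCoverage Coverage threshold; kept genes need coverage
#'   strictly greater than this fraction.
#' @param valFrac,testFrac Sample-count quotas of the validation and test
#'   splits.
#' @return A list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(maxZeroRun = 20L, maxLen = 2000L,
                             minCoverage = 0.30, valFrac = 0.05,
                             testFrac = 0.20) {
  stopifnot(minCoverage > 0, minCoverage < 1, valFrac + testFrac < 1)
  structure(list(maxZeroRun = as.integer(maxZeroRun),
                 maxLen = as.integer(maxLen), minCoverage = minCoverage,
                 valFrac = valFrac, testFrac = testFrac),
            class = "PreprocessConfig")
}

#' Merge replicate profiles
#'
#' Each replicate is first scaled to an equal library-depth contribution
#' (divided by its own mean over annotated positions); the merged value at
#' a position is then the mean over replicates annotated there, so the
#' merged annotation is the union of the replicate annotations. An
#' all-missing replicate is dropped with a warning; an all-zero replicate
#' is kept unscaled (its mean is zero, so scaling is undefined and a
#' no-op is the neutral choice).
#'
#' @param profiles List of numeric profiles of equal length (`NA` =
#'   missing).
#' @return The merged numeric profile.
#' @export
#' @examples
#' mergeReplicates(list(c(2, NA), c(NA, 4)))
mergeReplicates <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  n <- length(profiles[[1]])
  stopifnot(all(vapply(profiles, length, integer(1)) == n))
  keep <- vapply(profiles, function(p) any(!is.na(p)), logical(1))
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " replicate(s) with no annotated positions")
    profiles <- profiles[keep]
  }
  if (length(profiles) == 0L)
    stop("no replicate has annotated positions", call. = FALSE)
  scaled <- lapply(profiles, function(p) {
    m <- mean(p, na.rm = TRUE)
    if (m > 0) p / m else p
  })
  mat <- do.call(rbind, scaled)
  cnt <- colSums(!is.na(mat))
  out <- colSums(mat, na.rm = TRUE) / pmax(cnt, 1L)
  out[cnt == 0L] <- NA_real_
  out
}

#' Merge replicate-level samples of a dataset
#'
#' Groups samples by (gene, condition) and applies [mergeReplicates()] to
#' their profiles, yielding one merged sample per group.
#'
#' @param dataset A [RiboDataset-class] of replicate-level samples (as
#'   produced by [readProfiles()]).
#' @return A [RiboDataset-class] with one sample per (gene, condition).
#' @export
mergeDatasetReplicates <- function(dataset) {
  ss <- samples(dataset)
  key <- paste(vapply(ss, geneId, character(1)),
               vapply(ss, condition, character(1)), sep = "\r")
  merged <- lapply(split(ss, key), function(grp) {
    y <- mergeReplicates(lapply(grp, yDc))
    riboSample(grp[[1]]@seq, condition(grp[[1]]), yDc = y)
  })
  riboDataset(unname(merged))
}

#' Attach control profiles and derive difference targets
#'
#' For every gene, the merged `CTRL` sample's profile becomes the
#' `yCtrl` of all that gene's samples; `yDelta` is recomputed. Genes
#' without a `CTRL` sample are dropped with a warning.
#'
#' @param dataset A merged [RiboDataset-class] (one sample per
#'   gene/condition).
#' @return A [RiboDataset-class] with paired control/DC/difference
#'   profiles.
#' @export
pairControls <- function(dataset) {
  ss <- samples(dataset)
  isCtrl <- vapply(ss, condition, character(1)) == "CTRL"
  ctrls <- ss[isCtrl]
  names(ctrls) <- vapply(ctrls, geneId, character(1))
  out <- list()
  dropped <- character(0)
  for (s in ss) {
    ctl <- ctrls[[geneId(s)]]
    if (is.null(ctl)) { dropped <- c(dropped, geneId(s)); next }
    out[[length(out) + 1L]] <- riboSample(s@seq, condition(s),
                                          yCtrl = yDc(ctl), yDc = yDc(s),
                                          split = s@split)
  }
  if (length(dropped))
    warning("dropped ", length(dropped),
            " sample(s) of gene(s) without a CTRL profile: ",
            paste(unique(dropped), collapse = ", "))
  riboDataset(out)
}

#' Normalize a profile
#'
#' Divides by the mean over annotated positions and applies
#' `log(x + 1)`: `out[i] = log(p[i] / mean(p) + 1)`. Missing positions
#' are preserved. The result is invariant to rescaling the raw profile.
#'
#' @param p Numeric profile (`NA` = missing), at least one annotated
#'   finite value.
#' @return The normalized profile.
#' @export
#' @examples
#' normalizeProfile(c(0, 2))  # log(0/1 + 1), log(2/1 + 1)
normalizeProfile <- function(p) {
  ann <- !is.na(p)
  if (!any(ann)) stop("cannot normalize an all-missing profile", call. = FALSE)
  m <- mean(p[ann])
  if (!is.finite(m) || m <= 0)
    stop("profile mean over annotated positions must be positive and finite",
         call. = FALSE)
  out <- p
  out[ann] <- log(p[ann] / m + 1)
  out
}

#' Normalize all profiles of a dataset
#'
#' Applies [normalizeProfile()] to `yCtrl` and `yDc` of each sample and
#' rederives `yDelta` from the normalized profiles.
#'
#' @param dataset A paired [RiboDataset-class] (see [pairControls()]).
#' @return The normalized [RiboDataset-class].
#' @export
normalizeDataset <- function(dataset) {
  riboDataset(lapply(samples(dataset), function(s) {
    riboSample(s@seq, condition(s),
               yCtrl = normalizeProfile(yCtrl(s)),
               yDc = normalizeProfile(yDc(s)), split = s@split)
  }))
}

#' Profile coverage
#'
#' The ratio of annotated positions with non-zero values to the total
#' number of annotated positions.
#'
#' @param p Numeric profile (`NA` = missing), at least one annotated
#'   position.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' computeCoverage(c(1, 0, NA, 2))  # 2/3
computeCoverage <- function(p) {
  ann <- p[!is.na(p)]
  if (length(ann) == 0L) stop("profile has no annotated positions",
                              call. = FALSE)
  mean(ann != 0)
}

#' Quality-filter one sample
#'
#' A sample is rejected iff (a) its profile contains a run of
#' consecutive zero-valued annotated positions strictly longer than
#' `maxZeroRun` (missing positions break a run: the filter is about
#' observed zeros), or (b) the gene exceeds `maxLen` codons, or (c) its
#' coverage is not strictly greater than `minCoverage`. The reason names
#' the first failing rule in that fixed order, so the decision is
#' independent of evaluation order.
#'
#' @param sample A [RiboSample-class] (filters look at `yDc`).
#' @param cfg A [preprocessConfig()].
#' @return List with `keep` (logical) and `reason` (`"pass"`,
#'   `"zero_run"`, `"length"`, or `"coverage"`).
#' @export
filterSample <- function(sample, cfg = preprocessConfig()) {
  y <- yDc(sample)
  ann <- !is.na(y)
  zr <- 0L
  if (any(ann)) {
    runs <- rle(ifelse(ann, y == 0, NA))
    zero <- !is.na(runs$values) & runs$values
    if (any(zero)) zr <- max(runs$lengths[zero])
  }
  failZero <- zr > cfg$maxZeroRun
  failLen <- nCodons(sample) > cfg$maxLen
  failCov <- computeCoverage(y) <= cfg$minCoverage
  reason <- if (failZero) "zero_run" else if (failLen) "length"
            else if (failCov) "coverage" else "pass"
  list(keep = reason == "pass", reason = reason)
}

#' Apply the three quality filters to a dataset
#'
#' @param dataset A [RiboDataset-class].
#' @param cfg A [preprocessConfig()].
#' @return List with `dataset` (kept samples) and `report` (data.frame:
#'   gene_id, condition, decision, reason).
#' @export
applyFilters <- function(dataset, cfg = preprocessConfig()) {
  ss <- samples(dataset)
  res <- lapply(ss, filterSample, cfg = cfg)
  keep <- vapply(res, `[[`, logical(1), "keep")
  report <- data.frame(
    gene_id = vapply(ss, geneId, character(1)),
    condition = vapply(ss, condition, character(1)),
    decision = ifelse(keep, "keep", "reject"),
    reason = vapply(res, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  list(dataset = riboDataset(ss[keep]), report = report)
}

#' Coverage-sorted train/validation/test split
#'
#' Genes are sorted by coverage (the maximum over the gene's samples,
#' computed on `yDc`) in descending order, ties broken by gene id
#' ascending. Walking that list, genes are assigned in the repeating
#' order train, val, test; once the validation (resp. test) split holds
#' its sample-count quota (`valFrac`/`testFrac` of the pre-split sample
#' count) it is skipped, and the remainder goes to training. All samples
#' of a gene share its split. Deterministic.
#'
#' @param dataset A [RiboDataset-class].
#' @param cfg A [preprocessConfig()].
#' @return List with `dataset` (split tags assigned) and `manifest`
#'   (data.frame: gene_id, split, coverage).
#' @export
splitDataset <- function(dataset, cfg = preprocessConfig()) {
  ss <- samples(dataset)
  gid <- vapply(ss, geneId, character(1))
  cov <- vapply(ss, function(s) computeCoverage(yDc(s)), numeric(1))
  geneCov <- tapply(cov, gid, max)
  geneN <- tapply(gid, gid, length)
  ord <- order(-geneCov, names(geneCov))
  genes <- names(geneCov)[ord]
  total <- length(ss)
  quotaVal <- cfg$valFrac * total
  quotaTest <- cfg$testFrac * total
  cycle <- c("train", "val", "test")
  slot <- 0L
  nVal <- 0; nTest <- 0
  assign <- character(length(genes)); names(assign) <- genes
  for (g in genes) {
    repeat {
      target <- cycle[slot %% 3L + 1L]
      if (target == "val" && nVal >= quotaVal) { slot <- slot + 1L; next }
      if (target == "test" && nTest >= quotaTest) { slot <- slot + 1L; next }
      break
    }
    assign[g] <- target
    k <- geneN[[g]]
    if (target == "val") nVal <- nVal + k
    if (target == "test") nTest <- nTest + k
    slot <- slot + 1L
  }
  if (nVal < quotaVal || nTest < quotaTest)
    warning("too few genes to fill the val/test quotas; quotas left short")
  out <- lapply(ss, function(s) {
    s@split <- assign[[geneId(s)]]
    s
  })
  manifest <- data.frame(gene_id = genes, split = unname(assign[genes]),
                         coverage = unname(geneCov[genes]),
                         stringsAsFactors = FALSE)
  list(dataset = riboDataset(out), manifest = manifest)
}

#' Run the full pre-processing pipeline
#'
#' Convenience wrapper: normalization ([normalizeDataset()]), the three
#' quality filters ([applyFilters()]), and the coverage-sorted split
#' ([splitDataset()]). Input samples must already be merged and
#' control-paired (as produced by [simulateDataset()] or by
#' [mergeDatasetReplicates()] + [pairControls()]).
#'
#' @param dataset A paired [RiboDataset-class] of raw-count samples.
#' @param cfg A [preprocessConfig()].
#' @return List with `dataset` (normalized, filtered, split),
#'   `filterReport`, and `manifest`.
#' @export
preprocessPipeline <- function(dataset, cfg = preprocessConfig()) {
  norm <- normalizeDataset(dataset)
  filt <- applyFilters(norm, cfg)
  spl <- splitDataset(filt$dataset, cfg)
  list(dataset = spl$dataset, filterReport = filt$report,
       manifest = spl$manifest)
}

#' Likelihood-ratio test for a deprivation response
#'
#' Tests, for one deprived sample, whether annotated difference-profile
#' values at positions whose A-site codon decodes the deprived amino
#' acid(s) have a different mean than the remaining positions. A
#' Gaussian working likelihood with a shared maximum-likelihood variance
#' is used: the null fits one common mean, the alternative one mean per
#' group; the statistic `2 * (loglik_alt - loglik_null) = n *
#' log(s0/s1)` is referred to a chi-square distribution with 1 degree of
#' freedom.
#'
#' @param sample A non-control [RiboSample-class] with a normalized
#'   difference profile; at least 3 annotated deprived-codon positions
#'   and 3 others are required.
#' @return List with `statistic`, `p.value`, `nDeprived`, `nOther`.
#' @export
deprivationLrt <- function(sample) {
  if (condition(sample) == "CTRL")
    stop("the deprivation test is undefined for CTRL samples", call. = FALSE)
  d <- yDelta(sample)
  dep <- codons(sample) %in% deprivedCodons(condition(sample))
  ann <- !is.na(d)
  x1 <- d[ann & dep]; x0 <- d[ann & !dep]
  if (length(x1) < 3L || length(x0) < 3L)
    stop("need >= 3 annotated deprived and other positions", call. = FALSE)
  x <- c(x1, x0); n <- length(x)
  s0 <- mean((x - mean(x))^2)
  s1 <- (sum((x1 - mean(x1))^2) + sum((x0 - mean(x0))^2)) / n
  stat <- if (s1 <= 0 || s0 <= 0) 0 else max(0, n * log(s0 / s1))
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       nDeprived = length(x1), nOther = length(x0))
}

#' Select the interpretability gene set
#'
#' Runs [deprivationLrt()] over every non-control sample of a dataset
#' and tags samples passing the (BH-adjusted) significance threshold
#' with the `interp` split if they are not already in train/val/test.
#'
#' @param dataset A normalized [RiboDataset-class].
#' @param alpha BH-adjusted significance threshold.
#' @return data.frame with gene_id, condition, statistic, p, q and the
#'   selection flag.
#' @export
selectInterpretabilitySet <- function(dataset, alpha = 0.05) {
  ss <- samples(dataset)
  rows <- list()
  for (s in ss) {
    if (condition(s) == "CTRL") next
    res <- tryCatch(deprivationLrt(s), error = function(e) NULL)
    if (is.null(res)) {
      warning("skipping ", geneId(s), "/", condition(s), ": ",
              "insufficient annotated positions for the deprivation test")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = geneId(s), condition = condition(s),
      statistic = res$statistic, p = res$p.value, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(data.frame())
  df$q <- stats::p.adjust(df$p, method = "BH")
  df$selected <- df$q <= alpha
  df
}
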