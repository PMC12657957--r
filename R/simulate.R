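#' Synthetic ribosome-profiling configuration
#'
#' The generator emulates per-gene footprint profiles with
#' codon-dependent dwell times, condition-specific stalling on deprived
#' codons, multiplicative lognormal noise, geometric runs of missing
#' values, per-sample sequencing-depth variation, and control-only
#' end-bias artifacts at the footprint-edge offsets -5 and +3. Every
#' planted parameter is retrievable via [groundTruth()] so attribution
#' and motif recovery can be scored against it.
#'
#' The default study conditions: 200 genes of 150-400 codons; A-site
#' log-dwell effects of +1.0 for the four VAL codons, +0.8 for the three
#' ILE codons (with an additional +0.4 long-range effect from ILE codons
#' four positions upstream of the A-site), and +0.3 for the six LEU
#' codons; combined deprivations take the union of their components'
#' effects. Base log-dwell times are drawn once per configuration from
#' N(0, 0.5); multiplicative noise has log-sd 0.3; 10% of positions are
#' missing in geometric runs of mean length 3.
#'
#' @param nGenes Number of genes.
#' @param lenRange Gene length range in codons (uniform).
#' @param baseDwellSd SD of the per-codon base log-dwell draw.
#' @param noiseSd Log-sd of the multiplicative observation noise.
#' @param missingRate Expected fraction of missing positions.
#' @param missingRunMean Mean geometric run length of missing stretches.
#' @param depthSd Log-sd of the per-sample depth factor.
#' @param valEffect,ileEffect,leuEffect A-site log-dwell increments on
#'   the deprived codons of the single deprivations.
#' @param ileUpstreamOffset,ileUpstreamEffect Long-range ILE effect: a
#'   deprived ILE codon at this offset relative to the A-site adds this
#'   log-dwell increment.
#' @param contextKernel Named list mapping offset (as character, e.g.
#'   `"-1"`) to a named numeric vector of codon log-dwell increments
#'   contributed by the codon at that offset.
#' @param endBias Named numeric vector of control-only artifact
#'   amplitudes at footprint-edge offsets (names are offsets).
#' @param seed Seed; the base dwell draw and all profile noise descend
#'   from it.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nGenes = 200L, lenRange = c(150L, 400L),
                             baseDwellSd = 0.5, noiseSd = 0.3,
                             missingRate = 0.10, missingRunMean = 3,
                             depthSd = 0.3, valEffect = 1.0,
                             ileEffect = 0.8, ileUpstreamOffset = -4L,
                             ileUpstreamEffect = 0.4, leuEffect = 0.3,
                             contextKernel = list(
                               `-1` = c(CCA = 0.3, CCG = 0.3),
                               `1` = c(GAA = 0.2)),
                             endBias = c(`-5` = 0.2, `3` = 0.15),
                             seed = 2024L) {
  stopifnot(missingRate >= 0, missingRate <= 1, lenRange[1] >= 30L)
  set.seed(seed)
  baseDwell <- stats::setNames(stats::rnorm(64L, 0, baseDwellSd), allCodons())
  baseDwell[c("TAA", "TAG", "TGA")] <- 0  # stops never occur internally
  condEffects <- list(
    CTRL = list(asite = numeric(0), offsets = list()),
    LEU = list(asite = stats::setNames(rep(leuEffect, 6L),
                                       deprivedCodons("LEU")),
               offsets = list()),
    ILE = list(asite = stats::setNames(rep(ileEffect, 3L),
                                       deprivedCodons("ILE")),
               offsets = stats::setNames(
                 list(stats::setNames(rep(ileUpstreamEffect, 3L),
                                      deprivedCodons("ILE"))),
                 as.character(ileUpstreamOffset))),
    VAL = list(asite = stats::setNames(rep(valEffect, 4L),
                                       deprivedCodons("VAL")),
               offsets = list()))
  combine <- function(a, b) {
    as <- c(a$asite, b$asite)
    offs <- a$offsets
    for (k in names(b$offsets))
      offs[[k]] <- c(offs[[k]], b$offsets[[k]])
    list(asite = as, offsets = offs)
  }
  condEffects$LEU_ILE <- combine(condEffects$LEU, condEffects$ILE)
  condEffects$LEU_ILE_VAL <- combine(condEffects$LEU_ILE, condEffects$VAL)
  structure(list(nGenes = as.integer(nGenes), lenRange = as.integer(lenRange),
                 baseDwell = baseDwell, contextKernel = contextKernel,
                 condEffects = condEffects, noiseSd = noiseSd,
                 missingRate = missingRate, missingRunMean = missingRunMean,
                 depthSd = depthSd, endBias = endBias, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Planted ground truth of a simulation
#'
#' @param cfg A [simulationConfig()].
#' @return Per condition: the deprived codon set, the planted A-site
#'   effect sizes, and any planted offset effects. The oracle against
#'   which attribution and motif recovery are scored.
#' @export
groundTruth <- function(cfg) {
  lapply(cfg$condEffects, function(e) {
    list(deprivedCodons = names(e$asite), effects = e$asite,
         offsets = e$offsets)
  })
}

#' Generate one random in-frame CDS
#'
#' Starts with ATG, contains no internal stop codons, samples the rest
#' uniformly from the sense codons (draws come from R's global RNG, so
#' seed outside for reproducibility).
#'
#' @param cfg A [simulationConfig()].
#' @param geneId Gene identifier.
#' @return A [CodonSequence-class].
#' @export
generateGene <- function(cfg, geneId = "g1") {
  n <- sample(cfg$lenRange[1]:cfg$lenRange[2], 1L)
  body <- sample(senseCodons(), n - 1L, replace = TRUE)
  codonSequence(geneId, c("ATG", body))
}

# expected (noise-free) log-dwell profile for one gene in one condition
expectedLogDwell <- function(gene, cfg, condition) {
  cs <- codons(gene)
  n <- length(cs)
  ld <- cfg$baseDwell[cs]
  for (off in names(cfg$contextKernel)) {
    o <- as.integer(off)
    eff <- cfg$contextKernel[[off]]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    contrib <- eff[cs[src[ok]]]
    contrib[is.na(contrib)] <- 0
    ld[ok] <- ld[ok] + contrib
  }
  ce <- cfg$condEffects[[condition]]
  if (length(ce$asite)) {
    contrib <- ce$asite[cs]
    contrib[is.na(contrib)] <- 0
    ld <- ld + contrib
  }
  for (off in names(ce$offsets)) {
    o <- as.integer(off)
    eff <- ce$offsets[[off]]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    contrib <- eff[cs[src[ok]]]
    contrib[is.na(contrib)] <- 0
    ld[ok] <- ld[ok] + contrib
  }
  unname(ld)
}

# control-only footprint-edge artifact: GC-dependent contribution of the
# codons at the configured offsets from the A-site
endBiasLog <- function(gene, cfg) {
  cs <- codons(gene)
  n <- length(cs)
  gc <- vapply(strsplit(cs, ""), function(x) mean(x %in% c("G", "C")),
               numeric(1))
  out <- numeric(n)
  for (off in names(cfg$endBias)) {
    o <- as.integer(off)
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + cfg$endBias[[off]] * (gc[src[ok]] - 0.5)
  }
  out
}

maskMissing <- function(y, cfg) {
  if (cfg$missingRate <= 0) return(y)
  n <- length(y)
  pStart <- cfg$missingRate / cfg$missingRunMean
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < pStart) {
      len <- 1L + stats::rgeom(1, 1 / cfg$missingRunMean)
      y[i:min(n, i + len - 1L)] <- NA_real_
      i <- i + len
    }
    i <- i + 1L
  }
  y
}

#' Simulate profiles for one gene under all six conditions
#'
#' The expected control count at position i is
#' `exp(base dwell + context-kernel terms + end-bias terms)`; the
#' expected deprivation count additionally multiplies in the planted
#' condition effects. Observations are expected counts times a
#' per-sample depth factor and position-wise lognormal noise, with
#' missing runs inserted afterwards. The control profile is generated
#' once and shared across all of the gene's samples.
#'
#' @param gene A [CodonSequence-class].
#' @param cfg A [simulationConfig()].
#' @param noise,missing Set `FALSE` to disable observation noise (and
#'   depth variation) or missingness, e.g. for closed-form checks.
#' @return List of six [RiboSample-class] objects (raw count scale), one
#'   per condition.
#' @export
simulateProfiles <- function(gene, cfg, noise = TRUE, missing = TRUE) {
  n <- length(gene)
  eb <- endBiasLog(gene, cfg)
  expectCtrl <- exp(expectedLogDwell(gene, cfg, "CTRL") + eb)
  obs <- function(expect) {
    y <- expect
    if (noise) {
      depth <- exp(stats::rnorm(1, 0, cfg$depthSd))
      y <- y * depth * exp(stats::rnorm(n, 0, cfg$noiseSd))
    }
    if (missing) y <- maskMissing(y, cfg)
    y
  }
  yCtrlObs <- obs(expectCtrl)
  out <- vector("list", length(conditionIds()))
  names(out) <- conditionIds()
  for (cond in conditionIds()) {
    if (cond == "CTRL") {
      out[[cond]] <- riboSample(gene, "CTRL", yCtrl = yCtrlObs)
    } else {
      expectDc <- exp(expectedLogDwell(gene, cfg, cond) + eb)
      out[[cond]] <- riboSample(gene, cond, yCtrl = yCtrlObs,
                                yDc = obs(expectDc))
    }
  }
  out
}

#' Simulate a full dataset
#'
#' Generates `nGenes` genes and their six-condition profiles under a
#' single seeded RNG stream (genes in order, then per gene the control
#' draw followed by the five deprivation draws), so every artifact is
#' reproducible from the configuration seed.
#'
#' @param cfg A [simulationConfig()].
#' @param noise,missing Passed to [simulateProfiles()].
#' @return A [RiboDataset-class] of raw-count samples.
#' @export
simulateDataset <- function(cfg = simulationConfig(), noise = TRUE,
                            missing = TRUE) {
  set.seed(cfg$seed + 1L)
  out <- list()
  for (g in seq_len(cfg$nGenes)) {
    gene <- generateGene(cfg, sprintf("g%04d", g))
    out <- c(out, unname(simulateProfiles(gene, cfg, noise, missing)))
  }
  riboDataset(out)
}
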