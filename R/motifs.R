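#' MutationWindow: a significance window prepared for mutation search
#'
#' A contiguous CDS slice containing the A-site (21 codons when
#' untruncated), together with the model's baseline prediction at the
#' A-site: the control head for control windows, the difference head
#' otherwise.
#'
#' @slot geneId,condition Provenance.
#' @slot codons Window codon tokens.
#' @slot start 0-based gene position of the first window codon.
#' @slot aSiteOffset 0-based A-site position within the window (10 when
#'   untruncated).
#' @slot baseline Baseline head prediction at the A-site.
#' @export
setClass("MutationWindow",
         representation(geneId = "character", condition = "character",
                        codons = "character", start = "integer",
                        aSiteOffset = "integer", baseline = "numeric"))

setMethod("show", "MutationWindow", function(object) {
  cat(sprintf("MutationWindow %s [%s] a-site %d (%d codons, baseline %.4f)\n",
              object@geneId, object@condition,
              object@start + object@aSiteOffset, length(object@codons),
              object@baseline))
})

#' Motif: a set of up to three codon mutations
#'
#' Mutations are (relative position, codon) pairs, positions relative to
#' the A-site (A-site = 0, P-site = -1), written canonically with one
#' `[SKIP]` token per gap codon. The score is the signed arctan
#' percentage increase of the predicted A-site count caused by applying
#' all mutations to the original window.
#'
#' @slot positions Sorted distinct relative positions.
#' @slot codons Mutated codons, in position order.
#' @slot canonical `[SKIP]`-gapped string.
#' @slot anchor Smallest relative position.
#' @slot score MAAPE-based stalling score.
#' @slot geneId,condition,aSite Provenance.
#' @export
setClass("Motif",
         representation(positions = "integer", codons = "character",
                        canonical = "character", anchor = "integer",
                        score = "numeric", geneId = "character",
                        condition = "character", aSite = "integer"))

setMethod("show", "Motif", function(object) {
  cat(sprintf("Motif \"%s\" @ %+d (size %d, score %.2f) [%s %s a-site %d]\n",
              object@canonical, object@anchor, length(object@positions),
              object@score, object@geneId, object@condition, object@aSite))
})

headFor <- function(condition) if (condition == "CTRL") "yCtrl" else "yDelta"

windowBaseline <- function(model, codonsVec, condition, aSiteOffset) {
  pr <- predictProfiles(model, codonsVec, condition)
  pr[[headFor(condition)]][aSiteOffset + 1L]
}

#' Select fast (non-peak) mutation windows
#'
#' Candidate A-sites are annotated positions whose stalling profile
#' value (difference profile for deprivations, footprint profile for
#' control) is strictly below the profile mean minus one population
#' standard deviation. `perCondition` windows are drawn uniformly
#' without replacement per condition (reproducibly by `seed`); if fewer
#' qualify, all are returned with a warning.
#'
#' @param dataset A normalized [RiboDataset-class].
#' @param model A [RiboModel-class] supplying baseline predictions.
#' @param perCondition Windows per condition (the study default is
#'   1000; scale down for desk runs).
#' @param seed RNG seed for the draw.
#' @param conditions Conditions to sample from.
#' @param halfWidth Window half-width (10 gives 21-codon windows).
#' @return List of [MutationWindow-class].
#' @export
selectFastWindows <- function(dataset, model, perCondition = 1000L,
                              seed = 1L, conditions = conditionIds(),
                              halfWidth = 10L) {
  set.seed(seed)
  out <- list()
  ss <- samples(dataset)
  condOf <- vapply(ss, condition, character(1))
  for (cond in conditions) {
    cand <- list()
    for (i in which(condOf == cond)) {
      tr <- findPeaks(stallingProfile(ss[[i]]))$troughs
      if (length(tr))
        cand[[length(cand) + 1L]] <- cbind(i, tr)
    }
    if (length(cand) == 0L) {
      if (perCondition > 0L)
        warning("no qualifying fast windows for condition ", cond)
      next
    }
    cand <- do.call(rbind, cand)
    k <- min(perCondition, nrow(cand))
    if (k < perCondition)
      warning("only ", nrow(cand), " qualifying windows for condition ",
              cond, " (requested ", perCondition, ")")
    if (k == 0L) next
    pick <- cand[sample.int(nrow(cand), k), , drop = FALSE]
    for (r in seq_len(k)) {
      s <- ss[[pick[r, 1L]]]
      p <- pick[r, 2L]
      n <- nCodons(s)
      sw <- significanceWindow(p, n, halfWidth)
      winCodons <- codons(s)[sw + 1L]
      off <- p - sw[1L]
      out[[length(out) + 1L]] <- new(
        "MutationWindow", geneId = geneId(s), condition = cond,
        codons = winCodons, start = as.integer(sw[1L]),
        aSiteOffset = as.integer(off),
        baseline = windowBaseline(model, winCodons, cond, off))
    }
  }
  out
}

#' Mutation stalling score
#'
#' Signed arctan percentage change of the predicted A-site count:
#' `sign(d) * 100 * atan(|d| / max(|orig|, eps))` with
#' `d = mut - orig`. Positive scores mark predicted stalling increases;
#' the score is antisymmetric under swapping the two predictions.
#'
#' @param orig,mut Predicted A-site values before/after mutation.
#' @param eps Denominator guard.
#' @return Signed score (bounded by 100*pi/2 in magnitude).
#' @export
mutationScore <- function(orig, mut, eps = 1e-6) {
  d <- mut - orig
  sign(d) * 100 * atan(abs(d) / pmax(abs(orig), eps))
}

# order candidates: higher score, then smaller relative position, then
# codon lexicographic (the package-wide deterministic tie rule)
candOrder <- function(score, relPos, codon)
  order(-score, relPos, codon, method = "radix")

#' Beam-search counterfactual motif extraction
#'
#' Level 1 scores every single-codon substitution in the window (61
#' sense codons, excluding the resident codon; the A-site itself is
#' mutable) and keeps the `width` best; level 2 freezes each level-1
#' mutation and searches the remaining positions, keeping `width` per
#' parent; level 3 likewise. All levels are returned:
#' `width + width^2 + width^3` motifs (155 at the defaults width 5,
#' depth 3). Scores are cumulative against the original window
#' baseline. Ties resolve by higher score, then smaller relative
#' position, then codon order, so the search is deterministic.
#'
#' @param window A [MutationWindow-class].
#' @param model The [RiboModel-class] the window was scored with.
#' @param width Beam width.
#' @param maxSize Maximum motif size (search depth).
#' @return List of [Motif-class], level by level.
#' @export
beamSearchMotifs <- function(window, model, width = 5L, maxSize = 3L) {
  w <- length(window@codons)
  condIdx <- match(window@condition, conditionIds())
  headIdx <- if (window@condition == "CTRL") "yCtrl" else "yDelta"
  baseTok <- codonIndex(window@codons)
  senseIdx <- codonIndex(senseCodons())
  aOff <- window@aSiteOffset
  orig <- window@baseline

  expandBeam <- function(beams) {
    # beams: list of (tok, frozen, mutations=list(pos, codonIdx))
    candTok <- list(); candMeta <- list()
    for (bi in seq_along(beams)) {
      b <- beams[[bi]]
      free <- setdiff(seq_len(w), b$frozen)
      for (p in free) {
        alt <- senseIdx[senseIdx != b$tok[p]]
        for (ci in alt) {
          tok <- b$tok; tok[p] <- ci
          candTok[[length(candTok) + 1L]] <- tok
          candMeta[[length(candMeta) + 1L]] <- list(parent = bi, pos = p,
                                                    codon = ci)
        }
      }
    }
    tokenMat <- do.call(rbind, candTok)
    pred <- nnScoreWindows(model, tokenMat, condIdx, aOff)[[headIdx]]
    score <- mutationScore(orig, pred)
    relPos <- vapply(candMeta, function(m) m$pos, integer(1)) - (aOff + 1L)
    codonStr <- allCodons()[vapply(candMeta, function(m) m$codon, integer(1))]
    parent <- vapply(candMeta, function(m) m$parent, integer(1))
    nxt <- list()
    for (bi in seq_along(beams)) {
      ix <- which(parent == bi)
      ord <- ix[candOrder(score[ix], relPos[ix], codonStr[ix])]
      for (j in ord[seq_len(min(width, length(ord)))]) {
        m <- candMeta[[j]]
        b <- beams[[m$parent]]
        nxt[[length(nxt) + 1L]] <- list(
          tok = candTok[[j]], frozen = c(b$frozen, m$pos),
          mutations = c(b$mutations, list(list(pos = m$pos,
                                               codon = m$codon))),
          score = score[j])
      }
    }
    nxt
  }

  beams <- list(list(tok = baseTok, frozen = integer(0), mutations = list(),
                     score = NA_real_))
  motifs <- list()
  for (lvl in seq_len(maxSize)) {
    beams <- expandBeam(beams)
    for (b in beams) {
      pos <- vapply(b$mutations, function(m) m$pos, integer(1)) - (aOff + 1L)
      cod <- allCodons()[vapply(b$mutations, function(m) m$codon, integer(1))]
      ord <- order(pos)
      can <- canonicalizeMotif(pos[ord], cod[ord])
      motifs[[length(motifs) + 1L]] <- new(
        "Motif", positions = as.integer(pos[ord]), codons = cod[ord],
        canonical = can$canonical, anchor = can$anchor, score = b$score,
        geneId = window@geneId, condition = window@condition,
        aSite = window@start + window@aSiteOffset)
    }
  }
  motifs
}

#' Canonical motif string
#'
#' Mutations are sorted by position and joined with one `[SKIP]` token
#' per gap codon; the anchor is the smallest relative position. E.g.
#' codons at -1 and +1 give `"XXX [SKIP] YYY"` anchored at -1.
#'
#' @param positions Distinct relative positions (1-3 of them).
#' @param codonsVec Mutated codons, same order as `positions`.
#' @return List with `canonical` and `anchor`.
#' @export
#' @examples
#' canonicalizeMotif(c(-1, 1), c("CTG", "CTT"))
canonicalizeMotif <- function(positions, codonsVec) {
  stopifnot(length(positions) >= 1L, length(positions) <= 3L,
            length(positions) == length(codonsVec))
  if (anyDuplicated(positions))
    stop("motif positions must be distinct", call. = FALSE)
  ord <- order(positions)
  positions <- positions[ord]; codonsVec <- codonsVec[ord]
  parts <- codonsVec[1]
  if (length(positions) > 1L) {
    for (k in 2:length(positions)) {
      gap <- positions[k] - positions[k - 1L] - 1L
      parts <- c(parts, rep("[SKIP]", gap), codonsVec[k])
    }
  }
  list(canonical = paste(parts, collapse = " "),
       anchor = as.integer(positions[1]))
}

#' @rdname canonicalizeMotif
#' @param canonical A canonical motif string.
#' @param anchor The anchor position.
#' @return `parseMotif()`: list with `positions` and `codons`.
#' @export
parseMotif <- function(canonical, anchor) {
  toks <- strsplit(canonical, " ", fixed = TRUE)[[1]]
  pos <- integer(0); cod <- character(0)
  p <- anchor
  for (t in toks) {
    if (t != "[SKIP]") { pos <- c(pos, p); cod <- c(cod, t) }
    p <- p + 1L
  }
  list(positions = as.integer(pos), codons = cod)
}

#' Fraction of motif mutations that hit a codon set
#'
#' @param motifs List of [Motif-class].
#' @param codonSet Character vector of codons (e.g.
#'   [deprivedCodons()]).
#' @return Fraction of all mutated codons belonging to the set.
#' @export
motifCodonRate <- function(motifs, codonSet) {
  all <- unlist(lapply(motifs, function(m) m@codons))
  mean(all %in% codonSet)
}

# merged peak significance windows per sample, as a logical inside-mask
peakSwMask <- function(sample, halfWidth = 10L) {
  n <- nCodons(sample)
  mask <- logical(n)
  pk <- findPeaks(stallingProfile(sample))$peaks
  for (p in pk) mask[significanceWindow(p, n, halfWidth) + 1L] <- TRUE
  mask
}

#' Motif enrichment near stalling peaks
#'
#' Ranks the canonical motif strings by frequency (repeated discoveries
#' count), keeps the `topN` most frequent, and tests each for enrichment
#' inside the merged peak significance windows of the condition's
#' samples versus all other CDS regions. A gapped motif (`[SKIP]` = any
#' codon) matched at any alignment start; an occurrence is inside when
#' its start position lies in a merged peak window. The 2x2 table of
#' occurrences and candidate alignment starts (inside/outside) is tested
#' with a two-sided Fisher exact test, BH-corrected across the tested
#' motifs.
#'
#' @param motifs List of [Motif-class] (typically pooled over many
#'   windows of one condition).
#' @param dataset The normalized [RiboDataset-class] the peaks come
#'   from.
#' @param cond Condition whose samples define the peaks.
#' @param topN Number of most frequent motifs to test.
#' @param halfWidth Significance-window half-width.
#' @param alwaysInclude Canonical motif strings tested regardless of
#'   their discovery frequency (e.g. planted or scrambled controls); the
#'   BH correction runs across everything tested.
#' @return data.frame: motif, countIn, countOut, totalIn, totalOut,
#'   oddsRatio, p, q; ordered by frequency rank.
#' @export
motifEnrichment <- function(motifs, dataset, cond, topN = 50L,
                            halfWidth = 10L, alwaysInclude = character(0)) {
  canon <- vapply(motifs, function(m) m@canonical, character(1))
  freq <- sort(table(canon), decreasing = TRUE)
  test <- union(names(freq)[seq_len(min(topN, length(freq)))], alwaysInclude)
  ss <- Filter(function(s) condition(s) == cond, samples(dataset))
  masks <- lapply(ss, peakSwMask, halfWidth = halfWidth)
  codonsList <- lapply(ss, codons)
  rows <- lapply(test, function(can) {
    pm <- parseMotif(can, 0L)
    offs <- pm$positions - pm$positions[1]
    L <- offs[length(offs)] + 1L
    kIn <- 0L; kOut <- 0L; nIn <- 0L; nOut <- 0L
    for (gi in seq_along(ss)) {
      cs <- codonsList[[gi]]
      n <- length(cs)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      hit <- rep(TRUE, length(starts))
      for (k in seq_along(offs))
        hit <- hit & cs[starts + offs[k]] == pm$codons[k]
      inside <- masks[[gi]][starts]
      kIn <- kIn + sum(hit & inside); kOut <- kOut + sum(hit & !inside)
      nIn <- nIn + sum(inside); nOut <- nOut + sum(!inside)
    }
    tab <- matrix(c(kIn, nIn - kIn, kOut, nOut - kOut), 2L)
    ft <- if (any(tab < 0) || sum(tab) == 0)
      list(p.value = NA_real_, estimate = NA_real_)
    else stats::fisher.test(tab, alternative = "two.sided")
    data.frame(motif = can, countIn = kIn, countOut = kOut, totalIn = nIn,
               totalOut = nOut, oddsRatio = unname(ft$estimate),
               p = ft$p.value, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$q <- stats::p.adjust(df$p, method = "BH")
  df
}
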