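#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' CodonSequence: an in-frame coding sequence
#'
#' Holds one CDS as an ordered run of codon tokens together with its gene
#' identifier. Profiles and model inputs are indexed by codon position
#' (0-based throughout the package).
#'
#' @slot geneId Single gene identifier.
#' @slot codons Character vector of 3-mers over \{A,C,G,T\}.
#' @export
setClass("CodonSequence",
         representation(geneId = "character", codons = "character"))

setValidity("CodonSequence", function(object) {
  if (length(object@geneId) != 1L || !nzchar(object@geneId))
    return("geneId must be a single non-empty string")
  if (length(object@codons) < 1L)
    return("a CodonSequence needs at least one codon")
  bad <- !grepl("^[ACGT]{3}$", object@codons)
  if (any(bad))
    return(paste0("invalid codon token(s): ",
                  paste(unique(object@codons[bad]), collapse = ", ")))
  TRUE
})

#' Construct a CodonSequence
#'
#' @param geneId Gene identifier.
#' @param x Either a character vector of codons or a single nucleotide
#'   string whose length is divisible by 3.
#' @return A [CodonSequence-class] object.
#' @export
#' @examples
#' codonSequence("g1", "ATGGTC")
codonSequence <- function(geneId, x) {
  if (length(x) == 1L && nchar(x) > 3L) {
    if (nchar(x) %% 3L != 0L)
      stop("sequence length of '", geneId, "' (", nchar(x),
           " nt) is not divisible by 3", call. = FALSE)
    x <- substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  new("CodonSequence", geneId = geneId, codons = toupper(as.character(x)))
}

#' @describeIn CodonSequence-class number of codons
#' @param x,object A `CodonSequence`.
#' @export
setMethod("length", "CodonSequence", function(x) length(x@codons))

#' Accessors for domain objects
#'
#' `geneId()` returns the gene identifier, `codons()` the codon tokens,
#' `nCodons()` the codon count.
#'
#' @param x A [CodonSequence-class] or [RiboSample-class].
#' @name accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname accessors
#' @export
setGeneric("nCodons", function(x) standardGeneric("nCodons"))

#' @rdname accessors
setMethod("geneId", "CodonSequence", function(x) x@geneId)
#' @rdname accessors
setMethod("codons", "CodonSequence", function(x) x@codons)
#' @rdname accessors
setMethod("nCodons", "CodonSequence", function(x) length(x@codons))

setMethod("show", "CodonSequence", function(object) {
  n <- length(object@codons)
  cat("CodonSequence", object@geneId, "with", n, "codons:",
      paste(utils::head(object@codons, 4L), collapse = " "),
      if (n > 4L) "..." else "", "\n")
})

#' RiboSample: one gene in one condition
#'
#' A sample pairs a coding sequence with its ribosome footprint profiles:
#' the control profile `yCtrl`, the (possibly identical) deprivation
#' profile `yDc`, and the derived difference `yDelta = yDc - yCtrl`.
#' Missing observations are encoded as `NA` and are distinct from zero
#' counts (zeros are real observations). For `CTRL` samples `yDc` equals
#' `yCtrl` and `yDelta` is zero wherever annotated.
#'
#' @slot seq A [CodonSequence-class].
#' @slot condition One of [conditionIds()].
#' @slot replicate Replicate label (used before merging; `"merged"` after).
#' @slot yCtrl,yDc,yDelta Numeric per-codon profiles (`NA` = missing).
#' @slot split One of `train`, `val`, `test`, `interp`, `unassigned`.
#' @export
setClass("RiboSample",
         representation(seq = "CodonSequence", condition = "character",
                        replicate = "character", yCtrl = "numeric",
                        yDc = "numeric", yDelta = "numeric",
                        split = "character"))

setValidity("RiboSample", function(object) {
  n <- length(object@seq)
  if (!object@condition %in% conditionIds())
    return("unknown condition identifier")
  for (nm in c("yCtrl", "yDc", "yDelta")) {
    v <- slot(object, nm)
    if (length(v) != n)
      return(sprintf("%s has length %d but the sequence has %d codons",
                     nm, length(v), n))
  }
  if (!object@split %in% c("train", "val", "test", "interp", "unassigned"))
    return("invalid split tag")
  TRUE
})

#' Construct a RiboSample
#'
#' `yDelta` is always derived: `yDc - yCtrl` where both are annotated, `NA`
#' otherwise. For `CTRL` samples, `yDc` is forced equal to `yCtrl`.
#'
#' @param seq A [CodonSequence-class].
#' @param condition One of [conditionIds()].
#' @param yCtrl,yDc Numeric profiles of length `nCodons(seq)`; `NA` encodes
#'   a missing observation. `yCtrl` may be omitted before control pairing.
#' @param replicate Replicate label.
#' @param split Split tag.
#' @return A [RiboSample-class].
#' @export
riboSample <- function(seq, condition, yCtrl = NULL, yDc = NULL,
                       replicate = "merged", split = "unassigned") {
  n <- length(seq)
  condition <- matchCondition(condition)
  if (is.null(yCtrl)) yCtrl <- rep(NA_real_, n)
  if (is.null(yDc)) yDc <- rep(NA_real_, n)
  if (condition == "CTRL") {
    if (all(is.na(yCtrl))) yCtrl <- yDc
    yDc <- yCtrl
  }
  yDelta <- yDc - yCtrl
  new("RiboSample", seq = seq, condition = condition, replicate = replicate,
      yCtrl = as.numeric(yCtrl), yDc = as.numeric(yDc),
      yDelta = as.numeric(yDelta), split = split)
}

#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("yCtrl", function(x) standardGeneric("yCtrl"))
#' @rdname accessors
#' @export
setGeneric("yDc", function(x) standardGeneric("yDc"))
#' @rdname accessors
#' @export
setGeneric("yDelta", function(x) standardGeneric("yDelta"))

#' @rdname accessors
setMethod("geneId", "RiboSample", function(x) x@seq@geneId)
#' @rdname accessors
setMethod("codons", "RiboSample", function(x) x@seq@codons)
#' @rdname accessors
setMethod("nCodons", "RiboSample", function(x) length(x@seq))
#' @rdname accessors
setMethod("condition", "RiboSample", function(x) x@condition)
#' @rdname accessors
setMethod("yCtrl", "RiboSample", function(x) x@yCtrl)
#' @rdname accessors
setMethod("yDc", "RiboSample", function(x) x@yDc)
#' @rdname accessors
setMethod("yDelta", "RiboSample", function(x) x@yDelta)

setMethod("show", "RiboSample", function(object) {
  cat(sprintf("RiboSample %s [%s, rep %s, split %s]: %d codons, %d annotated DC positions\n",
              geneId(object), object@condition, object@replicate,
              object@split, nCodons(object), sum(!is.na(object@yDc))))
})

#' RiboDataset: a collection of samples with split tags
#'
#' @slot samples List of [RiboSample-class] objects.
#' @export
setClass("RiboDataset", representation(samples = "list"))

setValidity("RiboDataset", function(object) {
  ok <- vapply(object@samples, inherits, logical(1), what = "RiboSample")
  if (!all(ok)) return("all elements must be RiboSample objects")
  # a gene must never straddle train/val/test
  sp <- vapply(object@samples, function(s) s@split, character(1))
  gid <- vapply(object@samples, geneId, character(1))
  core <- sp %in% c("train", "val", "test")
  if (any(core)) {
    tab <- tapply(sp[core], gid[core], function(v) length(unique(v)))
    if (any(tab > 1L))
      return("a gene appears in more than one of train/val/test")
  }
  TRUE
})

#' Construct a RiboDataset
#' @param samples List of [RiboSample-class] objects.
#' @return A [RiboDataset-class].
#' @export
riboDataset <- function(samples) new("RiboDataset", samples = samples)

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setGeneric("splits", function(x) standardGeneric("splits"))

#' @rdname accessors
setMethod("samples", "RiboDataset", function(x) x@samples)
#' @rdname accessors
setMethod("nSamples", "RiboDataset", function(x) length(x@samples))
#' @rdname accessors
setMethod("splits", "RiboDataset",
          function(x) vapply(x@samples, function(s) s@split, character(1)))
#' @rdname accessors
setMethod("geneId", "RiboDataset",
          function(x) vapply(x@samples, geneId, character(1)))
#' @rdname accessors
setMethod("condition", "RiboDataset",
          function(x) vapply(x@samples, condition, character(1)))

setMethod("show", "RiboDataset", function(object) {
  sp <- splits(object)
  cat("RiboDataset:", length(object@samples), "samples,",
      length(unique(geneId(object))), "genes\n  splits:",
      paste(sprintf("%s=%d", names(table(sp)), table(sp)), collapse = " "),
      "\n")
})

#' Subset a dataset by split tag
#'
#' @param x A [RiboDataset-class].
#' @param split Character vector of split tags to keep.
#' @return A [RiboDataset-class] with the matching samples.
#' @export
subsetSplit <- function(x, split) {
  riboDataset(x@samples[splits(x) %in% split])
}

#' RiboModel: the conditional double-headed sequence model
#'
#' Wraps the model configuration and the flat list of parameter matrices.
#' Forward passes produce a control-head and a difference-head profile;
#' the deprivation-condition prediction is their sum by construction.
#'
#' @slot config Model configuration list (see [modelConfig()]).
#' @slot params Named list of parameter matrices/vectors.
#' @export
setClass("RiboModel", representation(config = "list", params = "list"))

setMethod("show", "RiboModel", function(object) {
  cfg <- object@config
  cat(sprintf("RiboModel [%s]: D=%d, %d layer(s), %d head(s), %d parameters\n",
              cfg$backbone, cfg$dModel, cfg$nLayers, cfg$nHeads,
              sum(vapply(object@params, length, integer(1)))))
})

#' @rdname accessors
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @rdname accessors
setMethod("modelConfigOf", "RiboModel", function(x) x@config)
#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))
#' @rdname accessors
setMethod("modelParams", "RiboModel", function(x) x@params)

#' AttributionVector: per-codon saliency for one A-site and head
#'
#' @slot geneId Gene identifier.
#' @slot aSite 0-based A-site position the scalar output was taken at.
#' @slot head `"ctrl"` or `"delta"`.
#' @slot values Per-codon attribution values (length = gene length).
#' @export
setClass("AttributionVector",
         representation(geneId = "character", aSite = "integer",
                        head = "character", values = "numeric"))

setValidity("AttributionVector", function(object) {
  if (!object@head %in% c("ctrl", "delta")) return("head must be ctrl/delta")
  if (any(!is.finite(object@values))) return("attributions must be finite")
  if (object@aSite < 0L || object@aSite >= length(object@values))
    return("aSite out of range")
  TRUE
})

setMethod("show", "AttributionVector", function(object) {
  cat(sprintf("AttributionVector %s head=%s a-site=%d over %d codons\n",
              object@geneId, object@head, object@aSite,
              length(object@values)))
})
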