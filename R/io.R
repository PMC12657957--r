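#' Read coding sequences from FASTA
#'
#' Each record must be an in-frame CDS: length divisible by 3 and only
#' A/C/G/T characters. Identifiers are taken from the header up to the
#' first whitespace; record order is preserved.
#'
#' @param path FASTA file path.
#' @return Named list of [CodonSequence-class] objects.
#' @export
readCdsFasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) return(structure(list(), names = character(0)))
  ids <- sub("\\s.*$", "", names(dna))
  out <- vector("list", length(dna))
  for (i in seq_along(dna)) {
    s <- toupper(as.character(dna[[i]]))
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of record '", ids[i], "' (", nchar(s),
           " nt) is not divisible by 3", call. = FALSE)
    if (grepl("[^ACGT]", s))
      stop("record '", ids[i], "' contains non-ACGT characters",
           call. = FALSE)
    out[[i]] <- codonSequence(ids[i], s)
  }
  names(out) <- ids
  if (anyDuplicated(ids))
    stop("duplicate gene ids in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out
}

#' Read ribosome footprint profiles
#'
#' Expects a tab-delimited file with header columns `gene_id`,
#' `condition`, `replicate`, `position`, `count`. Positions are 0-based
#' codon indices; the literal `NA` encodes a missing observation
#' (distinct from a zero count). Rows are grouped by (gene, condition,
#' replicate); unlisted positions become missing. Each group yields one
#' replicate-level [RiboSample-class] whose `yDc` holds the group's
#' profile; control profiles are attached later by [pairControls()].
#'
#' @param path TSV file path.
#' @param seqs Named list of [CodonSequence-class] (e.g. from
#'   [readCdsFasta()]); genes without a sequence are skipped with a
#'   warning.
#' @return A [RiboDataset-class] of replicate-level samples.
#' @export
readProfiles <- function(path, seqs) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(gene_id = "character",
                                         condition = "character",
                                         replicate = "character",
                                         position = "integer",
                                         count = "numeric"))
  need <- c("gene_id", "condition", "replicate", "position", "count")
  if (!all(need %in% names(df)))
    stop("profile file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$condition), conditionIds())
  if (length(bad))
    stop("unknown condition string(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  missingSeq <- setdiff(unique(df$gene_id), names(seqs))
  if (length(missingSeq)) {
    warning("skipping ", length(missingSeq),
            " gene(s) without a CDS sequence: ",
            paste(utils::head(missingSeq, 5L), collapse = ", "))
    df <- df[!df$gene_id %in% missingSeq, , drop = FALSE]
  }
  key <- paste(df$gene_id, df$condition, df$replicate, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    g <- df$gene_id[ix[1]]
    seq <- seqs[[g]]
    n <- length(seq)
    pos <- df$position[ix]
    if (any(pos < 0L | pos >= n))
      stop("position out of range for gene '", g, "' (n = ", n, "): ",
           max(pos), call. = FALSE)
    if (anyDuplicated(pos))
      stop("duplicate positions for gene '", g, "'", call. = FALSE)
    cnt <- df$count[ix]
    if (any(cnt[!is.na(cnt)] < 0))
      stop("negative count for gene '", g, "'", call. = FALSE)
    y <- rep(NA_real_, n)
    y[pos + 1L] <- cnt
    riboSample(seq, df$condition[ix[1]], yDc = y,
               replicate = df$replicate[ix[1]])
  })
  riboDataset(unname(out))
}

#' Write profiles in the package's TSV dialect
#'
#' Writes one row per annotated position of each sample's `yDc` profile
#' (missing positions are written as `NA` so a round-trip preserves the
#' annotation mask).
#'
#' @param dataset A [RiboDataset-class].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
writeProfiles <- function(dataset, path) {
  rows <- lapply(samples(dataset), function(s) {
    y <- yDc(s)
    data.frame(gene_id = geneId(s), condition = condition(s),
               replicate = s@replicate, position = seq_along(y) - 1L,
               count = y, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param seqs List of [CodonSequence-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCdsFasta <- function(seqs, path) {
  dna <- Biostrings::DNAStringSet(
    vapply(seqs, function(s) paste(codons(s), collapse = ""), character(1)))
  names(dna) <- vapply(seqs, geneId, character(1))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a parameter file (RDS) plus a structured-text sidecar
#' (`<path>.json`) holding the full configuration: architecture, seed,
#' and the codon and condition vocabularies. Loading verifies the
#' vocabularies and requires every configuration field to be present so
#' legacy or foreign files fail loudly rather than defaulting silently.
#'
#' @param model A [RiboModel-class].
#' @param path Checkpoint file path.
#' @return `writeCheckpoint()`: invisibly, the path. `readCheckpoint()`:
#'   the restored [RiboModel-class], bit-identical parameters.
#' @export
writeCheckpoint <- function(model, path) {
  saveRDS(model@params, path)
  cfg <- model@config
  cfg$codon_vocab <- allCodons()
  cfg$condition_vocab <- conditionIds()
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar config: ", side, call. = FALSE)
  cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
  need <- c("dModel", "nLayers", "nHeads", "dFf", "backbone", "dropout",
            "seed", "codon_vocab", "condition_vocab")
  absent <- setdiff(need, names(cfg))
  if (length(absent))
    stop("checkpoint config is missing field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!identical(as.character(cfg$codon_vocab), allCodons()))
    stop("checkpoint codon vocabulary differs from the package vocabulary",
         call. = FALSE)
  if (!identical(as.character(cfg$condition_vocab), conditionIds()))
    stop("checkpoint condition vocabulary differs from the package vocabulary",
         call. = FALSE)
  params <- readRDS(path)
  cfg$codon_vocab <- NULL
  cfg$condition_vocab <- NULL
  cfg$dModel <- as.integer(cfg$dModel)
  cfg$nLayers <- as.integer(cfg$nLayers)
  cfg$nHeads <- as.integer(cfg$nHeads)
  cfg$dFf <- as.integer(cfg$dFf)
  new("RiboModel", config = cfg, params = params)
}
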