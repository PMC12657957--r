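#' Codon and condition vocabularies
#'
#' The package works on in-frame coding sequences tokenized into the 64
#' codons over the DNA alphabet. Deprivation conditions form a closed
#' vocabulary of six identifiers: the replete control plus five
#' branched-chain amino-acid deprivations (single LEU/ILE/VAL and the
#' double and triple combinations). Each deprivation maps to the set of
#' codons decoding the deprived amino acid(s); stalling under deprivation
#' is expected at those codons when they occupy the ribosomal A-site.
#'
#' @name vocabularies
NULL

# fixed token order: all 64 codons, lexicographic over A<C<G<T
.CODONS <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                 paste0), c("A", "C", "G", "T"), paste0))
.CODONS <- sort(.CODONS)
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.CONDITIONS <- c("CTRL", "LEU", "ILE", "VAL", "LEU_ILE", "LEU_ILE_VAL")

.AA_CODONS <- list(
  LEU = c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"),
  ILE = c("ATA", "ATC", "ATT"),
  VAL = c("GTA", "GTC", "GTG", "GTT")
)

#' All codon tokens
#'
#' @return Character vector of the 64 codons in the fixed model vocabulary
#'   order (lexicographic).
#' @export
#' @examples
#' length(allCodons())
allCodons <- function() .CODONS

#' Sense codons
#'
#' @return The 61 codons that encode an amino acid (stop codons excluded).
#'   This is the substitution alphabet of the counterfactual mutation
#'   search, so that mutated windows remain translatable.
#' @export
senseCodons <- function() setdiff(.CODONS, .STOP_CODONS)

#' Condition identifiers
#'
#' @return Character vector of the six supported condition identifiers:
#'   `CTRL`, `LEU`, `ILE`, `VAL`, `LEU_ILE`, `LEU_ILE_VAL`.
#' @export
conditionIds <- function() .CONDITIONS

#' Codons encoding the deprived amino acid(s) of a condition
#'
#' Combined deprivations take the union of their components; `CTRL` has no
#' deprived codons.
#'
#' @param condition One of [conditionIds()].
#' @return Character vector of deprived codons (empty for `CTRL`).
#' @export
#' @examples
#' deprivedCodons("VAL")
#' deprivedCodons("LEU_ILE")
deprivedCodons <- function(condition) {
  condition <- matchCondition(condition)
  if (condition == "CTRL") return(character(0))
  parts <- strsplit(condition, "_", fixed = TRUE)[[1]]
  sort(unique(unlist(.AA_CODONS[parts], use.names = FALSE)))
}

matchCondition <- function(condition) {
  if (length(condition) != 1L || !condition %in% .CONDITIONS) {
    stop("unknown condition identifier: ", paste(condition, collapse = ","),
         " (expected one of ", paste(.CONDITIONS, collapse = ", "), ")",
         call. = FALSE)
  }
  condition
}

codonIndex <- function(codons) {
  idx <- match(codons, .CODONS)
  if (anyNA(idx)) {
    stop("unknown codon token(s): ",
         paste(unique(codons[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}
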