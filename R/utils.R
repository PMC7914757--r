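## Small shared helpers.

#' Global pairwise sequence identity
#'
#' Aligns two sequences globally (Needleman-Wunsch, affine gaps) and returns
#' the percent identity computed as matches divided by aligned columns where
#' both sequences are ungapped, times 100. Symmetric by construction.
#'
#' @param a,b Character scalars, \code{DNAString}/\code{AAString} or
#'   length-one \code{XStringSet}; both nucleotide or both amino acid.
#' @param mode \code{"nt"} or \code{"aa"}; selects the scoring scheme.
#' @return Numeric percent identity in \[0, 100\].
#' @export
#' @examples
#' pairwiseIdentitySeq("ATGGCC", "ATGGCC")          # 100
#' pairwiseIdentitySeq("ATGGCA", "ATGGCC")          # 5/6 * 100
pairwiseIdentitySeq <- function(a, b, mode = c("nt", "aa")) {
  mode <- match.arg(mode)
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b))
    stop("pairwiseIdentitySeq: empty sequence")
  if (identical(a, b)) return(100)
  if (mode == "nt") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- p != "-" & s != "-"
  if (!any(ok)) return(0)
  100 * mean(p[ok] == s[ok])
}

## Translate a CDS; returns list(protein=, valid=, note=).
.translateCDS <- function(nt) {
  nt <- toupper(nt)
  if (nchar(nt) %% 3 != 0)
    return(list(protein = "", valid = FALSE, note = "length_not_multiple_of_3"))
  if (grepl("[^ACGT]", nt))
    return(list(protein = "", valid = FALSE, note = "ambiguous_nucleotides"))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  ## strip one terminal stop if present
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("\\*", aa))
    return(list(protein = "", valid = FALSE, note = "internal_stop"))
  list(protein = aa, valid = TRUE, note = "")
}

## deterministic longest common prefix of two strings
.commonPrefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0
  while (i < n && substr(a, i + 1, i + 1) == substr(b, i + 1, i + 1)) i <- i + 1
  substr(a, 1, i)
}
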