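# Pairwise alignment helpers over the extended alphabet.
#
# Biostrings' DNAString alphabet has no 5mC letter, so alignments run on
# plain BStrings with an explicit substitution matrix covering
# {A, T, C, G, M}. M is scored as its own letter: a C/M mismatch is a real
# mismatch, which is exactly the substitution class the methylation
# channel produces.

extended_letters <- c("A", "T", "C", "G", "M")

substitution_matrix <- function(match = 2, mismatch = -2,
                                letters = extended_letters) {
  m <- matrix(mismatch, length(letters), length(letters),
    dimnames = list(letters, letters)
  )
  diag(m) <- match
  m
}

align_pair <- function(a, b, type = "global", match = 2, mismatch = -2,
                       gap_opening = 4, gap_extension = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::BString(a), Biostrings::BString(b),
    type = type,
    substitutionMatrix = substitution_matrix(match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
}

# aligned pattern/subject strings (with "-" gaps) of a pairwise alignment
aligned_strings <- function(aln) {
  list(
    pattern = as.character(Biostrings::pattern(aln)),
    subject = as.character(Biostrings::subject(aln))
  )
}

#' Alignment identity between a read and a reference
#'
#' Matches divided by alignment length of a semi-global (overlap)
#' pairwise alignment, so flanking sequence present in only one of the
#' two (barcodes, neighbouring units) is not penalised. Used with the
#' 0.85 retention threshold for read screening.
#'
#' @param read,reference Non-empty letter strings over {A, T, C, G, M}.
#' @param type Alignment type passed to the aligner (default
#'   `"overlap"`).
#' @return Fraction in [0, 1].
#' @examples
#' alignment_identity("GACA", "GACA")  # 1
#' @export
alignment_identity <- function(read, reference, type = "overlap") {
  if (nchar(read) == 0 || nchar(reference) == 0) {
    stop("empty sequence", call. = FALSE)
  }
  aln <- align_pair(read, reference, type = type)
  len <- nchar(aligned_strings(aln)$pattern)
  if (len == 0) return(0)
  Biostrings::nmatch(aln) / len
}
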