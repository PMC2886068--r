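#' Percent identity of two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties (BLOSUM62,
#' gap open 10, gap extend 0.5), then identity = identical aligned positions
#' divided by alignment length including gap columns, times 100, half-up
#' rounded to one decimal. Alignment-method details are not standardized
#' across published identity figures, so small differences from other tools'
#' values are expected.
#'
#' @param seq_a,seq_b Non-empty amino-acid sequences (standard one-letter
#'   codes, `X`/`B`/`Z` ambiguity codes allowed).
#' @return Percent identity (numeric scalar).
#' @examples
#' pairwise_identity("AAAA", "AATA") # 75
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  check_aa <- function(s, which) {
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
      stop("sequence ", which, " must be a non-empty string")
    }
    s <- toupper(gsub("[[:space:]]", "", s))
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYXBZ]", s)) {
      stop("sequence ", which, " contains non-amino-acid characters: ",
           paste(unique(strsplit(gsub("[ACDEFGHIKLMNPQRSTVWYXBZ]", "", s),
                                 "")[[1]]), collapse = ""))
    }
    s
  }
  a <- check_aa(seq_a, "a")
  b <- check_aa(seq_b, "b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  round_half_up(100 * sum(pa == pb & pa != "-") / length(pa), 1)
}
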