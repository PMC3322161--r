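#' Globally align two DNA sequences
#'
#' Needleman-Wunsch global alignment with affine gap costs, as a thin wrapper
#' around [Biostrings::pairwiseAlignment()]. The defaults (match 1, mismatch
#' -1, gap open 10, gap extend 0.5) are a conventional parameterisation for
#' closely related rDNA sequences; distance estimates downstream are checked
#' with tolerances, not bit-exactness, precisely because alignment parameters
#' are a free choice.
#'
#' @param seq_a,seq_b DNA strings over A/C/G/T.
#' @param id_a,id_b labels carried into the result.
#' @param match,mismatch match score and mismatch penalty (penalty given as a
#'   negative score).
#' @param gap_open,gap_extend affine gap penalties (non-negative).
#' @return a list of class `alignment_pair`: `id_a`, `id_b`, `aligned_a`,
#'   `aligned_b` (equal-length strings over A/C/G/T/-), `score`.
#' @export
align_pair <- function(seq_a, seq_b, id_a = "A", id_b = "B",
                       match = 1, mismatch = -1, gap_open = 10, gap_extend = 0.5) {
  seq_a <- normalize_dna(seq_a); seq_b <- normalize_dna(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  if (grepl("[^ACGT]", seq_a) || grepl("[^ACGT]", seq_b)) {
    stop("align_pair expects plain A/C/G/T sequences")
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                 baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  structure(
    list(id_a = id_a, id_b = id_b,
         aligned_a = as.character(Biostrings::alignedPattern(aln)),
         aligned_b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln)),
    class = "alignment_pair")
}

#' @export
print.alignment_pair <- function(x, ...) {
  cat("<alignment_pair> ", x$id_a, " vs ", x$id_b,
      " (", nchar(x$aligned_a), " columns, score ", x$score, ")\n", sep = "")
  invisible(x)
}
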