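# Shared pairwise-alignment helpers. All identity/divergence numbers in the
# package use one definition: matches / aligned columns, where aligned
# columns are those with a residue in both sequences (gap columns excluded
# from numerator and denominator).

#' Global pairwise alignment with free end gaps
#'
#' Aligns two nucleotide sequences end-gap-free (Needleman-Wunsch with
#' unpenalized terminal gaps) and summarizes the gap-free columns. This is
#' the single alignment definition used for LTR-pair divergence, detector
#' identity, family clustering and library deduplication.
#'
#' @param a,b nucleotide strings
#' @return list with `identity`, `p` (mismatch proportion), `matches`,
#'   `aligned_sites` (gap-free shared columns), and `coverage_a`,
#'   `coverage_b` (aligned sites / input length)
#' @export
align_pair <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "overlap",
    substitutionMatrix = submat, gapOpening = 6, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  st <- pdist_pairs(c(pa, sa))
  aligned_sites <- st$shared[1, 2]
  p <- if (aligned_sites > 0) st$d[1, 2] else NA_real_
  rng <- aln@subject@range
  list(identity = if (aligned_sites > 0) 1 - p else 0,
       p = p,
       matches = if (aligned_sites > 0)
         as.integer(round((1 - p) * aligned_sites)) else 0L,
       aligned_sites = aligned_sites,
       coverage_a = aligned_sites / nchar(a),
       coverage_b = aligned_sites / nchar(b),
       b_start = Biostrings::start(rng) - 1L,   # 0-based on b
       b_end = Biostrings::end(rng))
}

#' Strand-aware pairwise alignment
#'
#' As [align_pair()], but also tries the reverse complement of `b` and
#' returns the orientation with the higher identity (reported in
#' `strand`). Used wherever genomic LTR copies of unknown orientation are
#' compared (family clustering, library deduplication), mirroring
#' strand-aware all-against-all search tools.
#'
#' @inheritParams align_pair
#' @export
align_pair_both_strands <- function(a, b) {
  fwd <- align_pair(a, b)
  rev <- align_pair(a, revcomp(b))
  # orientation with more matched bases wins: raw identity would favour
  # degenerate few-column overlaps of the wrong strand
  if (rev$matches > fwd$matches) c(rev, strand = "-")
  else c(fwd, strand = "+")
}

#' Local protein alignment score against a reference
#'
#' Smith-Waterman with BLOSUM62, used by the domain scanner.
#'
#' @param query,ref amino-acid strings
#' @return list with `score`, `q_start`, `q_end` (0-based half-open on the
#'   query), `ref_coverage`
#' @keywords internal
align_protein_local <- function(query, ref) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(ref), type = "local",
    substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 4)
  pat <- aln@pattern
  list(score = Biostrings::score(aln),
       q_start = Biostrings::start(pat@range) - 1L,
       q_end = Biostrings::end(pat@range),
       ref_coverage = Biostrings::width(aln@subject@range) / nchar(ref))
}
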