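.datatable.aware <- TRUE

DNA <- c("A", "C", "G", "T")

#' Random i.i.d. nucleotide sequence
#'
#' Uniform over A/C/G/T; used for genomic background, LTR and spacer
#' sequence. Driven by the current RNG state.
#'
#' @param n length in bases
#' @return a single character string of length `n`
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA, n, replace = TRUE), collapse = "")
}

#' Reverse complement of a nucleotide string
#' @param x character string over A/C/G/T/N
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Jukes-Cantor aging of a sequence
#'
#' Applies the exact JC69 transition kernel for an expected number of
#' substitutions per site `d = rate * time`: each site changes with
#' probability 3/4 (1 - exp(-4d/3)) and, if it changes, moves uniformly to
#' one of the three alternative bases. Multiple hits are thereby modelled
#' exactly, so downstream JC correction of pairwise divergence is unbiased.
#'
#' @param seq nucleotide string
#' @param d expected substitutions per site (rate x years)
#' @return mutated nucleotide string of identical length
#' @keywords internal
mutate_jc <- function(seq, d) {
  n <- nchar(seq)
  if (n == 0L || d <= 0) return(seq)
  p_change <- 0.75 * (1 - exp(-4 * d / 3))
  hits <- which(runif(n) < p_change)
  if (length(hits) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hits) {
    chars[i] <- sample(setdiff(DNA, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Stable per-stage seed derived from a global seed
#'
#' Fans one user-facing seed out to independent stage seeds by hashing the
#' stage name (sum of UTF-8 codes with a small multiplier) into a 31-bit
#' integer, so toggling stages never shifts another stage's random stream.
#'
#' @param seed global integer seed
#' @param stage stage name, e.g. "detect"
#' @keywords internal
stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- 0
  for (cc in codes) h <- (h * 131 + cc) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Substring by 0-based half-open interval
#' @keywords internal
substr0 <- function(x, start, end) substr(x, start + 1L, end)

jc_correct <- function(p) -0.75 * log(1 - 4 * p / 3)

`%||%` <- function(a, b) if (is.null(a)) b else a
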