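#' Read a FASTA file into a named character vector
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]; accepts wrapped or
#' unwrapped records and CRLF line endings. Names are truncated at the
#' first whitespace, matching common tool behaviour.
#'
#' @param path FASTA file
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Write a paired read set to a pair of FASTQ files
#'
#' Reads are named `read<i>/1` and `read<i>/2`; qualities are constant
#' ("I", Q40) because the simulator models substitution errors directly.
#'
#' @param reads a `read_set` from [simulate_reads()]
#' @param prefix output prefix; writes `<prefix>_1.fq` and `<prefix>_2.fq`
#' @return the two paths, invisibly
#' @export
write_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  p1 <- paste0(prefix, "_1.fq")
  p2 <- paste0(prefix, "_2.fq")
  ids <- sprintf("read%06d", seq_len(nrow(reads$pairs)))
  for (side in 1:2) {
    seqs <- if (side == 1) reads$pairs$r1 else reads$pairs$r2
    ss <- Biostrings::DNAStringSet(seqs)
    names(ss) <- paste0(ids, "/", side)
    Biostrings::writeXStringSet(
      ss, if (side == 1) p1 else p2, format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(seqs)))
    )
  }
  invisible(c(p1, p2))
}

#' Read paired FASTQ files back into a read set
#'
#' @param path1,path2 FASTQ files for mates 1 and 2
#' @return a `read_set` (origin coordinates unknown, set to NA)
#' @export
read_fastq_pairs <- function(path1, path2) {
  r1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  structure(list(
    pairs = data.frame(
      r1 = as.character(r1), r2 = as.character(r2),
      pos1 = NA_integer_, pos2 = NA_integer_
    ),
    read_length = if (length(r1)) nchar(as.character(r1[[1]])) else NA_integer_,
    coverage = NA_real_, error_rate = NA_real_, genome_length = NA_integer_
  ), class = "read_set")
}

# ---- GFF3 ----------------------------------------------------------------
# Internal coordinates throughout the package are 0-based half-open;
# GFF3 is written (and read back) as 1-based inclusive.

#' Write a GFF3 feature table
#'
#' @param df data.frame with columns seqid, source, type, start, end
#'   (1-based inclusive), score, strand, phase, attributes
#' @param path output file
#' @export
gff3_write <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(df) > 0) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     df$seqid, df$source, df$type,
                     as.integer(df$start), as.integer(df$end),
                     as.character(df$score), df$strand,
                     as.character(df$phase), df$attributes)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' @param path GFF3 file
#' @return data.frame in the layout accepted by [gff3_write()]
#' @export
gff3_read <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0) {
    return(data.frame(seqid = character(), source = character(),
                      type = character(), start = integer(), end = integer(),
                      score = character(), strand = character(),
                      phase = character(), attributes = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) stop("malformed GFF3 record at line ", bad[1])
  m <- do.call(rbind, parts)
  data.frame(seqid = m[, 1], source = m[, 2], type = m[, 3],
             start = as.integer(m[, 4]), end = as.integer(m[, 5]),
             score = m[, 6], strand = m[, 7], phase = m[, 8],
             attributes = m[, 9], stringsAsFactors = FALSE)
}

#' Write/read a tab-separated table
#'
#' TSV is the exchange format for all tabular artifacts (truth ledgers,
#' family tables, dating tables, depth tables).
#'
#' @param df data.frame
#' @param path file path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
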