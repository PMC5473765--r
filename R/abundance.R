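# Read-depth copy-number proxy. Reference LTRs are deduplicated into a
# library (greedy, longest first, 0.95 identity over the shorter
# sequence), short reads are mapped to the library with k-mer-seeded
# ungapped alignment (multi-mapped reads split fractionally across their
# equal-best placements), and per-representative depth normalized by the
# genome-wide mean depth is the copy-number proxy. An intact element
# carries two LTRs, so normalized family depth / 2 estimates the intact
# copy count.

#' Build a deduplicated reference LTR library
#'
#' Sequences shorter than `min_length` are excluded (their count is kept
#' in the `n_dropped` field). The rest are clustered greedily, longest
#' first: a sequence joins the first existing representative whose
#' alignment matches cover at least `dedupe_identity` of the shorter of
#' the two sequences, otherwise it becomes a new representative.
#'
#' @param ltrs named character vector of LTR sequences
#' @param family optional named vector mapping sequence name -> family
#'   label (representatives inherit their own sequence's family)
#' @param dedupe_identity identity cutoff (default 0.95)
#' @param min_length minimum LTR length retained (default 150)
#' @return object of class `ltr_library`: `reps` (named sequences),
#'   `family` (named vector), `members` (provenance list), `n_dropped`
#' @export
build_ltr_library <- function(ltrs, family = NULL, dedupe_identity = 0.95,
                              min_length = 150L) {
  if (is.null(names(ltrs))) names(ltrs) <- paste0("ltr", seq_along(ltrs))
  short <- nchar(ltrs) < min_length
  n_dropped <- sum(short)
  ltrs <- ltrs[!short]
  ord <- order(-nchar(ltrs), names(ltrs))
  ltrs <- ltrs[ord]
  reps <- character(0)
  members <- list()
  # cd-hit-style short-word prefilter: sequences sharing too few 11-mers
  # (in either orientation) cannot reach the identity cutoff, so the
  # expensive alignment is skipped
  kw <- 11L
  kmer_set <- function(s) {
    n <- nchar(s)
    if (n < kw) return(character(0))
    unique(substring(s, 1:(n - kw + 1L), kw:n))
  }
  rep_kmers <- list()
  for (nm in names(ltrs)) {
    placed <- FALSE
    ks_f <- kmer_set(ltrs[[nm]])
    ks_r <- kmer_set(revcomp(ltrs[[nm]]))
    for (r in names(reps)) {
      shr <- max(mean(ks_f %in% rep_kmers[[r]]),
                 mean(ks_r %in% rep_kmers[[r]]))
      if (is.na(shr) || shr < 0.35) next
      al <- align_pair_both_strands(ltrs[[nm]], reps[[r]])
      short_len <- min(nchar(ltrs[[nm]]), nchar(reps[[r]]))
      if (al$matches / short_len >= dedupe_identity) {
        members[[r]] <- c(members[[r]], nm)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[nm] <- ltrs[[nm]]
      members[[nm]] <- nm
      rep_kmers[[nm]] <- ks_f
    }
  }
  fam <- if (is.null(family)) setNames(names(reps), names(reps))
         else setNames(family[names(reps)], names(reps))
  structure(list(reps = reps, family = fam, members = members,
                 n_dropped = n_dropped, dedupe_identity = dedupe_identity,
                 min_length = as.integer(min_length)),
            class = "ltr_library")
}

#' @export
print.ltr_library <- function(x, ...) {
  cat("ltr_library:", length(x$reps), "representatives from",
      length(unlist(x$members)), "input LTRs (", x$n_dropped,
      "dropped as <", x$min_length, "b )\n")
  invisible(x)
}

read_seed_offsets <- function(read_length, k) {
  if (read_length <= k) return(1L)
  # several spread seeds so that scattered mismatches against a diverged
  # representative rarely kill every seed falling inside the overlap
  n <- max(3L, (read_length - k) %/% 12L + 1L)
  unique(pmax(1L, pmin(read_length - k + 1L,
                       as.integer(round(seq(1L, read_length - k + 1L,
                                            length.out = n))))))
}

#' Map reads to an LTR library
#'
#' k-mer-seeded ungapped alignment of every read (both orientations)
#' against the library. A placement may overhang the representative ends;
#' only the overlapping span is scored, and a placement is accepted when
#' the overlap is at least `min_overlap` and its mismatch rate is at most
#' `max_mismatch_per_100bp` per 100 bases. Each read contributes weight
#' `1/n_best` to every equal-best placement (most matching bases), making
#' multi-mapping deterministic.
#'
#' @param reads a `read_set`
#' @param library an `ltr_library`
#' @param max_mismatch_per_100bp mismatch budget per 100 bases of overlap
#' @param seed_k seed length (default 31)
#' @param min_overlap minimum read/representative overlap in bases
#' @return data.frame of class `read_hits`: read, rep, pos (0-based, may
#'   be negative), strand, overlap, mismatches, weight; attributes
#'   `n_reads` and `total_read_bases`
#' @export
map_reads <- function(reads, library, max_mismatch_per_100bp = 2,
                      seed_k = 31L, min_overlap = 31L) {
  stopifnot(inherits(reads, "read_set"), inherits(library, "ltr_library"))
  rl <- reads$read_length
  if (rl < seed_k) stop("read length below seed size")
  empty_hits <- data.frame(read = character(), rep = character(),
                           pos = integer(), strand = character(),
                           overlap = integer(), mismatches = integer(),
                           weight = numeric(), stringsAsFactors = FALSE)
  all_reads <- c(reads$pairs$r1, reads$pairs$r2)
  read_ids <- c(sprintf("read%06d/1", seq_len(nrow(reads$pairs))),
                sprintf("read%06d/2", seq_len(nrow(reads$pairs))))
  finish <- function(df) {
    attr(df, "n_reads") <- length(all_reads)
    attr(df, "total_read_bases") <- sum(nchar(all_reads))
    class(df) <- c("read_hits", "data.frame")
    df
  }
  if (length(library$reps) == 0 || length(all_reads) == 0)
    return(finish(empty_hits))

  lib_idx <- data.table::rbindlist(lapply(names(library$reps), function(r) {
    s <- library$reps[[r]]
    n <- nchar(s)
    if (n < seed_k) return(NULL)
    data.table::data.table(kmer = substring(s, 1:(n - seed_k + 1L),
                                            seed_k:n),
                           rep = r, rpos = 0:(n - seed_k))
  }))
  if (nrow(lib_idx) == 0) return(finish(empty_hits))

  rc_reads <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_reads)))
  offs <- read_seed_offsets(rl, seed_k)
  seed_tabs <- list()
  for (strand in c("+", "-")) {
    src <- if (strand == "+") all_reads else rc_reads
    for (o in offs) {
      seed_tabs[[length(seed_tabs) + 1L]] <- data.table::data.table(
        kmer = substring(src, o, o + seed_k - 1L),
        ridx = seq_along(src), off = o - 1L, strand = strand)
    }
  }
  seeds <- data.table::rbindlist(seed_tabs)
  data.table::setkeyv(lib_idx, "kmer")
  cand <- lib_idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(cand) == 0) return(finish(empty_hits))
  cand$pos <- cand$rpos - cand$off
  cand <- unique(cand[, c("ridx", "strand", "rep", "pos")])

  qry <- ifelse(cand$strand == "+", all_reads[cand$ridx],
                rc_reads[cand$ridx])
  om <- overlap_mismatches(qry, unname(library$reps[cand$rep]), cand$pos)
  cand$overlap <- om[, 1]
  cand$mismatches <- om[, 2]
  cand <- cand[cand$overlap >= min_overlap &
                 cand$mismatches * 100 <= max_mismatch_per_100bp *
                   cand$overlap, ]
  if (nrow(cand) == 0) return(finish(empty_hits))
  cand$matches <- cand$overlap - cand$mismatches
  best <- cand[, list(bm = max(matches)), by = "ridx"]
  cand <- best[cand, on = "ridx"][matches == bm]
  nb <- cand[, list(nbest = .N), by = "ridx"]
  cand <- nb[cand, on = "ridx"]
  out <- data.frame(read = read_ids[cand$ridx], rep = cand$rep,
                    pos = cand$pos, strand = cand$strand,
                    overlap = cand$overlap, mismatches = cand$mismatches,
                    weight = 1 / cand$nbest, stringsAsFactors = FALSE)
  finish(out[order(out$read, out$rep, out$pos), ])
}

#' Genome-wide mean read depth by read arithmetic
#'
#' Total read bases divided by genome length -- identical in expectation
#' to a whole-genome mapping pass on uniform synthetic reads.
#'
#' @param reads a `read_set` (needs its `genome_length`)
#' @param genome_length override when reads were loaded from FASTQ
#' @export
genome_mean_depth <- function(reads, genome_length = NULL) {
  L <- genome_length %||% reads$genome_length
  stopifnot(!is.na(L), L > 0)
  sum(nchar(c(reads$pairs$r1, reads$pairs$r2))) / L
}

#' Per-representative and per-family normalized read depth
#'
#' Raw per-representative depth is the mean per-base weighted coverage
#' from the accepted placements; normalized depth divides by the
#' genome-wide mean depth. Family depth is the representative depth
#' averaged with representative-length weights; `copies_est` divides the
#' normalized family depth by `ltrs_per_element` (2 for intact elements,
#' which carry two LTRs each).
#'
#' @param hits `read_hits` from [map_reads()]
#' @param library the `ltr_library` that was mapped against
#' @param mean_depth genome-wide mean depth (see [genome_mean_depth()])
#' @param ltrs_per_element LTR copies contributed per element (default 2)
#' @return object of class `depth_profile` with `per_rep` and `per_family`
#'   data.frames and `mean_depth`
#' @export
depth_profile <- function(hits, library, mean_depth,
                          ltrs_per_element = 2) {
  stopifnot(mean_depth > 0)
  reps <- names(library$reps)
  lens <- nchar(library$reps)
  raw <- setNames(numeric(length(reps)), reps)
  nmapped <- setNames(numeric(length(reps)), reps)
  if (nrow(hits) > 0) {
    agg <- stats::aggregate(
      cbind(bases = hits$weight * hits$overlap, w = hits$weight),
      by = list(rep = hits$rep), FUN = sum)
    raw[agg$rep] <- agg$bases / lens[agg$rep]
    nmapped[agg$rep] <- agg$w
  }
  per_rep <- data.frame(rep = reps, family = library$family[reps],
                        length = lens, raw_depth = raw,
                        norm_depth = raw / mean_depth,
                        mapped_reads = nmapped, stringsAsFactors = FALSE)
  rownames(per_rep) <- NULL
  fams <- sort(unique(per_rep$family))
  per_family <- do.call(rbind, lapply(fams, function(f) {
    # sum representative depths (invariant to how finely the family's
    # LTRs split into representatives), length-weighting each so that
    # shorter truncated representatives do not dominate
    sel <- per_rep$family == f
    w <- per_rep$length[sel] / mean(per_rep$length[sel])
    nd <- sum(per_rep$norm_depth[sel] * w)
    data.frame(family = f, n_reps = sum(sel),
               norm_depth = nd, copies_est = nd / ltrs_per_element,
               stringsAsFactors = FALSE)
  }))
  structure(list(per_rep = per_rep,
                 per_family = per_family %||% data.frame(),
                 mean_depth = mean_depth), class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat("depth_profile:", nrow(x$per_rep), "representatives,",
      nrow(x$per_family), "families; genome mean depth",
      sprintf("%.3f", x$mean_depth), "\n")
  invisible(x)
}

#' Annotate homologous LTR copies (solo LTRs and fragments) in a genome
#'
#' Seed-and-extend homology search of every library representative (both
#' orientations) against the genome. Accepted hits (identity >=
#' `min_identity`, aligned span >= `min_length`) are labeled:
#' `intact_member` when overlapping a supplied intact element,
#' `solo_ltr` when the hit covers most of the representative and carries
#' an exact 4-6 bp flanking duplication but no paired LTR, `fragment`
#' otherwise.
#'
#' @param genome genome to scan
#' @param library an `ltr_library`
#' @param intact optional `intact_elements` (or truth ledger rows) whose
#'   intervals mark intact members; needs `contig`/`start`/`end`
#' @param min_identity minimum alignment identity of a hit
#' @param min_length minimum hit span in bases
#' @param seed_k homology seed size (smaller than the detector's, to
#'   tolerate diverged copies)
#' @return data.frame: contig, start, end (0-based half-open), rep,
#'   family, strand, identity, label
#' @export
annotate_homologous_copies <- function(genome, library, intact = NULL,
                                       min_identity = 0.80,
                                       min_length = 100L, seed_k = 13L) {
  contigs <- as_contigs(genome)
  out <- list()
  for (cn in names(contigs)) {
    seq <- contigs[[cn]]
    n <- nchar(seq)
    gidx <- data.table::data.table(
      kmer = substring(seq, 1:(n - seed_k + 1L), seed_k:n),
      gpos = 0:(n - seed_k))
    data.table::setkeyv(gidx, "kmer")
    for (r in names(library$reps)) {
      for (strand in c("+", "-")) {
        rs <- if (strand == "+") library$reps[[r]]
              else revcomp(library$reps[[r]])
        m <- nchar(rs)
        if (m < seed_k) next
        ridx <- data.table::data.table(
          kmer = substring(rs, 1:(m - seed_k + 1L), seed_k:m),
          rpos = 0:(m - seed_k))
        mt <- gidx[ridx, on = "kmer", nomatch = NULL,
                   allow.cartesian = TRUE]
        if (nrow(mt) == 0) next
        mt$diag <- mt$gpos - mt$rpos
        data.table::setorderv(mt, c("diag", "gpos"))
        grp <- cumsum(c(TRUE, diff(mt$diag) > 25L | diff(mt$gpos) > 150L))
        cl <- mt[, list(g1 = min(gpos), g2 = max(gpos) + seed_k,
                        nseed = .N), by = list(grp = grp)]
        cl <- cl[cl$g2 - cl$g1 >= max(seed_k, min_length %/% 2L)]
        if (nrow(cl) == 0) next
        # merge overlapping clusters of this rep/strand
        cl <- cl[order(cl$g1), ]
        merged <- list(c(cl$g1[1], cl$g2[1]))
        for (i in seq_len(nrow(cl))[-1]) {
          last <- merged[[length(merged)]]
          if (cl$g1[i] <= last[2] + 50L) {
            merged[[length(merged)]] <- c(last[1], max(last[2], cl$g2[i]))
          } else merged[[length(merged) + 1L]] <- c(cl$g1[i], cl$g2[i])
        }
        for (iv in merged) {
          a <- max(0L, iv[1] - 30L); b <- min(n, iv[2] + 30L)
          al <- align_pair(rs, substr0(seq, a, b))
          span <- al$aligned_sites
          if (span < min_length || al$identity < min_identity) next
          out[[length(out) + 1L]] <- data.frame(
            contig = cn, start = a + al$b_start, end = a + al$b_end,
            rep = r,
            family = unname(library$family[r]), strand = strand,
            identity = al$identity, rep_coverage = span / nchar(rs),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), rep = character(),
                      family = character(), strand = character(),
                      identity = numeric(), rep_coverage = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, out)
  # collapse overlapping hits from different reps: keep highest identity
  hits <- hits[order(hits$contig, hits$start, -hits$identity), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j == i || !keep[j] || hits$contig[j] != hits$contig[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov > 0.5 * (hits$end[j] - hits$start[j]) &&
          hits$identity[j] <= hits$identity[i] && j > i)
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$label <- "fragment"
  if (!is.null(intact) && nrow(intact) > 0) {
    ic <- if ("contig" %in% names(intact)) intact$contig
          else rep(names(contigs)[1], nrow(intact))
    for (i in seq_len(nrow(hits))) {
      ovl <- ic == hits$contig[i] & intact$start < hits$end[i] &
        intact$end > hits$start[i]
      if (any(ovl)) hits$label[i] <- "intact_member"
    }
  }
  # a solo LTR covers most of its representative and keeps the host TSD
  # duplicated tightly around the hit boundaries; a small search window
  # keeps chance 4-mer duplications (which would mislabel fragments) rare
  for (i in seq_len(nrow(hits))) {
    if (hits$label[i] != "fragment") next
    if (hits$rep_coverage[i] < 0.8) next
    tsd <- find_tsd(contigs[[hits$contig[i]]], hits$start[i], hits$end[i],
                    w = 3L)
    if (!is.null(tsd)) hits$label[i] <- "solo_ltr"
  }
  rownames(hits) <- NULL
  hits
}

#' Per-family annotated sequence length totals
#'
#' @param annotations output of [annotate_homologous_copies()]
#' @return data.frame family, total_bases, n_hits
#' @export
family_sequence_lengths <- function(annotations) {
  if (nrow(annotations) == 0)
    return(data.frame(family = character(), total_bases = integer(),
                      n_hits = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(
    cbind(total_bases = annotations$end - annotations$start, n_hits = 1),
    by = list(family = annotations$family), FUN = sum)
  agg[order(agg$family), ]
}

#' Correlate the depth proxy with intact copy counts
#'
#' Pearson correlation between per-family normalized depth and per-family
#' intact counts -- the synthetic analogue of validating read depth as a
#' copy-number proxy. Requires >= 3 families; zero variance in either
#' vector leaves the result undefined and flagged.
#'
#' @param depth named numeric vector: family -> normalized depth
#' @param counts named numeric vector: family -> intact copy count
#' @return list: r, p_value, n, slope (depth ~ counts), flagged
#' @export
validate_depth_proxy <- function(depth, counts) {
  fams <- intersect(names(depth), names(counts))
  if (length(fams) < 3) stop("need at least 3 families")
  x <- as.numeric(counts[fams]); y <- as.numeric(depth[fams])
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(fams),
                slope = NA_real_, flagged = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(fams),
       slope = unname(coef(lm(y ~ x))[2]), flagged = FALSE)
}
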