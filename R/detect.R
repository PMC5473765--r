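# Structural detection of intact LTR retrotransposons: exact k-mer seeds
# anchor candidate direct-repeat pairs, ungapped x-drop extension delimits
# the two repeat copies, and a candidate is accepted only if an identical
# 4-6 bp target-site duplication flanks the refined outer boundaries and
# the two repeats align above the identity floor. No homology library is
# involved, so degraded copies are out of scope here (see the abundance
# module's homology annotator).

#' Detector configuration
#'
#' @param min_ltr,max_ltr accepted LTR length range (bases)
#' @param min_element,max_element accepted element length range (bases)
#' @param min_ltr_identity minimum alignment identity between the two LTRs
#' @param tsd_window how far (bases) boundary refinement may move each
#'   outer boundary while searching for the TSD
#' @param require_tg_ca also require the canonical TG...CA LTR termini
#' @param seed_k exact-match seed length; 20 keeps false seeds on random
#'   background negligible (~n^2/4^20 expected pairs)
#' @return object of class `detector_config`
#' @export
detector_config <- function(min_ltr = 100L, max_ltr = 3500L,
                            min_element = 1000L, max_element = 20000L,
                            min_ltr_identity = 0.75, tsd_window = 20L,
                            require_tg_ca = FALSE, seed_k = 20L) {
  stopifnot(min_ltr <= max_ltr, max_ltr < max_element,
            min_ltr_identity > 0, min_ltr_identity <= 1)
  structure(list(min_ltr = as.integer(min_ltr), max_ltr = as.integer(max_ltr),
                 min_element = as.integer(min_element),
                 max_element = as.integer(max_element),
                 min_ltr_identity = min_ltr_identity,
                 tsd_window = as.integer(tsd_window),
                 require_tg_ca = isTRUE(require_tg_ca),
                 seed_k = as.integer(seed_k)),
            class = "detector_config")
}

as_contigs <- function(genome) {
  if (inherits(genome, "synthetic_genome"))
    return(c(synthetic = genome$sequence))
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- paste0("contig", seq_along(genome))
    return(toupper(genome))
  }
  stop("genome must be a synthetic_genome or a (named) character vector")
}

# partners j > i with p[j] - p[i] in [dmin, dmax]; p sorted ascending
window_pairs <- function(p, dmin, dmax) {
  lo <- findInterval(p + dmin - 1L, p) + 1L
  hi <- findInterval(p + dmax, p)
  cnt <- pmax(0L, hi - lo + 1L)
  i <- rep.int(seq_along(p), cnt)
  keep <- cnt > 0L
  j <- sequence(cnt[keep], from = lo[keep])
  list(i = p[i], j = p[j])
}

# search for an exact 4-6 bp duplication flanking [s5, e3); boundaries may
# move by at most w. Candidates are ranked by TSD length, then -- when the
# repeat diagonal `d` is known -- by how well the implied LTR boundaries
# match between the two repeat copies (a shifted boundary drags random
# flank/internal bases into the comparison), then by the smallest shift.
# Returns NULL or list(da, db, tsd).
find_tsd <- function(seq, s5, e3, w, require_tg_ca = FALSE, d = NULL) {
  n <- nchar(seq)
  grid <- expand.grid(L = 6:4, da = -w:w, db = -w:w,
                      KEEP.OUT.ATTRS = FALSE)
  ls <- s5 + grid$da          # candidate element start
  re <- e3 + grid$db          # candidate element end
  ok <- ls - grid$L >= 0 & re + grid$L <= n & ls < re
  grid <- grid[ok, ]; ls <- ls[ok]; re <- re[ok]
  if (nrow(grid) == 0) return(NULL)
  left <- substring(seq, ls - grid$L + 1L, ls)
  right <- substring(seq, re + 1L, re + grid$L)
  hit <- left == right & !grepl("N", left, fixed = TRUE)
  if (require_tg_ca) {
    hit <- hit & substring(seq, ls + 1L, ls + 2L) == "TG" &
      substring(seq, re - 1L, re) == "CA"
  }
  if (!any(hit)) return(NULL)
  grid <- grid[hit, ]; left <- left[hit]; ls <- ls[hit]; re <- re[hit]
  # contrast score: repeat-pair columns just inside the implied element
  # are correlated (LTR vs LTR), columns just outside are not; the true
  # boundary maximizes inside-matches minus outside-matches on both ends
  bscore <- rep(0L, nrow(grid))
  if (!is.null(d)) {
    m <- 12L
    pair_matches <- function(from, to) {
      if (from < 0 || to + d > n || to <= from) return(NA_integer_)
      len <- to - from
      len - hamming_count(substr0(seq, from, to),
                          substr0(seq, from + d, to + d))
    }
    for (i in seq_len(nrow(grid))) {
      a5 <- ls[i]                 # implied ltr5 start
      e5 <- re[i] - d             # implied ltr5 end
      if (e5 - a5 < m) next
      in5 <- pair_matches(a5, a5 + m)
      out5 <- pair_matches(a5 - m, a5)
      in3 <- pair_matches(e5 - m, e5)
      out3 <- pair_matches(e5, e5 + m)
      parts <- c(in5, -out5, in3, -out3)
      bscore[i] <- sum(parts[!is.na(parts)])
    }
  }
  # boundary correctness first: a spurious longer duplication at a shifted
  # offset must not beat the true TSD at the contrast-optimal boundary
  pick <- order(-bscore, -grid$L, abs(grid$da) + abs(grid$db),
                grid$da, grid$db)[1]
  list(da = grid$da[pick], db = grid$db[pick], tsd = left[pick])
}

#' Find intact LTR retrotransposons by direct-repeat structure
#'
#' Indexes each contig with exact `seed_k`-mers, pairs seed matches whose
#' separation is compatible with the element length bounds, chains seeds on
#' a common diagonal into candidate repeat pairs, delimits both repeat
#' copies by ungapped x-drop extension, refines the outer boundaries to the
#' offsets carrying an identical 4-6 bp target-site duplication, and keeps
#' candidates whose repeats align at `min_ltr_identity` or better.
#' Overlapping calls are resolved deterministically (longer TSD, then
#' higher LTR identity, then leftmost) unless one element lies fully inside
#' the other's internal region (a nested insertion, which is kept).
#'
#' @param genome a `synthetic_genome`, or a (named) character vector of
#'   contig sequences over A/C/G/T/N
#' @param config a [detector_config()]
#' @return data.frame of class `intact_elements`, ordered by contig and
#'   start, with 0-based half-open coordinates for the element, both LTRs
#'   and the internal region, the TSD string and the LTR alignment identity
#' @export
find_intact_elements <- function(genome, config = detector_config()) {
  contigs <- as_contigs(genome)
  out <- lapply(names(contigs), function(nm)
    detect_contig(contigs[[nm]], nm, config))
  res <- do.call(rbind, c(out, list(empty_elements())))
  res <- res[order(res$contig, res$start), , drop = FALSE]
  if (nrow(res) > 0)
    res$element_id <- sprintf("E%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  class(res) <- c("intact_elements", "data.frame")
  attr(res, "config") <- config
  res
}

empty_elements <- function() {
  data.frame(element_id = character(), contig = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             tsd = character(), strand = character(),
             ltr_identity = numeric(), stringsAsFactors = FALSE)
}

detect_contig <- function(seq, contig, config) {
  k <- config$seed_k
  n <- nchar(seq)
  if (n < config$min_element) return(empty_elements())
  # element length = diagonal + LTR length, so the diagonal is bounded by
  d_min <- max(config$min_ltr, config$min_element - config$max_ltr)
  d_max <- config$max_element - config$min_ltr

  km <- substring(seq, 1:(n - k + 1L), k:n)
  dt <- data.table::data.table(kmer = km, pos = 0:(n - k))
  dt <- dt[!grepl("N", dt$kmer, fixed = TRUE)]
  cnt <- dt[, .N, by = "kmer"]
  dup <- cnt$kmer[cnt$N >= 2L & cnt$N <= 2000L]
  if (length(dup) == 0) return(empty_elements())
  dt <- dt[dt$kmer %in% dup]
  data.table::setorderv(dt, c("kmer", "pos"))
  pr <- dt[, window_pairs(pos, d_min, d_max), by = "kmer"]
  if (nrow(pr) == 0) return(empty_elements())
  pr <- unique(pr[, c("i", "j")])
  pr$d <- pr$j - pr$i
  data.table::setorderv(pr, c("d", "i"))

  gap_max <- 200L
  grp <- cumsum(c(TRUE, diff(pr$d) != 0L | diff(pr$i) > gap_max))
  cand <- pr[, list(s_min = min(i), s_max = max(i) + k, nseed = .N),
             by = list(grp = grp, d = d)]
  cand <- cand[cand$nseed >= 2L &
                 cand$s_max - cand$s_min >= max(50L, config$min_ltr %/% 2L)]
  if (nrow(cand) == 0) return(empty_elements())

  ext <- extend_repeat_batch(seq, cand$s_min, cand$s_min + cand$d,
                             cand$s_max - cand$s_min)
  a <- cand$s_min - ext[, 1]
  b <- cand$s_max + ext[, 2]
  d <- cand$d

  hits <- list()
  for (c_i in seq_len(nrow(cand))) {
    lw <- b[c_i] - a[c_i]
    if (lw < config$min_ltr - config$tsd_window ||
        lw > config$max_ltr + config$tsd_window) next
    el <- d[c_i] + lw
    if (el < config$min_element - 2L * config$tsd_window ||
        el > config$max_element + 2L * config$tsd_window) next
    tsd <- find_tsd(seq, a[c_i], b[c_i] + d[c_i], config$tsd_window,
                    config$require_tg_ca, d = d[c_i])
    if (is.null(tsd)) next
    s5 <- a[c_i] + tsd$da          # refined ltr5 start
    e5 <- b[c_i] + tsd$db          # refined ltr5 end
    lw2 <- e5 - s5
    if (lw2 < config$min_ltr || lw2 > config$max_ltr || lw2 > d[c_i]) next
    el2 <- d[c_i] + lw2
    if (el2 < config$min_element || el2 > config$max_element) next
    ident <- align_pair(substr0(seq, s5, e5),
                        substr0(seq, s5 + d[c_i], e5 + d[c_i]))$identity
    if (ident < config$min_ltr_identity) next
    # chimera guard: pairing the LTRs of two adjacent same-family copies
    # leaves additional near-full LTR copies inside the "internal" region
    if (ltr_in_internal(seq, s5, e5, s5 + d[c_i]) >= 0.5) next
    hits[[length(hits) + 1L]] <- data.frame(
      element_id = NA_character_, contig = contig,
      start = s5, end = e5 + d[c_i],
      ltr5_start = s5, ltr5_end = e5,
      ltr3_start = s5 + d[c_i], ltr3_end = e5 + d[c_i],
      tsd = tsd$tsd, strand = "+", ltr_identity = ident,
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0) return(empty_elements())
  res <- do.call(rbind, hits)
  resolve_overlaps(res)
}

# fraction of the candidate's own LTR length found again (as exact
# 12-mers) inside its internal region; ~0 for genuine elements, large for
# chimeric calls that span two neighbouring copies of one family
ltr_in_internal <- function(seq, s5, e5, s3) {
  k <- 12L
  lw <- e5 - s5
  int_len <- s3 - e5
  if (int_len < k || lw < k) return(0)
  ltr <- substr0(seq, s5, e5)
  inr <- substr0(seq, e5, s3)
  lk <- unique(substring(ltr, 1:(nchar(ltr) - k + 1L), k:nchar(ltr)))
  ik <- substring(inr, 1:(nchar(inr) - k + 1L), k:nchar(inr))
  m <- ik %in% lk
  covered <- logical(nchar(inr))
  for (p in which(m)) covered[p:(p + k - 1L)] <- TRUE
  sum(covered) / lw
}

# drop the worse of two overlapping calls unless one is fully nested in the
# other's internal region; ranking: longer TSD, higher identity, leftmost
resolve_overlaps <- function(res) {
  res <- unique(res)
  o <- order(-nchar(res$tsd), -res$ltr_identity, res$start)
  res <- res[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(res))) {
      if (i == j || !keep[j]) next
      overlaps <- res$start[j] < res$end[i] & res$end[j] > res$start[i]
      if (!overlaps) next
      nested <- (res$start[j] >= res$ltr5_end[i] &
                   res$end[j] <= res$ltr3_start[i]) ||
        (res$start[i] >= res$ltr5_end[j] & res$end[i] <= res$ltr3_start[j])
      if (!nested && j > i) keep[j] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

#' Drop tandem-array false positives
#'
#' A long tandem repeat can masquerade as an LTR pair whose "internal"
#' region is just more copies of the repeat unit. A candidate is dropped
#' when at least `max_cover` of its internal region is covered by 12-mers
#' of its own 5' LTR. True elements score near zero because their internal
#' region shares no repeat unit with the LTR; strongly diverged tandem
#' arrays can escape the filter (documented limitation).
#'
#' @param candidates `intact_elements` from [find_intact_elements()]
#' @param genome same genome the candidates were called on
#' @param max_cover coverage fraction above which a candidate is dropped
#' @return filtered `intact_elements`
#' @export
remove_tandem_false_positives <- function(candidates, genome,
                                          max_cover = 0.8) {
  if (nrow(candidates) == 0) return(candidates)
  contigs <- as_contigs(genome)
  k <- 12L
  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    e <- candidates[i, ]
    seq <- contigs[[e$contig]]
    int_len <- e$ltr3_start - e$ltr5_end
    if (int_len < k) return(FALSE)     # no internal region: pure tandem
    ltr <- substr0(seq, e$ltr5_start, e$ltr5_end)
    inr <- substr0(seq, e$ltr5_end, e$ltr3_start)
    lk <- unique(substring(ltr, 1:(nchar(ltr) - k + 1L), k:nchar(ltr)))
    ik <- substring(inr, 1:(nchar(inr) - k + 1L), k:nchar(inr))
    m <- ik %in% lk
    covered <- logical(nchar(inr))
    for (p in which(m)) covered[p:(p + k - 1L)] <- TRUE
    mean(covered) < max_cover
  }, logical(1))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("intact_elements", "data.frame")
  out
}

#' Extract element sequences from the genome
#'
#' @param elements an `intact_elements` data.frame
#' @param genome the genome the elements were called on
#' @return list of named character vectors `ltr5`, `ltr3`, `internal`,
#'   keyed by element id
#' @export
element_sequences <- function(elements, genome) {
  contigs <- as_contigs(genome)
  grab <- function(s, e) {
    vapply(seq_len(nrow(elements)), function(i)
      substr0(contigs[[elements$contig[i]]], elements[[s]][i],
              elements[[e]][i]),
      character(1))
  }
  n <- nrow(elements)
  out <- list(
    ltr5 = if (n) grab("ltr5_start", "ltr5_end") else character(),
    ltr3 = if (n) grab("ltr3_start", "ltr3_end") else character(),
    internal = if (n) grab("ltr5_end", "ltr3_start") else character())
  for (nm in names(out)) names(out[[nm]]) <- elements$element_id
  out
}

#' Convert intact elements to GFF3 features
#'
#' Emits, per element, a parent `LTR_retrotransposon` feature, two
#' `long_terminal_repeat` children, and one `target_site_duplication`
#' feature (the 5' flank copy). Coordinates are 1-based inclusive.
#'
#' @param elements `intact_elements`
#' @return data.frame accepted by [gff3_write()]
#' @export
elements_to_gff <- function(elements) {
  if (nrow(elements) == 0) {
    return(gff3_read_empty())
  }
  rows <- lapply(seq_len(nrow(elements)), function(i) {
    e <- elements[i, ]
    tl <- nchar(e$tsd)
    data.frame(
      seqid = e$contig, source = "retrochrono",
      type = c("LTR_retrotransposon", "long_terminal_repeat",
               "long_terminal_repeat", "target_site_duplication"),
      start = c(e$start + 1L, e$ltr5_start + 1L, e$ltr3_start + 1L,
                e$start - tl + 1L),
      end = c(e$end, e$ltr5_end, e$ltr3_end, e$start),
      score = c(sprintf("%.4f", e$ltr_identity), ".", ".", "."),
      strand = e$strand, phase = ".",
      attributes = c(sprintf("ID=%s", e$element_id),
                     sprintf("Parent=%s", e$element_id),
                     sprintf("Parent=%s", e$element_id),
                     sprintf("Parent=%s;tsd=%s", e$element_id, e$tsd)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

gff3_read_empty <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character(), stringsAsFactors = FALSE)
}
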