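# Molecular-clock dating of insertions. An element's two LTRs are
# identical at insertion; their divergence K accumulates at 2r per year
# (r on each branch), so the insertion age is T = K / (2r). Divergence is
# estimated from an end-gap-free global alignment of the LTR pair, with
# gap columns excluded, and corrected for multiple hits with the JC69
# closed form by default.

#' Molecular clock configuration
#'
#' @param rate substitution rate r, per site per year; the default
#'   1.3e-8 is the canonical rice LTR rate
#' @param correction "jukes_cantor" (default) or "raw_p"
#' @param min_aligned_sites minimum gap-free aligned columns for an
#'   element to be datable
#' @export
clock_config <- function(rate = 1.3e-8,
                         correction = c("jukes_cantor", "raw_p"),
                         min_aligned_sites = 50L) {
  correction <- match.arg(correction)
  stopifnot(rate > 0)
  structure(list(rate = rate, correction = correction,
                 min_aligned_sites = as.integer(min_aligned_sites)),
            class = "clock_config")
}

#' Observed divergence between an element's two LTRs
#'
#' Global alignment with free end gaps; p is the mismatch proportion over
#' the gap-free aligned columns.
#'
#' @param ltr5,ltr3 nucleotide strings
#' @return list with `p` and `aligned_sites`
#' @export
ltr_pair_divergence <- function(ltr5, ltr3) {
  al <- align_pair(ltr5, ltr3)
  list(p = al$p, aligned_sites = al$aligned_sites)
}

#' Correct observed divergence for multiple hits
#'
#' Jukes-Cantor closed form K = -3/4 log(1 - 4p/3); `raw_p` returns p
#' unchanged (a sensitivity mode). Under JC the correction is undefined
#' for p >= 0.75 and NA is returned (the element is undatable).
#'
#' @param p observed mismatch proportion
#' @param correction "jukes_cantor" or "raw_p"
#' @return corrected divergence K (per site), NA if undefined
#' @export
correct_divergence <- function(p, correction = "jukes_cantor") {
  if (correction == "raw_p") return(p)
  ifelse(p < 0.75, jc_correct(p), NA_real_)
}

#' Insertion time from divergence
#'
#' T = K / (2 r): both LTRs accumulate substitutions independently, so
#' their pairwise divergence grows at twice the clock rate.
#'
#' @param K corrected divergence per site
#' @param config a [clock_config()]
#' @return age in years
#' @export
insertion_time <- function(K, config = clock_config()) {
  K / (2 * config$rate)
}

#' Date a set of intact elements
#'
#' Applies [ltr_pair_divergence()], [correct_divergence()] and
#' [insertion_time()] to every element. Elements without a TSD are not
#' datable (the TSD certifies a genuine insertion) and neither are
#' elements with fewer aligned sites than `min_aligned_sites` or with p
#' beyond the JC domain; these receive `datable = FALSE` and NA estimates.
#'
#' @param elements `intact_elements` (needs a `tsd` column)
#' @param genome genome to extract LTR sequences from, or NULL if `seqs`
#'   is supplied
#' @param config a [clock_config()]
#' @param seqs optional list as from [element_sequences()]
#' @return data.frame: element_id, p, K, T, aligned_sites, datable
#' @export
date_elements <- function(elements, genome = NULL, config = clock_config(),
                          seqs = NULL) {
  if (is.null(seqs)) seqs <- element_sequences(elements, genome)
  n <- nrow(elements)
  out <- data.frame(element_id = elements$element_id,
                    p = NA_real_, K = NA_real_, T = NA_real_,
                    aligned_sites = NA_integer_, datable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(elements$tsd[i]) || !nzchar(elements$tsd[i])) next
    dv <- ltr_pair_divergence(seqs$ltr5[[i]], seqs$ltr3[[i]])
    out$p[i] <- dv$p
    out$aligned_sites[i] <- dv$aligned_sites
    if (is.na(dv$p) || dv$aligned_sites < config$min_aligned_sites) next
    K <- correct_divergence(dv$p, config$correction)
    if (is.na(K)) next
    out$K[i] <- K
    out$T[i] <- insertion_time(K, config)
    out$datable[i] <- TRUE
  }
  out
}

#' Per-family insertion-age summaries
#'
#' @param dates data.frame from [date_elements()] (datable rows are used)
#' @param membership named vector element id -> family id
#' @param cap_my optional display cap in million years: ages above the cap
#'   are truncated in the `display_*` columns only, never in the stored
#'   ages (mirrors capping very old insertions at the plot margin)
#' @return data.frame per family: n, mean, min, q05, q25, q75, q95, max
#'   (years), plus display_mean if `cap_my` is set
#' @export
summarize_family_ages <- function(dates, membership, cap_my = NULL) {
  ok <- dates$datable
  fam <- membership[dates$element_id[ok]]
  ages <- dates$T[ok]
  fams <- sort(unique(fam))
  out <- do.call(rbind, lapply(fams, function(f) {
    a <- ages[fam == f]
    q <- quantile(a, c(0.05, 0.25, 0.75, 0.95), names = FALSE, type = 7)
    data.frame(family_id = f, n = length(a), mean = mean(a), min = min(a),
               q05 = q[1], q25 = q[2], q75 = q[3], q95 = q[4], max = max(a),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(family_id = character(), n = integer(),
                      mean = numeric(), min = numeric(), q05 = numeric(),
                      q25 = numeric(), q75 = numeric(), q95 = numeric(),
                      max = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.null(cap_my)) {
    cap <- cap_my * 1e6
    capped <- lapply(fams, function(f) pmin(ages[fam == f], cap))
    out$display_mean <- vapply(capped, mean, numeric(1))
  }
  rownames(out) <- NULL
  out
}
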