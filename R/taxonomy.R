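# Superfamily classification and family clustering.
#
# Ty1-copia and Ty3-gypsy differ by pol-domain order (PR-IN-RT versus
# PR-RT-IN); elements without a recognizable pol complement are
# "unclassified". Families are connected components of the 5'-LTR identity
# graph (single linkage): two elements are linked when their LTRs align at
# > min_identity over >= min_reciprocal_coverage of both LTR lengths.

#' Family clustering thresholds
#'
#' Defaults follow the classical family criterion: identity strictly above
#' 80% over at least 50% of both 5'-LTRs.
#'
#' @param min_identity identity threshold (strict inequality)
#' @param min_reciprocal_coverage required aligned fraction of both LTRs
#' @export
clustering_config <- function(min_identity = 0.80,
                              min_reciprocal_coverage = 0.50) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_reciprocal_coverage > 0, min_reciprocal_coverage <= 1)
  structure(list(min_identity = min_identity,
                 min_reciprocal_coverage = min_reciprocal_coverage),
            class = "clustering_config")
}

translate_frames <- function(nt) {
  n <- nchar(nt)
  if (n < 3) return(list())
  rc <- revcomp(nt)
  out <- list()
  for (f in 1:3) {
    len <- ((n - f + 1L) %/% 3L) * 3L
    if (len < 3) next
    out[[paste0("+", f)]] <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(nt, f, f + len - 1L)),
      if.fuzzy.codon = "solve"))
    out[[paste0("-", f)]] <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(rc, f, f + len - 1L)),
      if.fuzzy.codon = "solve"))
  }
  out
}

#' Scan an internal region for gag/pol domains
#'
#' Six-frame translation of the internal region followed by local protein
#' alignment (BLOSUM62) against user-supplied amino-acid references for
#' each domain. The best hit per domain above `min_score` and covering at
#' least `min_coverage` of the reference is kept; hits of different
#' domains overlapping on the nucleotide sequence are resolved by score.
#'
#' @param internal nucleotide string (the region between the two LTRs)
#' @param references named list keyed by domain (GAG/PR/IN/RT), each a
#'   named character vector of amino-acid reference sequences; synthetic
#'   runs can use [domain_references()]
#' @param min_score minimum Smith-Waterman BLOSUM62 score
#' @param min_coverage minimum aligned fraction of the reference
#' @return data.frame of domain hits ordered by coordinate: domain, start,
#'   end (0-based on the internal region), score, frame (e.g. "+2"),
#'   strand, ref, ref_coverage
#' @export
scan_domains <- function(internal, references, min_score = 100,
                         min_coverage = 0.30) {
  stopifnot(length(references) > 0, all(lengths(references) > 0))
  empty <- data.frame(domain = character(), start = integer(),
                      end = integer(), score = numeric(),
                      frame = character(), strand = character(),
                      ref = character(), ref_coverage = numeric(),
                      stringsAsFactors = FALSE)
  n <- nchar(internal)
  frames <- translate_frames(internal)
  if (length(frames) == 0) return(empty)
  hits <- empty
  for (domain in names(references)) {
    best <- NULL
    refs <- references[[domain]]
    for (ri in seq_along(refs)) {
      for (fr in names(frames)) {
        al <- align_protein_local(frames[[fr]], refs[[ri]])
        if (al$score < min_score || al$ref_coverage < min_coverage) next
        if (is.null(best) || al$score > best$score) {
          f <- as.integer(substr(fr, 2, 2))
          strand <- substr(fr, 1, 1)
          nt_s <- (f - 1L) + 3L * al$q_start
          nt_e <- (f - 1L) + 3L * al$q_end
          if (strand == "-") { tmp <- nt_s; nt_s <- n - nt_e; nt_e <- n - tmp }
          best <- list(score = al$score, start = nt_s, end = nt_e,
                       frame = fr, strand = strand,
                       ref = names(refs)[ri] %||% as.character(ri),
                       ref_coverage = al$ref_coverage)
        }
      }
    }
    if (!is.null(best)) {
      hits <- rbind(hits, data.frame(
        domain = domain, start = best$start, end = best$end,
        score = best$score, frame = best$frame, strand = best$strand,
        ref = best$ref, ref_coverage = best$ref_coverage,
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits) == 0) return(empty)
  # resolve cross-domain overlaps by score
  hits <- hits[order(-hits$score), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(hits))) {
      if (j <= i || !keep[j]) next
      if (hits$start[j] < hits$end[i] && hits$end[j] > hits$start[i])
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Classify an element into a superfamily from its domain hits
#'
#' Reads the pol-domain order along the element (coordinate order,
#' reversed when the coding strand is minus): PR before IN before RT is
#' Ty1-copia, PR before RT before IN is Ty3-gypsy; a missing RT (or any
#' other order/subset) is unclassified, covering elements that lack pol.
#'
#' @param hits data.frame from [scan_domains()] (may have zero rows)
#' @return one of "copia", "gypsy", "unclassified"
#' @export
classify_superfamily <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return("unclassified")
  strand <- names(sort(table(hits$strand), decreasing = TRUE))[1]
  ord <- hits[order(hits$start), "domain"]
  if (strand == "-") ord <- rev(ord)
  pol <- ord[ord %in% c("PR", "IN", "RT")]
  if (identical(pol, c("PR", "IN", "RT"))) return("copia")
  if (identical(pol, c("PR", "RT", "IN"))) return("gypsy")
  "unclassified"
}

union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  list(find = find,
       union = function(a, b) parent[find(a)] <<- find(b))
}

#' Cluster intact elements into families by 5'-LTR identity
#'
#' Single-linkage clustering over the pairwise 5'-LTR alignment graph
#' (the semantics of all-against-all clustering tools): an edge joins two
#' elements iff alignment identity exceeds `min_identity` and the aligned
#' span covers at least `min_reciprocal_coverage` of BOTH LTRs; connected
#' components are families. Family superfamily is the majority vote of
#' member superfamilies (ties break to "unclassified").
#'
#' @param elements `intact_elements`; if a `superfamily` column is present
#'   it feeds the family-level vote
#' @param genome the genome the elements were called on (for LTR
#'   extraction), or NULL if `ltr5` is given
#' @param config a [clustering_config()]
#' @param ltr5 optional named character vector of 5'-LTR sequences keyed
#'   by element id, overriding extraction from `genome`
#' @return object of class `family_set`: `families` data.frame (family_id,
#'   superfamily, n_intact, members as comma-joined ids) and `membership`
#'   (named vector element id -> family id)
#' @export
cluster_families <- function(elements, genome = NULL,
                             config = clustering_config(), ltr5 = NULL) {
  if (is.null(ltr5)) {
    stopifnot(!is.null(genome))
    ltr5 <- element_sequences(elements, genome)$ltr5
  }
  ids <- elements$element_id
  stopifnot(all(ids %in% names(ltr5)))
  n <- length(ids)
  uf <- union_find(n)
  # 11-mer prefilter: a pair that could pass identity > 0.8 over half of
  # both LTRs shares >> 2% of its words, so pairs below that are skipped
  # without alignment
  kw <- 11L
  kset <- function(s) {
    if (nchar(s) < kw) return(character(0))
    unique(substring(s, 1:(nchar(s) - kw + 1L), kw:nchar(s)))
  }
  ks_f <- lapply(ids, function(id) kset(ltr5[[id]]))
  ks_r <- lapply(ids, function(id) kset(revcomp(ltr5[[id]])))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        shr <- max(mean(ks_f[[j]] %in% ks_f[[i]]),
                   mean(ks_r[[j]] %in% ks_f[[i]]), 0, na.rm = TRUE)
        if (shr < 0.02) next
        al <- align_pair_both_strands(ltr5[[ids[i]]], ltr5[[ids[j]]])
        if (al$identity > config$min_identity &&
            al$coverage_a >= config$min_reciprocal_coverage &&
            al$coverage_b >= config$min_reciprocal_coverage)
          uf$union(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n), uf$find, integer(1))
  # stable component labels: order of first appearance along sorted ids
  comp <- match(comp, unique(comp))
  sf <- if ("superfamily" %in% names(elements)) elements$superfamily
        else rep("unclassified", n)
  fam_ids <- sprintf("F%03d", seq_len(max(comp, 0)))
  families <- do.call(rbind, lapply(seq_len(max(comp, 0)), function(f) {
    m <- ids[comp == f]
    votes <- table(sf[comp == f])
    top <- votes[votes == max(votes)]
    famsf <- if (length(top) > 1) "unclassified" else names(top)
    data.frame(family_id = fam_ids[f], superfamily = famsf,
               n_intact = length(m),
               members = paste(sort(m), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(families)) {
    families <- data.frame(family_id = character(),
                           superfamily = character(), n_intact = integer(),
                           members = character(), stringsAsFactors = FALSE)
  }
  structure(list(families = families,
                 membership = setNames(fam_ids[comp], ids),
                 config = config),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat("family_set:", nrow(x$families), "families over",
      length(x$membership), "elements\n")
  invisible(x)
}

#' Rank, name, and copy-classify families
#'
#' Families are sorted by descending intact-copy count in the reference
#' genome (all elements, if no per-genome labels are supplied), ties by
#' total count then by smallest member id, and renamed OAL001, OAL002, ...
#' Copy classes follow the printed bounds: high-copy (>20), low-copy
#' (2-20), single-copy.
#'
#' @param famset a `family_set`
#' @param genome_of optional named vector mapping element id -> genome
#'   label, for multi-genome runs
#' @param reference_genome label whose counts drive the ranking
#' @return `family_set` with families renamed, ranked, and annotated with
#'   `rank` and `copy_class`
#' @export
name_and_rank_families <- function(famset, genome_of = NULL,
                                   reference_genome = NULL) {
  fams <- famset$families
  if (nrow(fams) == 0) return(famset)
  members <- strsplit(fams$members, ",", fixed = TRUE)
  ref_count <- if (is.null(genome_of) || is.null(reference_genome)) {
    fams$n_intact
  } else {
    vapply(members, function(m)
      sum(genome_of[m] == reference_genome), integer(1))
  }
  first_member <- vapply(members, function(m) sort(m)[1], character(1))
  o <- order(-ref_count, -fams$n_intact, first_member)
  fams <- fams[o, , drop = FALSE]
  old <- fams$family_id
  fams$family_id <- sprintf("OAL%03d", seq_len(nrow(fams)))
  fams$rank <- seq_len(nrow(fams))
  fams$copy_class <- ifelse(fams$n_intact > 20, "high",
                            ifelse(fams$n_intact >= 2, "low", "single"))
  rownames(fams) <- NULL
  remap <- setNames(fams$family_id, old)
  famset$families <- fams
  famset$membership <- setNames(remap[famset$membership],
                                names(famset$membership))
  famset
}
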