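# Neighbor-joining phylogenies of reverse-transcriptase (RT) domains.
# Distances are uncorrected p-distances on aligned sequences (amino acids
# by default); trees are unrooted, with the classical Q-criterion join
# selection and branch-length formulas, and deterministic tie-breaking.

#' Extract the RT amino-acid sequence of an element
#'
#' Translates the RT hit interval in the hit's frame; minus-strand hits
#' are reverse-complemented first. Internal stop codons are counted and
#' reported (a decayed element may have them).
#'
#' @param internal internal-region nucleotide string
#' @param rt_hit one row of [scan_domains()] output with domain == "RT"
#' @return list with `aa` (amino-acid string) and `internal_stops`
#' @export
extract_rt <- function(internal, rt_hit) {
  stopifnot(nrow(rt_hit) == 1, rt_hit$domain == "RT")
  n <- nchar(internal)
  if (rt_hit$strand == "-") {
    rc <- revcomp(internal)
    nt <- substr0(rc, n - rt_hit$end, n - rt_hit$start)
  } else {
    nt <- substr0(internal, rt_hit$start, rt_hit$end)
  }
  nt <- substr(nt, 1, (nchar(nt) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "solve"))
  core <- substr(aa, 1, nchar(aa) - 1L)   # a trailing stop is not internal
  list(aa = aa, internal_stops = lengths(regmatches(
    core, gregexpr("*", core, fixed = TRUE))))
}

#' Center-star multiple alignment
#'
#' Greedy progressive alignment: the longest sequence (ties: first) is the
#' center; every other sequence is aligned to it globally and the pairwise
#' gap patterns are merged into one master profile. Exact for gap-free
#' sequence sets of equal length; adequate as a guide alignment for RT
#' sets, which is its only role here.
#'
#' @param seqs named character vector (>= 2 sequences)
#' @param type "protein" (BLOSUM62) or "dna"
#' @return named character vector of aligned rows (equal lengths)
#' @export
align_center_star <- function(seqs, type = c("protein", "dna")) {
  type <- match.arg(type)
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ci <- which.max(nchar(seqs))
  center <- seqs[[ci]]
  others <- setdiff(seq_along(seqs), ci)
  if (type == "protein") {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    args <- list(substitutionMatrix = BLOSUM62, gapOpening = 10,
                 gapExtension = 1)
    as_x <- Biostrings::AAString
  } else {
    args <- list(substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE), gapOpening = 6,
      gapExtension = 1)
    as_x <- Biostrings::DNAString
  }
  pair_aln <- lapply(others, function(i) {
    aln <- do.call(Biostrings::pairwiseAlignment,
                   c(list(as_x(seqs[[i]]), as_x(center), type = "global"),
                     args))
    list(row = as.character(Biostrings::alignedPattern(aln)),
         cen = as.character(Biostrings::alignedSubject(aln)))
  })
  # master profile: max gaps inserted before each center column (and after
  # the last) across the pairwise alignments
  nc <- nchar(center)
  gaps_before <- integer(nc + 1L)
  split_by_center <- function(cen_aln) {
    # run lengths of '-' preceding each center residue
    chars <- strsplit(cen_aln, "", fixed = TRUE)[[1]]
    out <- integer(nc + 1L)
    col <- 1L; run <- 0L
    for (ch in chars) {
      if (ch == "-") run <- run + 1L
      else { out[col] <- run; run <- 0L; col <- col + 1L }
    }
    out[nc + 1L] <- run
    out
  }
  per_aln_gaps <- lapply(pair_aln, function(pa) split_by_center(pa$cen))
  for (g in per_aln_gaps) gaps_before <- pmax(gaps_before, g)
  # rebuild each row on the master profile by walking its pairwise
  # alignment while tracking the center column index
  build_row <- function(row_aln, cen_aln) {
    rchars <- strsplit(row_aln, "", fixed = TRUE)[[1]]
    cchars <- strsplit(cen_aln, "", fixed = TRUE)[[1]]
    segs <- vector("list", nc + 1L)   # residues of row per center slot
    for (s in seq_len(nc + 1L)) segs[[s]] <- character(0)
    col <- 1L
    for (t in seq_along(cchars)) {
      if (cchars[t] == "-") {
        segs[[col]] <- c(segs[[col]], rchars[t])
      } else {
        segs[[col]] <- c(segs[[col]], rchars[t])
        col <- col + 1L
      }
    }
    # segment for center column c holds (gap-run residues + the residue
    # aligned to center residue c); pad each gap run to the master width
    out <- character(nc + 1L)
    for (s in seq_len(nc)) {
      seg <- segs[[s]]
      run <- seg[-length(seg)]
      res <- seg[length(seg)]
      out[s] <- paste0(strrep("-", gaps_before[s] - length(run)),
                       paste(run, collapse = ""), res)
    }
    out[nc + 1L] <- paste0(paste(segs[[nc + 1L]], collapse = ""),
                           strrep("-", gaps_before[nc + 1L] -
                                    length(segs[[nc + 1L]])))
    paste(out, collapse = "")
  }
  res <- character(length(seqs))
  cen_row <- paste(vapply(seq_len(nc), function(s)
    paste0(strrep("-", gaps_before[s]), substr(center, s, s)),
    character(1)), collapse = "")
  cen_row <- paste0(cen_row, strrep("-", gaps_before[nc + 1L]))
  res[ci] <- cen_row
  for (t in seq_along(others)) {
    res[others[t]] <- build_row(pair_aln[[t]]$row, pair_aln[[t]]$cen)
  }
  names(res) <- names(seqs)
  res
}

#' Uncorrected pairwise distance matrix from an alignment
#'
#' Distance = mismatches / gap-free shared columns. Pairs with zero shared
#' columns are undefined (NA) and flagged with a warning.
#'
#' @param aligned named character vector of equal-length alignment rows
#' @return symmetric numeric matrix with dimnames; attribute `shared`
#'   carries the shared-column counts
#' @export
p_distance_matrix <- function(aligned) {
  if (length(aligned) < 2) stop("need at least two sequences")
  if (length(unique(nchar(aligned))) != 1)
    stop("alignment rows differ in length")
  if (is.null(names(aligned)))
    names(aligned) <- paste0("seq", seq_along(aligned))
  st <- pdist_pairs(unname(aligned))
  d <- st$d
  dimnames(d) <- list(names(aligned), names(aligned))
  if (anyNA(d[upper.tri(d)]))
    warning("some pairs share no gap-free columns; distances undefined")
  attr(d, "shared") <- st$shared
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical NJ: at each step the pair minimizing
#' Q(i,j) = (N-2) d(i,j) - R(i) - R(j) is joined, with ties broken by the
#' smallest pair of current indices; branch lengths follow the standard
#' formulas and negative estimates are clamped to zero (total clamped
#' deficit stored in the `clamped` attribute). On an additive matrix the
#' generating tree is recovered exactly.
#'
#' @param d symmetric numeric matrix with zero diagonal (labels in
#'   dimnames), n >= 3
#' @return an unrooted `ape::phylo` tree
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is asymmetric")
  if (any(d < -1e-12)) stop("negative distances")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # each active cluster is a newick fragment
  frag <- labels
  clamped <- 0
  fmt <- function(x) {
    if (x < 0) { clamped <<- clamped + (-x); x <- 0 }
    sprintf("%.12g", x)
  }
  while (nrow(d) > 3) {
    N <- nrow(d)
    R <- rowSums(d)
    Q <- (N - 2) * d - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (N - 2))
    vj <- d[i, j] - vi
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",",
                      frag[j], ":", fmt(vj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    d <- d2
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(v1), ",", frag[2], ":", fmt(v2),
                ",", frag[3], ":", fmt(v3), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- clamped
  tree
}

#' Assign RT sequences to lineages by nearest reference seed
#'
#' Each query is assigned the lineage of its nearest seed by pairwise
#' p-distance (global protein alignment); exact ties between different
#' lineages yield "unassigned".
#'
#' @param queries named character vector of amino-acid RT sequences
#' @param seeds named list: lineage -> character vector of seed sequences
#' @return named character vector query -> lineage
#' @export
assign_lineages <- function(queries, seeds) {
  if (length(seeds) == 0) stop("no lineage seeds supplied")
  seed_seqs <- unlist(unname(lapply(names(seeds), function(l)
    setNames(seeds[[l]], rep(l, length(seeds[[l]]))))))
  out <- vapply(queries, function(q) {
    dd <- vapply(seed_seqs, function(s) {
      al <- align_center_star(c(a = q, b = s), type = "protein")
      p_distance_matrix(al)[1, 2]
    }, numeric(1))
    best <- min(dd)
    lins <- unique(names(seed_seqs)[abs(dd - best) < 1e-12])
    if (length(lins) == 1) lins else "unassigned"
  }, character(1))
  setNames(out, names(queries))
}

#' Greedy redundancy filter for tree display
#'
#' Keeps sequences in input order, dropping any whose identity to an
#' already-kept sequence reaches `max_identity`. Display-only: analysis
#' outputs are never filtered.
#'
#' @param seqs named character vector
#' @param max_identity identity at or above which a sequence is redundant
#' @param type "protein" or "dna"
#' @return the retained subset
#' @export
reduce_redundancy <- function(seqs, max_identity = 0.99,
                              type = c("protein", "dna")) {
  type <- match.arg(type)
  keep <- character(0)
  kept <- list()
  for (nm in names(seqs)) {
    redundant <- FALSE
    for (ks in kept) {
      al <- align_center_star(c(a = seqs[[nm]], b = ks), type = type)
      p <- p_distance_matrix(al)[1, 2]
      if (!is.na(p) && 1 - p >= max_identity) { redundant <- TRUE; break }
    }
    if (!redundant) { keep <- c(keep, nm); kept <- c(kept, seqs[[nm]]) }
  }
  seqs[keep]
}
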