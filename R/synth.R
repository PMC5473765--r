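# Synthetic genomes with planted LTR retrotransposons.
#
# The generator states its world explicitly: elements are born with two
# identical LTRs, age by a Jukes-Cantor substitution process at a fixed
# per-site per-year rate, and carry an exact 4-6 bp target-site duplication
# (TSD) on both flanks. Solo LTRs model unequal-recombination products;
# fragments model decayed copies. Every planted feature is recorded in a
# ground-truth ledger so detection, clustering, dating and depth estimation
# can all be scored against truth.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# modest domain sizes keep synthetic internals compact while staying long
# enough for unambiguous six-frame protein hits
DOMAIN_AA_LEN <- c(GAG = 100L, PR = 60L, IN = 90L, RT = 120L)

#' Specify a retrotransposon family for the generator
#'
#' A `family_spec` describes one family to be planted: its superfamily
#' (which fixes the canonical pol-domain order unless overridden), LTR and
#' internal lengths, copy number, age distribution, and the fractions of
#' copies planted as solo LTRs or fragments rather than intact elements.
#'
#' @param family_id family label, e.g. "FAM1"
#' @param superfamily one of "copia" (pol order PR-IN-RT), "gypsy"
#'   (PR-RT-IN), or "unclassified" (no pol domains)
#' @param ltr_length LTR length in bases (>= 50)
#' @param internal_length internal-region length in bases (>= 300 when a
#'   domain complement is present)
#' @param domain_order ordered subset of GAG/PR/IN/RT; defaults to the
#'   canonical order for the superfamily, empty for "unclassified"
#' @param copy_number number of copies to plant (>= 1)
#' @param age_dist insertion-age distribution, from [age_uniform()] or
#'   [age_point()], in years
#' @param solo_fraction fraction of copies planted as solo LTRs
#' @param fragment_fraction fraction planted as fragments
#' @return an object of class `family_spec`
#' @export
family_spec <- function(family_id,
                        superfamily = c("unclassified", "copia", "gypsy"),
                        ltr_length = 400L,
                        internal_length = 3000L,
                        domain_order = NULL,
                        copy_number = 1L,
                        age_dist = age_uniform(0, 3e6),
                        solo_fraction = 0,
                        fragment_fraction = 0) {
  superfamily <- match.arg(superfamily)
  if (is.null(domain_order)) {
    domain_order <- switch(superfamily,
      copia = c("GAG", "PR", "IN", "RT"),
      gypsy = c("GAG", "PR", "RT", "IN"),
      unclassified = character(0))
  }
  stopifnot(all(domain_order %in% names(DOMAIN_AA_LEN)))
  if (ltr_length < 50) stop("ltr_length must be >= 50")
  if (length(domain_order) > 0 && internal_length < 300)
    stop("internal_length must be >= 300 when domains are present")
  if (copy_number < 1) stop("copy_number must be >= 1")
  if (solo_fraction + fragment_fraction > 1)
    stop("solo_fraction + fragment_fraction must be <= 1")
  structure(list(
    family_id = as.character(family_id), superfamily = superfamily,
    ltr_length = as.integer(ltr_length),
    internal_length = as.integer(internal_length),
    domain_order = domain_order, copy_number = as.integer(copy_number),
    age_dist = age_dist, solo_fraction = solo_fraction,
    fragment_fraction = fragment_fraction
  ), class = "family_spec")
}

#' Insertion-age distributions
#'
#' @param min,max bounds of a uniform age distribution, in years
#' @return a distribution descriptor for [family_spec()]
#' @export
age_uniform <- function(min, max) {
  stopifnot(min >= 0, max >= min)
  list(type = "uniform", min = min, max = max)
}

#' @rdname age_uniform
#' @param value fixed age in years (point mass)
#' @export
age_point <- function(value) {
  stopifnot(value >= 0)
  list(type = "point", value = value)
}

draw_ages <- function(dist, n) {
  switch(dist$type,
    uniform = runif(n, dist$min, dist$max),
    point = rep(dist$value, n),
    stop("unknown age distribution type: ", dist$type))
}

mutate_aa <- function(seq, p) {
  n <- nchar(seq)
  hits <- which(runif(n) < p)
  if (length(hits) == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in hits) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  paste(chars, collapse = "")
}

# reverse-translate an amino-acid sequence with uniform synonymous codons
reverse_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    cands <- names(gc)[gc == a]
    cands[sample.int(length(cands), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

# lay out coding domains inside the internal region with random spacers;
# returns the internal sequence and 0-based coding intervals per domain
build_internal <- function(internal_length, domain_order, proteins) {
  if (length(domain_order) == 0) {
    return(list(seq = random_dna(internal_length),
                coding = data.frame(domain = character(), start = integer(),
                                    end = integer())))
  }
  cds <- vapply(domain_order, function(d) reverse_translate(proteins[[d]]),
                character(1))
  coding_total <- sum(nchar(cds))
  n_gap <- length(cds) + 1L
  slack <- internal_length - coding_total
  if (slack < n_gap * 5L)
    stop("internal_length too small for the requested domain complement (",
         coding_total, " coding bases)")
  cuts <- sort(sample.int(slack - n_gap * 5L + 1L, n_gap - 1L, replace = TRUE)) - 1L
  gaps <- diff(c(0L, cuts, slack - n_gap * 5L)) + 5L
  pieces <- character(2L * length(cds) + 1L)
  coding <- data.frame(domain = domain_order, start = integer(length(cds)),
                       end = integer(length(cds)))
  pos <- 0L
  for (i in seq_along(cds)) {
    sp <- random_dna(gaps[i])
    pieces[2L * i - 1L] <- sp
    pos <- pos + nchar(sp)
    pieces[2L * i] <- cds[i]
    coding$start[i] <- pos
    pos <- pos + nchar(cds[i])
    coding$end[i] <- pos
  }
  pieces[2L * length(cds) + 1L] <- random_dna(gaps[n_gap])
  list(seq = paste(pieces, collapse = ""), coding = coding)
}

#' Build a synthetic genome with planted LTR retrotransposons
#'
#' Plants every copy requested by `specs` into an i.i.d. random background.
#' Each copy is born with two identical LTRs and aged by applying the exact
#' Jukes-Cantor kernel independently to each LTR (and to the internal
#' region) for `mutation_rate * age` expected substitutions per site, so
#' the expected observed LTR-pair mismatch proportion is
#' `3/4 (1 - exp(-8 r T / 3))` and the JC-corrected divergence has
#' expectation `K = 2 r T`. A TSD of 4-6 random bases is duplicated
#' exactly on both flanks of every copy (solo LTRs keep both host TSD
#' copies, the signature of unequal recombination). Fragments lose a
#' uniform 40-90% span of the internal region, most of one LTR (only
#' 5-20% of it survives) and that flank's TSD copy, so they no longer
#' satisfy the both-complete-LTR-ends definition of intactness.
#'
#' @param specs list of [family_spec()] objects (may be empty)
#' @param background_length background genome length in bases
#' @param mutation_rate substitutions per site per year (default 1.3e-8,
#'   the canonical rice LTR rate)
#' @param seed integer seed; identical inputs and seed reproduce the
#'   genome byte-for-byte
#' @param minus_fraction probability a copy is planted on the minus strand
#' @param nesting if TRUE, insertion sites may fall inside previously
#'   planted elements (younger into older); default FALSE
#' @param aa_divergence per-site amino-acid divergence of each family's
#'   domain proteins from the shared ancestral proteins
#' @return an object of class `synthetic_genome`: `sequence` (character),
#'   `truth` (data.frame ledger, 0-based half-open coordinates), `params`
#' @export
build_genome <- function(specs, background_length, mutation_rate = 1.3e-8,
                         seed = 1L, minus_fraction = 0.5, nesting = FALSE,
                         aa_divergence = 0.15) {
  stopifnot(background_length >= 1)
  set.seed(stage_seed(seed, "synth"))
  background <- random_dna(background_length)

  ancestral <- lapply(DOMAIN_AA_LEN, function(n)
    paste(sample(AA20, n, replace = TRUE), collapse = ""))

  families <- list()
  copies <- list()
  for (sp in specs) {
    stopifnot(inherits(sp, "family_spec"))
    prot <- lapply(ancestral, mutate_aa, p = aa_divergence)
    ltr_cons <- random_dna(sp$ltr_length)
    internal <- build_internal(sp$internal_length, sp$domain_order, prot)
    families[[sp$family_id]] <- list(
      spec = sp, proteins = prot, ltr = ltr_cons,
      internal = internal$seq, coding = internal$coding)

    n <- sp$copy_number
    n_solo <- round(sp$solo_fraction * n)
    n_frag <- round(sp$fragment_fraction * n)
    if (n_solo + n_frag > n) n_frag <- n - n_solo
    states <- sample(c(rep("solo_ltr", n_solo), rep("fragment", n_frag),
                       rep("intact", n - n_solo - n_frag)))
    ages <- draw_ages(sp$age_dist, n)
    strands <- sample(c("+", "-"), n, replace = TRUE,
                      prob = c(1 - minus_fraction, minus_fraction))
    for (i in seq_len(n)) {
      copies[[length(copies) + 1L]] <- make_copy(
        sp, families[[sp$family_id]], states[i], ages[i], strands[i],
        mutation_rate)
    }
  }

  n_total <- length(copies)
  if (n_total == 0) {
    truth <- empty_truth()
    return(structure(list(sequence = background, truth = truth,
                          params = list(specs = specs,
                                        background_length = background_length,
                                        mutation_rate = mutation_rate,
                                        seed = seed, families = families)),
                     class = "synthetic_genome"))
  }
  copies <- copies[sample.int(n_total)]   # interleave families along the genome

  if (!nesting) {
    if (n_total > background_length + 1L)
      stop("placement failure: ", n_total, " copies cannot be hosted on a ",
           background_length, " b background")
    sites <- sort(sample.int(background_length + 1L, n_total) - 1L)
    genome <- assemble_linear(background, copies, sites)
  } else {
    genome <- assemble_nested(background, copies)
  }
  genome$truth$element_id <- sprintf("PL%04d", seq_len(nrow(genome$truth)))
  structure(list(sequence = genome$sequence, truth = genome$truth,
                 params = list(specs = specs,
                               background_length = background_length,
                               mutation_rate = mutation_rate, seed = seed,
                               minus_fraction = minus_fraction,
                               nesting = nesting, families = families)),
            class = "synthetic_genome")
}

empty_truth <- function() {
  data.frame(element_id = character(), family_id = character(),
             superfamily = character(), state = character(),
             age = numeric(), strand = character(), tsd = character(),
             start = integer(), end = integer(),
             ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             stringsAsFactors = FALSE)
}

# realize one planted copy: aged sequence plus LTR offsets relative to the
# copy start (TSD excluded; ltr5/ltr3 are the genomic-left/right repeats)
make_copy <- function(sp, fam, state, age, strand, rate) {
  d <- rate * age
  tsd <- random_dna(sample(4:6, 1L))
  tsd_left <- tsd
  tsd_right <- tsd
  ltr_a <- mutate_jc(fam$ltr, d)
  lw <- nchar(ltr_a)
  if (state == "solo_ltr") {
    seq <- ltr_a
    ltr5 <- c(0L, lw); ltr3 <- c(NA_integer_, NA_integer_)
  } else {
    ltr_b <- mutate_jc(fam$ltr, d)
    int_i <- mutate_jc(fam$internal, d)
    if (state == "fragment") {
      # decay: drop 40-90% of the internal span, most of one LTR end, and
      # the TSD copy on the decayed flank
      ilen <- nchar(int_i)
      span <- round(runif(1, 0.4, 0.9) * ilen)
      from <- sample.int(ilen - span + 1L, 1L)
      int_i <- paste0(substr(int_i, 1L, from - 1L),
                      substr(int_i, from + span, ilen))
      keep <- round(runif(1, 0.05, 0.2) * lw)
      ltr_b <- substr(ltr_b, 1L, keep)
      seq <- paste0(ltr_a, int_i, ltr_b)
      ltr5 <- c(0L, lw)
      ltr3 <- c(NA_integer_, NA_integer_)
      tsd_right <- ""
    } else {
      seq <- paste0(ltr_a, int_i, ltr_b)
      ltr5 <- c(0L, lw)
      ltr3 <- c(nchar(seq) - lw, nchar(seq))
    }
  }
  if (strand == "-") {
    n <- nchar(seq)
    seq <- revcomp(seq)
    flip <- function(iv) if (anyNA(iv)) iv else c(n - iv[2], n - iv[1])
    new5 <- flip(ltr3); new3 <- flip(ltr5)
    # keep ltr5 = genomic-left interval
    if (anyNA(new5)) { ltr5 <- new3; ltr3 <- new5 } else { ltr5 <- new5; ltr3 <- new3 }
    tmp <- tsd_left; tsd_left <- tsd_right; tsd_right <- tmp
  }
  list(family_id = sp$family_id, superfamily = sp$superfamily, state = state,
       age = age, strand = strand, tsd = tsd, seq = seq,
       tsd_left = tsd_left, tsd_right = tsd_right,
       ltr5 = ltr5, ltr3 = ltr3)
}

assemble_linear <- function(background, copies, sites) {
  n <- length(copies)
  pieces <- character(2L * n + 1L)
  truth <- vector("list", n)
  prev <- 0L     # background consumed so far
  pos <- 0L      # length of assembled sequence so far
  for (i in seq_len(n)) {
    bgseg <- substr(background, prev + 1L, sites[i])
    pieces[2L * i - 1L] <- bgseg
    pos <- pos + nchar(bgseg)
    cp <- copies[[i]]
    tl <- nchar(cp$tsd_left)
    el <- nchar(cp$seq)
    start <- pos + tl
    truth[[i]] <- data.frame(
      element_id = NA_character_, family_id = cp$family_id,
      superfamily = cp$superfamily, state = cp$state, age = cp$age,
      strand = cp$strand, tsd = cp$tsd, start = start, end = start + el,
      ltr5_start = start + cp$ltr5[1], ltr5_end = start + cp$ltr5[2],
      ltr3_start = start + cp$ltr3[1], ltr3_end = start + cp$ltr3[2],
      stringsAsFactors = FALSE)
    pieces[2L * i] <- paste0(cp$tsd_left, cp$seq, cp$tsd_right)
    pos <- pos + tl + el + nchar(cp$tsd_right)
    prev <- sites[i]
  }
  pieces[2L * n + 1L] <- substr(background, prev + 1L, nchar(background))
  list(sequence = paste(pieces, collapse = ""),
       truth = do.call(rbind, truth))
}

# sequential insertion, oldest copies first; younger copies may land inside
# older ones, shifting/stretching previously recorded intervals
assemble_nested <- function(background, copies) {
  ord <- order(-vapply(copies, `[[`, numeric(1), "age"))
  seq <- background
  truth <- empty_truth()
  for (cp in copies[ord]) {
    site <- sample.int(nchar(seq) + 1L, 1L) - 1L
    tl <- nchar(cp$tsd_left); el <- nchar(cp$seq)
    ins_len <- tl + el + nchar(cp$tsd_right)
    seq <- paste0(substr(seq, 1L, site), cp$tsd_left, cp$seq, cp$tsd_right,
                  substr(seq, site + 1L, nchar(seq)))
    shift <- function(v) ifelse(is.na(v), v,
                                ifelse(v >= site, v + ins_len,
                                       v))
    if (nrow(truth) > 0) {
      for (col in c("start", "end", "ltr5_start", "ltr5_end",
                    "ltr3_start", "ltr3_end"))
        truth[[col]] <- shift(truth[[col]])
    }
    start <- site + tl
    truth <- rbind(truth, data.frame(
      element_id = NA_character_, family_id = cp$family_id,
      superfamily = cp$superfamily, state = cp$state, age = cp$age,
      strand = cp$strand, tsd = cp$tsd, start = start, end = start + el,
      ltr5_start = start + cp$ltr5[1], ltr5_end = start + cp$ltr5[2],
      ltr3_start = start + cp$ltr3[1], ltr3_end = start + cp$ltr3[2],
      stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$start), ]
  rownames(truth) <- NULL
  list(sequence = seq, truth = truth)
}

#' Planted amino-acid domain references of a synthetic genome
#'
#' Returns the per-family domain proteins the generator embedded, keyed by
#' domain, for use as the reference set of [scan_domains()]. Synthetic runs
#' use these in place of curated profile databases.
#'
#' @param genome a `synthetic_genome`
#' @return named list (GAG/PR/IN/RT) of named character vectors
#' @export
domain_references <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  out <- list()
  for (fam in names(genome$params$families)) {
    f <- genome$params$families[[fam]]
    for (d in f$spec$domain_order) {
      out[[d]] <- c(out[[d]], setNames(f$proteins[[d]], paste0(fam, "_", d)))
    }
  }
  out
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", nchar(x$sequence), "bases,",
      nrow(x$truth), "planted copies (",
      sum(x$truth$state == "intact"), "intact /",
      sum(x$truth$state == "solo_ltr"), "solo /",
      sum(x$truth$state == "fragment"), "fragment )\n")
  invisible(x)
}

#' Extract planted-element sequences from the truth ledger
#'
#' Convenience accessor mirroring [element_sequences()], but driven by the
#' ground-truth coordinates instead of detector output.
#'
#' @param genome a `synthetic_genome`
#' @return list of named character vectors `ltr5`, `ltr3` (NA-free only
#'   for intact elements) keyed by planted element id
#' @export
truth_element_sequences <- function(genome) {
  stopifnot(inherits(genome, "synthetic_genome"))
  tr <- genome$truth
  grab <- function(s, e) {
    out <- rep(NA_character_, nrow(tr))
    ok <- !is.na(tr[[s]]) & !is.na(tr[[e]])
    out[ok] <- substring(genome$sequence, tr[[s]][ok] + 1L, tr[[e]][ok])
    setNames(out, tr$element_id)
  }
  list(ltr5 = grab("ltr5_start", "ltr5_end"),
       ltr3 = grab("ltr3_start", "ltr3_end"))
}

#' Simulate uniform-coverage paired-end reads from a genome
#'
#' Fragment starts are uniform over the genome; mates are `read_length`
#' bases from the fragment ends, mate 2 reverse-complemented. Per-base
#' substitution errors are applied at `error_rate`. The expected pair
#' count is `coverage * genome_length / (2 * read_length)`.
#'
#' @param genome a `synthetic_genome` or a plain character sequence
#' @param coverage fold coverage (> 0)
#' @param read_length read length in bases
#' @param error_rate per-base substitution error probability
#' @param seed integer seed
#' @param insert_mean,insert_sd fragment-size distribution (normal,
#'   truncated below at `2 * read_length`)
#' @return object of class `read_set` with `pairs` (r1, r2 and 0-based
#'   forward-strand origin coordinates pos1, pos2)
#' @export
simulate_reads <- function(genome, coverage, read_length = 100L,
                           error_rate = 0, seed = 1L,
                           insert_mean = 300, insert_sd = 20) {
  seq <- if (inherits(genome, "synthetic_genome")) genome$sequence else genome
  L <- nchar(seq)
  if (read_length > L) stop("read_length exceeds genome length")
  stopifnot(coverage > 0)
  set.seed(stage_seed(seed, "reads"))
  n <- round(coverage * L / (2 * read_length))
  ins <- pmin(L, pmax(2L * read_length,
                      round(rnorm(n, insert_mean, insert_sd))))
  start <- floor(runif(n) * (L - ins + 1))   # 0-based fragment start
  r1 <- substr0(rep(seq, n), start, start + read_length)
  pos2 <- start + ins - read_length
  r2f <- substr0(rep(seq, n), pos2, pos2 + read_length)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2f)))
  if (error_rate > 0) {
    r1 <- add_read_errors(r1, error_rate)
    r2 <- add_read_errors(r2, error_rate)
  }
  structure(list(
    pairs = data.frame(r1 = r1, r2 = r2, pos1 = start, pos2 = pos2,
                       stringsAsFactors = FALSE),
    read_length = as.integer(read_length), coverage = coverage,
    error_rate = error_rate, genome_length = L
  ), class = "read_set")
}

add_read_errors <- function(reads, rate) {
  k <- rbinom(length(reads), nchar(reads), rate)
  for (i in which(k > 0)) {
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(length(chars), k[i])
    for (j in at) chars[j] <- sample(setdiff(DNA, chars[j]), 1L)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", nrow(x$pairs), "pairs of", x$read_length, "b reads",
      sprintf("(%.2fx requested, error rate %g)\n", x$coverage, x$error_rate))
  invisible(x)
}

#' Write the ground-truth ledger of a synthetic genome
#'
#' Writes `<prefix>.gff3` (1-based inclusive coordinates) and
#' `<prefix>.tsv` (the full ledger, 0-based half-open) under `dir`.
#'
#' @param genome a `synthetic_genome`
#' @param dir output directory (created if missing)
#' @param prefix file name prefix
#' @return paths of the files written, invisibly
#' @export
write_truth <- function(genome, dir, prefix = "truth") {
  stopifnot(inherits(genome, "synthetic_genome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff_path <- file.path(dir, paste0(prefix, ".gff3"))
  tsv_path <- file.path(dir, paste0(prefix, ".tsv"))
  tr <- genome$truth
  type <- c(intact = "LTR_retrotransposon", solo_ltr = "solo_LTR",
            fragment = "LTR_retrotransposon_fragment")[tr$state]
  gff <- if (nrow(tr) == 0) gff3_read_empty() else data.frame(
    seqid = "synthetic", source = "retrochrono_synth", type = type,
    start = tr$start + 1L, end = tr$end, score = ".", strand = tr$strand,
    phase = ".",
    attributes = sprintf("ID=%s;family=%s;state=%s;age=%g",
                         tr$element_id, tr$family_id, tr$state, tr$age),
    stringsAsFactors = FALSE)
  gff3_write(gff, gff_path)
  write_tsv(tr, tsv_path)
  invisible(c(gff_path, tsv_path))
}

#' Read back a truth ledger written by [write_truth()]
#'
#' @param path the `.tsv` ledger path
#' @return the truth data.frame
#' @export
read_truth <- function(path) {
  df <- read_tsv(path)
  int_cols <- c("start", "end", "ltr5_start", "ltr5_end",
                "ltr3_start", "ltr3_end")
  for (cc in int_cols) df[[cc]] <- as.integer(df[[cc]])
  df
}
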