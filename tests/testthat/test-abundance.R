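# LTR library deduplication, read mapping, depth, homology annotation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
mut_dna <- function(s, f) {
  ch <- strsplit(s, "")[[1]]
  at <- sample(length(ch), round(f * length(ch)))
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

test_that("library dedupe follows the 0.95 cutoff and 150 b floor", {
  set.seed(81)
  a <- rand_dna(1000)
  near <- mut_dna(a, 0.04)        # ~0.96 identity -> collapses
  far <- mut_dna(a, 0.10)         # ~0.90 identity -> stays
  short <- rand_dna(140)          # excluded outright
  lib <- build_ltr_library(c(a = a, near = near, far = far,
                             short = short))
  expect_equal(length(lib$reps), 2)
  expect_equal(lib$n_dropped, 1)
  expect_setequal(unlist(lib$members), c("a", "near", "far"))
  # idempotence: feeding duplicates changes nothing
  lib2 <- build_ltr_library(c(a = a, a2 = a, near = near, far = far))
  expect_equal(length(lib2$reps), 2)
  # reverse-complement copies collapse too (strand-aware dedupe)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  lib3 <- build_ltr_library(c(a = a, rc = rc))
  expect_equal(length(lib3$reps), 1)
})

test_that("exact reads map uniquely, duplicates split weight", {
  set.seed(82)
  repA <- rand_dna(400)
  repB <- rand_dna(400)
  # read present identically in two representatives
  shared <- substr(repA, 101, 200)
  repB2 <- paste0(substr(repB, 1, 100), shared, substr(repB, 201, 400))
  lib <- build_ltr_library(c(A = repA, B = repB2), dedupe_identity = 0.99)
  rs <- structure(list(
    pairs = data.frame(r1 = c(substr(repA, 51, 150), shared),
                       r2 = c(rand_dna(100), rand_dna(100)),
                       pos1 = NA, pos2 = NA),
    read_length = 100L, coverage = 1, error_rate = 0,
    genome_length = 10000L), class = "read_set")
  hits <- map_reads(rs, lib)
  h1 <- hits[hits$read == "read000001/1", ]
  expect_equal(nrow(h1), 1)
  expect_equal(h1$weight, 1)
  expect_equal(h1$pos, 50)
  h2 <- hits[hits$read == "read000002/1", ]
  expect_equal(nrow(h2), 2)
  expect_equal(h2$weight, c(0.5, 0.5))
  # conservation: per-read weights always sum to 1
  ws <- tapply(hits$weight, hits$read, sum)
  expect_true(all(abs(ws - 1) < 1e-12))
})

test_that("reads beyond the mismatch budget stay unmapped", {
  set.seed(83)
  repA <- rand_dna(400)
  # 5 mismatches clustered in the first half so a clean seed remains
  # available in the last third of the read
  ch <- strsplit(substr(repA, 101, 200), "")[[1]]
  for (i in c(5, 15, 25, 35, 45))
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  read5 <- paste(ch, collapse = "")
  rs <- structure(list(
    pairs = data.frame(r1 = read5, r2 = rand_dna(100),
                       pos1 = NA, pos2 = NA),
    read_length = 100L, coverage = 1, error_rate = 0,
    genome_length = 10000L), class = "read_set")
  lib <- build_ltr_library(c(A = repA))
  hits <- map_reads(rs, lib, max_mismatch_per_100bp = 2)
  expect_equal(nrow(hits[hits$read == "read000001/1", ]), 0)
  loose <- map_reads(rs, lib, max_mismatch_per_100bp = 6)
  expect_equal(nrow(loose[loose$read == "read000001/1", ]), 1)
})

test_that("single-copy and multi-copy depth track the planted truth", {
  sp1 <- family_spec("MULTI", ltr_length = 400, internal_length = 1200,
                     domain_order = character(0), copy_number = 10,
                     age_dist = age_point(0))
  sp2 <- family_spec("ONE", ltr_length = 400, internal_length = 1200,
                     domain_order = character(0), copy_number = 1,
                     age_dist = age_point(0))
  g <- build_genome(list(sp1, sp2), background_length = 80000, seed = 84)
  rd <- simulate_reads(g, coverage = 5, seed = 85)
  tr <- g$truth
  l5 <- truth_element_sequences(g)$ltr5
  lib <- build_ltr_library(l5, family = setNames(tr$family_id,
                                                 tr$element_id))
  dp <- depth_profile(map_reads(rd, lib), lib, genome_mean_depth(rd))
  pf <- dp$per_family
  one <- pf$copies_est[pf$family == "ONE"]
  multi <- pf$copies_est[pf$family == "MULTI"]
  expect_lt(abs(one - 1), 0.15)
  expect_lt(abs(multi - 10) / 10, 0.15)
  expect_equal(dp$mean_depth, 5, tolerance = 0.01)
  # zero mapped reads -> zero depth
  alien <- build_ltr_library(c(x = rand_dna(400)))
  dp0 <- depth_profile(map_reads(rd, alien, max_mismatch_per_100bp = 0),
                       alien, 5)
  expect_equal(dp0$per_rep$norm_depth, 0)
})

test_that("homology annotation labels solos and fragments", {
  set.seed(86)
  sp <- family_spec("S", ltr_length = 400, internal_length = 2000,
                    domain_order = character(0), copy_number = 10,
                    age_dist = age_point(2e5), solo_fraction = 0.3,
                    fragment_fraction = 0.2)
  g <- build_genome(list(sp), background_length = 400000, seed = 56)
  tr <- g$truth
  els <- find_intact_elements(g)
  l5 <- truth_element_sequences(g)$ltr5[tr$state == "intact"]
  lib <- build_ltr_library(l5, family = setNames(
    tr$family_id, tr$element_id)[tr$state == "intact"])
  ann <- annotate_homologous_copies(g, lib, intact = els)
  hit_label <- function(row) {
    hit <- ann[ann$start < row$end & ann$end > row$start, ]
    if (nrow(hit)) hit$label else NA_character_
  }
  # every planted copy is annotated as something
  for (i in seq_len(nrow(tr)))
    expect_false(anyNA(hit_label(tr[i, ])))
  # solos / fragments lying clear of detector calls carry their label
  clear <- function(row) !any(els$start < row$end & els$end > row$start)
  solos <- tr[tr$state == "solo_ltr", ]
  for (i in seq_len(nrow(solos)))
    if (clear(solos[i, ]))
      expect_true("solo_ltr" %in% hit_label(solos[i, ]))
  frags <- tr[tr$state == "fragment", ]
  for (i in seq_len(nrow(frags)))
    if (clear(frags[i, ]))
      expect_true(all(hit_label(frags[i, ]) %in%
                        c("fragment", "solo_ltr")))
  # per-family totals cover the annotated spans
  tot <- family_sequence_lengths(ann)
  expect_equal(tot$total_bases, sum(ann$end - ann$start))
  # genomes without copies of a family produce no annotations for it
  other <- build_ltr_library(c(o = rand_dna(400)))
  expect_equal(nrow(annotate_homologous_copies(
    c(chr = substr(g$sequence, 1, 50000)), other)), 0)
})

test_that("depth-proxy validation computes Pearson r", {
  n <- c(F1 = 1, F2 = 2, F3 = 3, F4 = 4)
  v <- validate_depth_proxy(2 * n, n)     # perfectly proportional
  expect_equal(v$r, 1)
  expect_equal(v$slope, 2)
  v2 <- validate_depth_proxy(5 - n, n)    # perfectly anti-proportional
  expect_equal(v2$r, -1)
  flat <- validate_depth_proxy(c(F1 = 1, F2 = 1, F3 = 1), n[1:3])
  expect_true(flat$flagged)
  expect_error(validate_depth_proxy(2 * n[1:2], n[1:2]), "at least 3")
})
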