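# Generator: planted-world contracts, aging statistics, reproducibility.

test_that("empty spec list yields bare background with empty truth", {
  g <- build_genome(list(), background_length = 50000, seed = 1)
  expect_equal(nchar(g$sequence), 50000)
  expect_equal(nrow(g$truth), 0)
  expect_true(all(strsplit(g$sequence, "")[[1]] %in% c("A", "C", "G", "T")))
})

test_that("LTR-pair divergence of same-age elements matches the clock", {
  # point mass at 1 MY, r = 1.3e-8, 1 kb LTRs, 200 copies: the observed
  # mismatch proportion has expectation 3/4 (1 - exp(-8 r T / 3)), which
  # first-order equals 2 r T = 0.026; assert within 3 binomial SE of the
  # exact expectation (oracle: direct mismatch counting below)
  r <- 1.3e-8; T <- 1e6
  specs <- lapply(1:4, function(i)
    family_spec(paste0("F", i), ltr_length = 1000, internal_length = 400,
                domain_order = character(0), copy_number = 50,
                age_dist = age_point(T)))
  g <- build_genome(specs, background_length = 300000, seed = 11,
                    mutation_rate = r)
  tr <- g$truth
  s <- truth_element_sequences(g)
  mm <- hamming_count(unname(s$ltr5), unname(s$ltr3))
  p_obs <- mean(mm / 1000)
  p_exp <- 0.75 * (1 - exp(-8 * r * T / 3))
  se <- sqrt(p_exp * (1 - p_exp) / 1000) / sqrt(nrow(tr))
  expect_lt(abs(p_obs - p_exp), 3 * se)
  # and the first-order 2rT value is itself within the same band
  expect_lt(abs(p_obs - 2 * r * T), 3 * se + abs(p_exp - 2 * r * T))
})

test_that("TSD flanks of every intact planted element are identical", {
  sp <- family_spec("F", ltr_length = 300, internal_length = 1000,
                    domain_order = character(0), copy_number = 30,
                    age_dist = age_uniform(0, 3e6))
  g <- build_genome(list(sp), background_length = 200000, seed = 21)
  tr <- g$truth[g$truth$state == "intact", ]
  for (i in seq_len(nrow(tr))) {
    tl <- nchar(tr$tsd[i])
    left <- substring(g$sequence, tr$start[i] - tl + 1, tr$start[i])
    right <- substring(g$sequence, tr$end[i] + 1, tr$end[i] + tl)
    expect_identical(left, right)
    expect_identical(left, tr$tsd[i])
  }
  expect_true(all(nchar(tr$tsd) %in% 4:6))
})

test_that("solo_fraction = 1 plants only solo LTRs", {
  sp <- family_spec("F", ltr_length = 300, internal_length = 1000,
                    domain_order = character(0), copy_number = 10,
                    age_dist = age_point(0), solo_fraction = 1)
  g <- build_genome(list(sp), background_length = 60000, seed = 3)
  expect_equal(sum(g$truth$state == "solo_ltr"), 10)
  expect_equal(sum(g$truth$state == "intact"), 0)
  # a solo spans exactly one LTR
  expect_equal(g$truth$end - g$truth$start, rep(300L, 10))
})

test_that("seeded reproducibility is byte-for-byte", {
  sp <- family_spec("F", copy_number = 5, age_dist = age_uniform(0, 2e6),
                    superfamily = "gypsy")
  g1 <- build_genome(list(sp), background_length = 50000, seed = 99)
  g2 <- build_genome(list(sp), background_length = 50000, seed = 99)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$truth, g2$truth)
  g3 <- build_genome(list(sp), background_length = 50000, seed = 100)
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("placement capacity failure is explicit", {
  sp <- family_spec("F", ltr_length = 50, internal_length = 300,
                    domain_order = character(0), copy_number = 30,
                    age_dist = age_point(0))
  expect_error(build_genome(list(sp), background_length = 10, seed = 1),
               "placement failure")
})

test_that("read simulation honours the coverage arithmetic", {
  g <- build_genome(list(), background_length = 100000, seed = 4)
  rd <- simulate_reads(g, coverage = 5, read_length = 100, seed = 5)
  expect_equal(nrow(rd$pairs), 2500)   # 5 * 100000 / (2 * 100)
  # error-free reads are exact substrings at their origin coordinates
  idx <- c(1, 500, 2500)
  for (i in idx) {
    expect_identical(rd$pairs$r1[i],
                     substring(g$sequence, rd$pairs$pos1[i] + 1,
                               rd$pairs$pos1[i] + 100))
  }
  # determinism and seed sensitivity
  rd2 <- simulate_reads(g, coverage = 5, read_length = 100, seed = 5)
  expect_identical(rd$pairs, rd2$pairs)
  rd3 <- simulate_reads(g, coverage = 5, read_length = 100, seed = 6)
  expect_false(identical(rd$pairs$pos1, rd3$pairs$pos1))
  expect_error(simulate_reads(g, coverage = 1, read_length = 2e6),
               "read_length")
})

test_that("read errors appear at the requested rate", {
  g <- build_genome(list(), background_length = 50000, seed = 7)
  rd <- simulate_reads(g, coverage = 4, error_rate = 0.01, seed = 8)
  orig <- substring(g$sequence, rd$pairs$pos1 + 1, rd$pairs$pos1 + 100)
  rate <- sum(hamming_count(rd$pairs$r1, orig)) / (100 * nrow(rd$pairs))
  expect_lt(abs(rate - 0.01), 0.002)
})

test_that("truth ledger round-trips through disk", {
  sp <- family_spec("F", copy_number = 4, superfamily = "copia",
                    age_dist = age_uniform(0, 1e6),
                    solo_fraction = 0.25)
  g <- build_genome(list(sp), background_length = 50000, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_truth(g, dir)
  back <- read_truth(file.path(dir, "truth.tsv"))
  expect_equal(back, g$truth, ignore_attr = TRUE)
  # GFF3 uses 1-based inclusive coordinates
  gff <- gff3_read(file.path(dir, "truth.gff3"))
  expect_equal(gff$start, g$truth$start + 1L)
  expect_equal(gff$end, g$truth$end)
  # empty truth -> header-only GFF3
  g0 <- build_genome(list(), background_length = 1000, seed = 1)
  write_truth(g0, dir, prefix = "empty")
  expect_equal(nrow(gff3_read(file.path(dir, "empty.gff3"))), 0)
})

test_that("fragments lack a complete second LTR; nesting stays in bounds", {
  sp <- family_spec("F", ltr_length = 400, internal_length = 2000,
                    domain_order = character(0), copy_number = 10,
                    age_dist = age_point(1e5), fragment_fraction = 0.5)
  g <- build_genome(list(sp), background_length = 100000, seed = 13)
  fr <- g$truth[g$truth$state == "fragment", ]
  expect_gt(nrow(fr), 0)
  expect_true(all(is.na(fr$ltr3_start)))
  expect_true(all(fr$end - fr$start < 2000 + 2 * 400))
  gn <- build_genome(list(sp), background_length = 100000, seed = 13,
                     nesting = TRUE)
  expect_true(all(gn$truth$end <= nchar(gn$sequence)))
  expect_true(all(gn$truth$start >= 0))
})
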