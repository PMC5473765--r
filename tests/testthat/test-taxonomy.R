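# Superfamily classification and family clustering.

test_that("planted domains are found in order and drive classification", {
  spc <- family_spec("C", superfamily = "copia", copy_number = 1,
                     age_dist = age_point(0))
  spg <- family_spec("G", superfamily = "gypsy", copy_number = 1,
                     age_dist = age_point(0))
  g <- build_genome(list(spc, spg), background_length = 30000, seed = 41,
                    minus_fraction = 0)
  refs <- domain_references(g)
  els <- find_intact_elements(g)
  expect_equal(nrow(els), 2)
  seqs <- element_sequences(els, g)
  tr <- g$truth[order(g$truth$start), ]
  for (i in 1:2) {
    hits <- scan_domains(seqs$internal[[i]], refs)
    expect_equal(nrow(hits), 4)
    want <- if (tr$superfamily[i] == "copia") c("GAG", "PR", "IN", "RT")
            else c("GAG", "PR", "RT", "IN")
    expect_equal(hits$domain, want)
    expect_equal(classify_superfamily(hits), tr$superfamily[i])
  }
})

test_that("random sequence and empty internals produce no hits", {
  spc <- family_spec("C", superfamily = "copia", copy_number = 1)
  g <- build_genome(list(spc), background_length = 20000, seed = 42)
  refs <- domain_references(g)
  set.seed(43)
  rand <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  expect_equal(nrow(scan_domains(rand, refs)), 0)
  expect_equal(nrow(scan_domains("", refs)), 0)
})

test_that("minus-strand elements classify through their coding strand", {
  spg <- family_spec("G", superfamily = "gypsy", copy_number = 2,
                     age_dist = age_point(0))
  g <- build_genome(list(spg), background_length = 40000, seed = 44,
                    minus_fraction = 1)
  refs <- domain_references(g)
  els <- find_intact_elements(g)
  seqs <- element_sequences(els, g)
  hits <- scan_domains(seqs$internal[[1]], refs)
  expect_true(all(hits$strand == "-"))
  expect_equal(classify_superfamily(hits), "gypsy")
})

test_that("superfamily rule is permutation-complete over {PR,IN,RT}", {
  doms <- c("PR", "IN", "RT")
  fake_hits <- function(order) {
    if (length(order) == 0) return(data.frame())
    data.frame(domain = order,
               start = seq(0, by = 500, length.out = length(order)),
               end = seq(400, by = 500, length.out = length(order)),
               score = 200, frame = "+1", strand = "+",
               ref = "x", ref_coverage = 1, stringsAsFactors = FALSE)
  }
  count <- 0
  for (k in 0:3) {
    subsets <- if (k == 0) list(character(0)) else
      combn(doms, k, simplify = FALSE)
    for (ss in subsets) {
      # enumerate permutations by recursion (small k)
      gen <- function(v) {
        if (length(v) <= 1) return(list(v))
        res <- list()
        for (i in seq_along(v))
          for (rest in gen(v[-i])) res <- c(res, list(c(v[i], rest)))
        res
      }
      perms <- gen(ss)
      for (pm in perms) {
        count <- count + 1
        lab <- classify_superfamily(fake_hits(pm))
        expect_true(lab %in% c("copia", "gypsy", "unclassified"))
        if (identical(pm, c("PR", "IN", "RT")))
          expect_equal(lab, "copia")
        else if (identical(pm, c("PR", "RT", "IN")))
          expect_equal(lab, "gypsy")
        else expect_equal(lab, "unclassified")
      }
    }
  }
  expect_equal(count, 16)   # 1 + 3 + 6 + 6 ordered subsets
  # reversed coordinate order on the minus strand
  h <- fake_hits(c("RT", "IN", "PR"))
  h$strand <- "-"
  expect_equal(classify_superfamily(h), "copia")
})

test_that("clustering thresholds follow the >80%/50% rule", {
  set.seed(45)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  mutate_frac <- function(s, f) {
    ch <- strsplit(s, "")[[1]]
    at <- sample(length(ch), round(f * length(ch)))
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  # identical pair -> one family
  fs <- cluster_families(make_elements_df(c("a", "b")),
                         ltr5 = c(a = base, b = base))
  expect_equal(nrow(fs$families), 1)
  # 0.85 identity, full coverage -> same family
  m15 <- mutate_frac(base, 0.15)
  fs <- cluster_families(make_elements_df(c("a", "b")),
                         ltr5 = c(a = base, b = m15))
  expect_equal(nrow(fs$families), 1)
  # identity below the strict 0.80 threshold -> split
  m25 <- mutate_frac(base, 0.25)
  fs <- cluster_families(make_elements_df(c("a", "b")),
                         ltr5 = c(a = base, b = m25))
  expect_equal(nrow(fs$families), 2)
  # high identity but only 40% reciprocal coverage -> split
  frag <- substr(base, 1, 160)
  other <- paste0(frag, paste(sample(c("A", "C", "G", "T"), 240,
                                     replace = TRUE), collapse = ""))
  fs <- cluster_families(make_elements_df(c("a", "b")),
                         ltr5 = c(a = base, b = other))
  expect_equal(nrow(fs$families), 2)
})

test_that("single linkage is transitive: A-B, B-C link pulls in A-C", {
  set.seed(46)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  ch <- strsplit(base, "")[[1]]
  flip <- function(ch, at) {
    for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    ch
  }
  # B and C differ from A at disjoint scattered site sets (scattered so
  # the aligner cannot gap whole diverged blocks out of the identity):
  # d(A,B) = d(A,C) = 0.15, d(B,C) = 0.30
  at <- sample(400, 120)
  B <- paste(flip(ch, at[1:60]), collapse = "")
  C <- paste(flip(ch, at[61:120]), collapse = "")
  ltr5 <- c(A = base, B = B, C = C)
  expect_lt(align_pair(B, C)$identity, 0.80)
  fs <- cluster_families(make_elements_df(c("A", "B", "C")), ltr5 = ltr5)
  expect_equal(nrow(fs$families), 1)
  # matches the matrix-closure oracle
  oracle <- single_linkage_oracle(unname(ltr5))
  expect_equal(rand_index(fs$membership[c("A", "B", "C")], oracle), 1)
})

test_that("family naming, ranking, and copy classes follow the rules", {
  set.seed(47)
  # build three families of sizes 25 / 3 / 1 via shared LTRs
  base1 <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  base2 <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  base3 <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  ids <- sprintf("e%02d", 1:29)
  ltr5 <- setNames(c(rep(base1, 25), rep(base2, 3), base3), ids)
  sf <- c(rep("gypsy", 25), rep("copia", 3), "unclassified")
  fs <- cluster_families(make_elements_df(ids, superfamily = sf),
                         ltr5 = ltr5)
  ranked <- name_and_rank_families(fs)
  fam <- ranked$families
  expect_equal(fam$family_id, c("OAL001", "OAL002", "OAL003"))
  expect_equal(fam$n_intact, c(25L, 3L, 1L))
  expect_equal(fam$copy_class, c("high", "low", "single"))
  expect_equal(fam$superfamily, c("gypsy", "copia", "unclassified"))
  # class boundaries: 21 is high, 20 and 2 are low, 1 is single
  fsb <- structure(list(
    families = data.frame(family_id = sprintf("F%03d", 1:4),
                          superfamily = "gypsy",
                          n_intact = c(21L, 20L, 2L, 1L),
                          members = c("a", "b", "c", "d"),
                          stringsAsFactors = FALSE),
    membership = setNames(sprintf("F%03d", 1:4), c("a", "b", "c", "d"))),
    class = "family_set")
  rb <- name_and_rank_families(fsb)
  expect_equal(rb$families$copy_class, c("high", "low", "low", "single"))
  # deterministic tie-break on equal counts: smallest member id first
  fs2 <- fs
  fs2$families$n_intact <- c(3L, 3L, 3L)
  r2a <- name_and_rank_families(fs2)
  r2b <- name_and_rank_families(fs2)
  expect_identical(r2a$families, r2b$families)
})

test_that("family superfamily is the member majority, ties unclassified", {
  set.seed(48)
  base <- paste(sample(c("A","C","G","T"), 300, replace = TRUE), collapse = "")
  ids <- c("a", "b", "c", "d")
  fs <- cluster_families(
    make_elements_df(ids, superfamily = c("gypsy", "gypsy", "copia",
                                          "copia")),
    ltr5 = setNames(rep(base, 4), ids))
  expect_equal(fs$families$superfamily, "unclassified")
  fs <- cluster_families(
    make_elements_df(ids, superfamily = c("gypsy", "gypsy", "gypsy",
                                          "copia")),
    ltr5 = setNames(rep(base, 4), ids))
  expect_equal(fs$families$superfamily, "gypsy")
})
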