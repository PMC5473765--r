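# Independent oracles used across the suite. These deliberately avoid the
# package's own alignment/clustering/NJ code paths.

# Needleman-Wunsch with free end gaps, linear gap penalty; returns
# identity over gap-free aligned columns. O(nm), for small fixtures only.
nw_identity_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  S <- matrix(0, n + 1, m + 1)          # free end gaps: first row/col 0
  P <- matrix(0L, n + 1, m + 1)         # 1 diag, 2 up, 3 left
  for (i in 1:n) {
    for (j in 1:m) {
      sc <- c(S[i, j] + if (x[i] == y[j]) match else mismatch,
              S[i, j + 1] + gap, S[i + 1, j] + gap)
      k <- which.max(sc)
      S[i + 1, j + 1] <- sc[k]
      P[i + 1, j + 1] <- k
    }
  }
  # free end gaps: best cell on last row/col
  lastcol <- S[, m + 1]; lastrow <- S[n + 1, ]
  if (max(lastcol) >= max(lastrow)) { i <- which.max(lastcol) - 1; j <- m }
  else { i <- n; j <- which.max(lastrow) - 1 }
  matches <- 0L; cols <- 0L
  while (i > 0 && j > 0) {
    k <- P[i + 1, j + 1]
    if (k == 1L) {
      cols <- cols + 1L
      if (x[i] == y[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (k == 2L) i <- i - 1
    else j <- j - 1
  }
  if (cols == 0) return(0)
  matches / cols
}

# brute-force single-linkage over the full pairwise 5'-LTR graph, using
# matrix transitive closure rather than union-find
single_linkage_oracle <- function(ltr5, min_identity = 0.80,
                                  min_cov = 0.50) {
  n <- length(ltr5)
  adj <- diag(TRUE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- align_pair_both_strands(ltr5[[i]], ltr5[[j]])
      edge <- al$identity > min_identity &&
        al$coverage_a >= min_cov && al$coverage_b >= min_cov
      adj[i, j] <- adj[j, i] <- edge
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      lab <- lab + 1L
      comp[adj[i, ]] <- lab
    }
  }
  comp
}

rand_index <- function(a, b) {
  a <- unname(a); b <- unname(b)
  n <- length(a)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- s + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  s / choose(n, 2)
}

# least-squares branch fit of a distance matrix on a fixed topology;
# returns RSS and fitted branch lengths (edge order of the tree)
ls_fit_tree <- function(tree, D) {
  labs <- rownames(D)
  n <- length(labs)
  pairs <- t(combn(n, 2))
  tips <- match(tree$tip.label, labs)
  ne <- nrow(tree$edge)
  A <- matrix(0, nrow(pairs), ne)
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  for (e in seq_len(ne)) {
    below <- desc[[e]]
    in_below <- seq_len(n) %in% match(tree$tip.label[below], labs)
    for (r in seq_len(nrow(pairs))) {
      A[r, e] <- xor(in_below[pairs[r, 1]], in_below[pairs[r, 2]])
    }
  }
  y <- D[pairs]
  fit <- lm.fit(A, y)
  list(rss = sum(fit$residuals^2), branch = fit$coefficients)
}

# exhaustive NJ oracle: enumerate all unrooted topologies, least-squares
# fit each, return the (unique, for additive D) zero-RSS tree
best_tree_oracle <- function(D) {
  labs <- rownames(D)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  best <- NULL
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]          # [[ ]] restores the shared tip labels
    f <- ls_fit_tree(tr, D)
    if (is.null(best) || f$rss < best$rss) {
      best <- list(rss = f$rss, tree = tr, branch = f$branch)
    }
  }
  best
}

# random unrooted binary tree with positive branch lengths -> additive
# distance matrix (built with ape, independent of package NJ)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 0.5))
  D <- cophenetic(tr)
  o <- sort(rownames(D))
  list(tree = tr, D = D[o, o])
}

make_elements_df <- function(ids, tsd = "ACGT", superfamily = NULL) {
  df <- data.frame(element_id = ids, tsd = tsd, stringsAsFactors = FALSE)
  if (!is.null(superfamily)) df$superfamily <- superfamily
  df
}
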