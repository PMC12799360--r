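# Shared fixtures and independent oracles. Oracles are deliberately naive
# (double loops, full enumeration) and never call the code paths they check.

# -- tiny handcrafted database -------------------------------------------

tiny_db <- function() {
  proteins <- data.frame(
    protein_id = paste0("P", 1:6),
    species_id = c("sp1", "sp1", "sp2", "sp2", "sp3", "sp3"),
    sequence = c("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ",
                 "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQA",
                 "MKTAYIAKQRNISFVKSHFSRQLEERLGLIEVQ",
                 "HEAGAWGHEEHEAGAWGHEEHEAGAWGHEE",
                 "HEAGAWGHEEHEAGAWGHEEHEAGAWGHEW",
                 "PAWHEAEPAWHEAEPAWHEAEPAWHEAE"),
    stringsAsFactors = FALSE)
  annotations <- list(
    P1 = c("GO:0000001", "GO:0000002"),
    P2 = c("GO:0000002", "GO:0000003"),
    P3 = c("GO:0000001"),
    P4 = c("GO:0000010", "GO:0000011"),
    P5 = c("GO:0000010"))
  memberships <- data.frame(
    protein_id    = c("P1", "P1", "P2", "P2", "P3", "P4", "P5", "P5"),
    orthogroup_id = c("OGa", "OGa.1", "OGa", "OGa.1", "OGa", "OGb", "OGb", "OGb.1"),
    level_rank    = c(0L, 2L, 0L, 2L, 0L, 0L, 0L, 1L),
    stringsAsFactors = FALSE)
  aspects <- c("GO:0000001" = "BP", "GO:0000002" = "MF", "GO:0000003" = "CC",
               "GO:0000010" = "BP", "GO:0000011" = "MF")
  reference_db(proteins, annotations, memberships, aspects)
}

# one small noisy synthetic fixture, built once per test run
shared_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_orthogroups = 8, members_per_group = 6,
                          seq_length = 120, length_jitter = 10,
                          n_queries = 24, seed = 101)
      fx <- generate_refdb(cfg)
      qs <- generate_queries(fx)
      hits <- builtin_search(qs$sequences, fx$db)
      cache <<- list(fx = fx, qs = qs, hits = hits,
                     by_q = hits_by_query(hits, names(qs$sequences)))
    }
    cache
  }
})

# -- independent oracles --------------------------------------------------

# plain-R Gotoh Smith-Waterman, full matrices, score only;
# gap of length L costs open + L * ext
sw_oracle <- function(a, b, blosum, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      d <- H[i - 1, j - 1] + blosum[av[i - 1], bv[j - 1]]
      H[i, j] <- max(0, d, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# brute-force confusion by element-wise scan
bf_confusion <- function(pred, ref) {
  pred <- unique(pred); ref <- unique(ref)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (p in pred) if (p %in% ref) tp <- tp + 1L else fp <- fp + 1L
  for (r in ref) if (!r %in% pred) fn <- fn + 1L
  list(tp = tp, fp = fp, fn = fn)
}

bf_metrics <- function(tp, fp, fn) {
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, accuracy = (pr + rc) / 2, f1 = f1)
}

# exhaustive Fmax over a grid, macro-averaged, recomputed from first
# principles on (query_id, term_id, probability) rows
bf_fmax <- function(scored, reference, grid) {
  fvals <- vapply(grid, function(t) {
    prs <- c(); rcs <- c()
    for (q in names(reference)) {
      pred <- scored$term_id[scored$query_id == q & scored$probability > t]
      cts <- bf_confusion(pred, reference[[q]])
      if (cts$tp + cts$fp + cts$fn == 0) next
      m <- bf_metrics(cts$tp, cts$fp, cts$fn)
      prs <- c(prs, m[["precision"]]); rcs <- c(rcs, m[["recall"]])
    }
    if (length(prs) == 0) return(0)
    mp <- mean(prs); mr <- mean(rcs)
    if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  }, numeric(1))
  list(fmax = max(fvals), t_star = grid[which.max(fvals)], f = fvals)
}

# brute-force orthogroup vote: frequency table over the neighbors'
# most-ancient orthogroups (computed by scanning membership lists), ties
# to the group holding the best-ranked hit
bf_vote <- function(top_hits, db) {
  ogs <- character(0)
  for (i in seq_len(nrow(top_hits))) {
    mem <- db$memberships[db$memberships$protein_id == top_hits$subject_id[i], ]
    if (nrow(mem) == 0) { ogs <- c(ogs, NA_character_); next }
    ogs <- c(ogs, mem$orthogroup_id[order(mem$level_rank)][1])
  }
  if (all(is.na(ogs))) return(list(orthogroup_id = NA_character_, vote_count = 0L))
  counts <- table(ogs[!is.na(ogs)])
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) > 1) {
    first_rank <- sapply(winners, function(g) {
      min(top_hits$rank[!is.na(ogs) & ogs == g])
    })
    winners <- winners[order(first_rank, winners)]
  }
  list(orthogroup_id = winners[1], vote_count = as.integer(max(counts)))
}

# rank-based AUROC (Mann-Whitney), ties averaged
auroc <- function(labels, scores) {
  r <- rank(scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# random hit table generator for filter/ranking property tests
random_hits <- function(n, seed, query_id = "Q") {
  set.seed(seed)
  tibble::tibble(
    query_id = query_id,
    subject_id = sprintf("S%03d", sample(1:500, n)),
    identity_pct = round(stats::runif(n, 20, 100), 1),
    query_coverage_pct = round(stats::runif(n, 30, 100), 1),
    evalue = 10^stats::runif(n, -40, 0),
    bit_score = round(stats::runif(n, 20, 300), 1),
    rank = NA_integer_)
}
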