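test_that("parse_tabular_hits computes query coverage and assigns ranks", {
  f <- withr::local_tempfile()
  line <- function(q, s, pid, qs, qe, ev, bs) {
    paste(q, s, pid, 60, 5, 0, qs, qe, 1, 60, ev, bs, sep = "\t")
  }
  writeLines(c(line("Q1", "S1", 90, 1, 70, 1e-30, 200),
               line("Q1", "S2", 80, 11, 90, 1e-20, 150),
               line("Q2", "S1", 70, 1, 50, 1e-10, 100)), f)
  qs <- c(Q1 = 100, Q2 = 100)
  hits <- parse_tabular_hits(f, qs)
  expect_equal(nrow(hits), 3)
  q1 <- hits[hits$query_id == "Q1", ]
  expect_equal(q1$query_coverage_pct, c(70, 80))
  expect_equal(q1$rank, c(1L, 2L))
  expect_equal(q1$subject_id[1], "S1")  # higher bit score first

  # shuffled lines give the identical ranked output
  f2 <- withr::local_tempfile()
  writeLines(rev(readLines(f)), f2)
  expect_equal(parse_tabular_hits(f2, qs), hits)

  # empty file -> empty table; wrong column count -> error with line number
  f3 <- withr::local_tempfile()
  file.create(f3)
  expect_equal(nrow(parse_tabular_hits(f3, qs)), 0)
  writeLines("Q1\tS1\t90", f3)
  expect_error(parse_tabular_hits(f3, qs), "12 tab-separated columns at line 1")
  # unknown query -> warning and skip
  writeLines(line("QX", "S1", 90, 1, 70, 1e-30, 200), f3)
  expect_warning(h <- parse_tabular_hits(f3, qs), "unknown query id")
  expect_equal(nrow(h), 0)
})

test_that("built-in aligner matches an exhaustive plain-R DP oracle on toy pairs", {
  blosum <- orthogo:::get_blosum62()
  aa <- rownames(blosum)[1:20]
  set.seed(7)
  for (i in 1:50) {
    a <- paste(sample(aa, sample(4:20, 1), replace = TRUE), collapse = "")
    b <- if (i %% 2 == 0) {
      paste(sample(aa, sample(4:20, 1), replace = TRUE), collapse = "")
    } else {
      orthogo:::mutate_sequence(a, runif(1, 0, 0.4))
    }
    got <- orthogo:::.sw_batch(orthogo:::encode_aa(a, blosum),
                               list(orthogo:::encode_aa(b, blosum)),
                               blosum, 11L, 1L, 1L)[1, "score"]
    expect_equal(unname(got), sw_oracle(a, b, blosum), info = paste(a, b))
  }
})

test_that("builtin_search: self-hit is a rank-1 perfect hit, excluded on request", {
  db <- tiny_db()
  q <- c(P1 = db$proteins$sequence[db$proteins$protein_id == "P1"])
  raw <- builtin_search(q, db, search_config(), filter = FALSE)
  self <- raw[raw$subject_id == "P1", ]
  expect_equal(self$rank, 1L)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$query_coverage_pct, 100)

  filt <- builtin_search(q, db, search_config())
  expect_false("P1" %in% filt$subject_id)
  # P2 differs from P1 only by a trailing A, not excluded
  expect_true("P2" %in% filt$subject_id)

  # disjoint-alphabet sequences produce no hits
  nohit <- builtin_search(c(X = strrep("A", 30)),
                          reference_db(data.frame(protein_id = "W", species_id = "s",
                                                  sequence = strrep("W", 30))),
                          search_config())
  expect_equal(nrow(nohit), 0)

  expect_error(builtin_search(c(E = ""), db), "empty query sequence")
  expect_error(builtin_search(unname(q), db), "named character")
})

test_that("filter_and_rank applies inclusive thresholds and matches a predicate scan", {
  db <- tiny_db()
  cfg <- search_config(min_identity_pct = 50, min_coverage_pct = 70,
                       max_evalue = 1e-6)
  hits <- random_hits(200, seed = 31)
  out <- filter_and_rank(hits, cfg, db)
  manual <- hits[hits$identity_pct >= 50 & hits$query_coverage_pct >= 70 &
                   hits$evalue <= 1e-6, ]
  expect_setequal(out$subject_id, manual$subject_id)
  expect_equal(out$rank, seq_len(nrow(out)))
  # deterministic total ranking key
  expect_false(is.unsorted(-out$bit_score))

  # boundary: identity exactly at the threshold is kept, just below dropped
  b <- tibble::tibble(query_id = "Q", subject_id = c("a", "b"),
                      identity_pct = c(50, 49.9),
                      query_coverage_pct = 80, evalue = 1e-10,
                      bit_score = 100, rank = NA_integer_)
  kept <- filter_and_rank(b, cfg, db)
  expect_identical(kept$subject_id, "a")
})

test_that("survivor count is monotone in every threshold", {
  db <- tiny_db()
  hits <- random_hits(300, seed = 13)
  n_surv <- function(id, cov, ev) {
    nrow(filter_and_rank(hits, search_config(id, cov, ev), db))
  }
  ids <- c(0, 30, 50, 80, 100); covs <- c(0, 40, 70, 95); evs <- 10^c(0, -5, -10, -20)
  for (cov in covs) for (ev in evs) {
    counts <- sapply(ids, n_surv, cov = cov, ev = ev)
    expect_false(is.unsorted(rev(counts)))
  }
  for (id in ids) for (ev in evs) {
    counts <- sapply(covs, function(cv) n_surv(id, cv, ev))
    expect_false(is.unsorted(rev(counts)))
  }
  for (id in ids) for (cov in covs) {
    counts <- sapply(evs, function(e) n_surv(id, cov, e))
    expect_false(is.unsorted(rev(counts)))  # evs descending -> counts shrink
  }
})

test_that("top_k is a prefix of the ranking with deterministic tie order", {
  db <- tiny_db()
  hits <- filter_and_rank(random_hits(40, seed = 3), search_config(0, 0, 1), db)
  expect_equal(top_k(hits, 15), hits[1:15, ])
  expect_equal(top_k(hits, nrow(hits)), hits)
  expect_equal(nrow(top_k(hits[1:3, ], 15)), 3)
  expect_error(top_k(hits, 0), "k must be >= 1")

  # equal bit scores: order by evalue asc, identity desc, subject lexicographic
  ties <- tibble::tibble(query_id = "Q",
                         subject_id = c("d", "c", "b", "a"),
                         identity_pct = c(60, 60, 70, 60),
                         query_coverage_pct = 90,
                         evalue = c(1e-8, 1e-9, 1e-8, 1e-8),
                         bit_score = 100, rank = NA_integer_)
  ranked <- filter_and_rank(ties, search_config(0, 0, 1), db)
  key <- order(ranked$evalue, -ranked$identity_pct, ranked$subject_id,
               method = "radix")
  expect_equal(key, seq_len(4))
  expect_identical(ranked$subject_id, c("c", "b", "a", "d"))
})

test_that("search output is deterministic and permutation-independent", {
  sf <- shared_fixture()
  again <- builtin_search(sf$qs$sequences, sf$fx$db)
  expect_identical(sf$hits, again)
})
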