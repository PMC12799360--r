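test_that("feature extraction follows the 31-feature schema", {
  sf <- shared_fixture()
  db <- sf$fx$db
  q <- names(sf$qs$sequences)[1]
  th <- top_k(sf$by_q[[q]], 10)
  cand <- annotate_query(q, th, db, "combined", 10)
  inst <- extract_features(cand, th, db, sf$qs$sequences[[q]])
  expect_equal(names(inst), c("query_id", "term_id", feature_schema()))
  expect_equal(nrow(inst), nrow(cand$terms))
  expect_true(all(is.finite(as.matrix(inst[, feature_schema()]))))
  # composition block sums to 1
  comp <- as.matrix(inst[, paste0("comp_", c("A", "C", "D", "E", "F", "G", "H",
                                             "I", "K", "L", "M", "N", "P", "Q",
                                             "R", "S", "T", "V", "W", "Y"))])
  expect_equal(unname(rowSums(comp)), rep(1, nrow(inst)))
  # background frequency equals the brute-force count over annotations
  annotated <- db$annotations[lengths(db$annotations) > 0]
  for (i in sample(nrow(inst), 3)) {
    manual <- mean(vapply(annotated, function(a) inst$term_id[i] %in% a,
                          logical(1)))
    expect_equal(inst$term_background_freq[i], manual)
  }
  # query sequence is mandatory
  expect_error(extract_features(cand, th, db, NULL), "sequence unavailable")
})

test_that("composition handles homopolymers and non-standard letters", {
  comp <- aa_composition("AAAA")
  expect_equal(unname(comp["comp_A"]), 1)
  expect_equal(sum(comp), 1)
  # X / unknown letters drop out of the denominator
  comp2 <- aa_composition("AAXXBB")  # B is non-canonical -> X
  expect_equal(unname(comp2["comp_A"]), 1)
})

test_that("OG-only terms carry zero KNN evidence and a sentinel support rank", {
  db <- tiny_db()
  hits <- tibble::tibble(query_id = "Q", subject_id = c("P1", "P3"),
                         identity_pct = c(90, 85), query_coverage_pct = 95,
                         evalue = c(1e-30, 1e-25), bit_score = c(150, 140),
                         rank = 1:2)
  cand <- annotate_query("Q", hits, db, "combined", 2)
  inst <- extract_features(cand, hits, db, "MKTAYIAKQR")
  og_only <- inst[inst$src_og == 1 & inst$src_knn == 0, ]
  if (nrow(og_only) > 0) {
    expect_true(all(og_only$knn_frequency == 0))
    expect_true(all(og_only$best_support_rank == cand$n_neighbors + 1))
  }
  knn_rows <- inst[inst$src_knn == 1, ]
  expect_true(all(knn_rows$knn_frequency > 0))
})

test_that("build_training_set labels by reference membership and splits by protein", {
  sf <- shared_fixture()
  db <- sf$fx$db
  inst <- do.call(rbind, lapply(names(sf$qs$sequences), function(q) {
    th <- top_k(sf$by_q[[q]], 10)
    extract_features(annotate_query(q, th, db, "combined", 10), th, db,
                     sf$qs$sequences[[q]])
  }))
  sets <- build_training_set(inst, sf$qs$truth, split = 0.8, seed = 5)
  # protein-level split: no query on both sides; 80/20 by query count
  expect_length(intersect(sets$train_queries, sets$test_queries), 0)
  n_q <- length(unique(inst$query_id))
  expect_equal(length(sets$train_queries), floor(0.8 * n_q))
  # label oracle: brute-force membership test
  both <- rbind(sets$train, sets$test)
  manual <- mapply(function(q, t) as.integer(t %in% sf$qs$truth[[q]]),
                   both$query_id, both$term_id)
  expect_equal(both$label, unname(manual))
  # reproducible from seed
  sets2 <- build_training_set(inst, sf$qs$truth, split = 0.8, seed = 5)
  expect_identical(sets$train_queries, sets2$train_queries)
  # queries without reference are excluded with a warning
  expect_warning(
    build_training_set(inst, sf$qs$truth[-1], split = 0.8, seed = 5),
    "without reference annotation")
})

test_that("verifiers train on separable data and reject degenerate labels", {
  set.seed(2)
  n <- 120
  base <- tibble::tibble(query_id = rep(paste0("q", 1:12), each = 10),
                         term_id = rep(sprintf("GO:%07d", 1:10), 12))
  feats <- matrix(runif(n * 31), n, 31, dimnames = list(NULL, feature_schema()))
  label <- as.integer(feats[, "knn_frequency"] > 0.5)  # separable on one feature
  inst <- cbind(base, tibble::as_tibble(feats))
  inst$label <- label
  for (alg in c("lr", "xgb", "rf")) {
    model <- train_verifier(inst, alg, seed = 3)
    scored <- score_instances(model, inst)
    expect_true(all(scored$probability >= 0 & scored$probability <= 1))
    acc <- mean((scored$probability > 0.5) == (label == 1))
    expect_gt(acc, 0.95)
  }
  inst$label <- 1L
  expect_error(train_verifier(inst, "lr"), "single class")
  # schema violations are rejected at scoring time
  inst$label <- label
  model <- train_verifier(inst, "lr")
  expect_error(score_instances(model, inst[, 1:5]), "feature schema")
})

test_that("xgb and rf training is deterministic given the seed", {
  set.seed(4)
  feats <- matrix(runif(600), 60, 10)
  inst <- tibble::as_tibble(matrix(runif(60 * 31), 60, 31,
                                   dimnames = list(NULL, feature_schema())))
  inst$query_id <- rep(paste0("q", 1:6), each = 10)
  inst$term_id <- rep(sprintf("GO:%07d", 1:10), 6)
  inst$label <- rep(c(0L, 1L), 30)
  for (alg in c("xgb", "rf")) {
    p1 <- score_instances(train_verifier(inst, alg, seed = 9), inst)$probability
    p2 <- score_instances(train_verifier(inst, alg, seed = 9), inst)$probability
    expect_identical(p1, p2)
  }
})

test_that("score_and_filter never adds terms and is anti-monotone in t", {
  sf <- shared_fixture()
  db <- sf$fx$db
  q <- names(sf$qs$sequences)[2]
  th <- top_k(sf$by_q[[q]], 10)
  cand <- annotate_query(q, th, db, "combined", 10)
  inst <- extract_features(cand, th, db, sf$qs$sequences[[q]])
  # deterministic fake probabilities keyed to term order
  inst$probability <- seq(0.05, 0.95, length.out = nrow(inst))
  model <- structure(list(algorithm = "lr", fit = NULL,
                          feature_names = feature_schema(), seed = 1),
                     class = "verifier_model")
  prev <- NULL
  for (t in seq(0.1, 0.9, by = 0.2)) {
    out <- score_and_filter(model, cand, inst, t)
    kept <- candidate_terms(out$candidate)
    expect_true(all(kept %in% candidate_terms(cand)))
    # brute-force threshold scan
    expect_setequal(kept, inst$term_id[inst$probability > t])
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # limit cases
  expect_equal(nrow(score_and_filter(model, cand, inst, 0.9999)$candidate$terms), 0)
  expect_setequal(candidate_terms(score_and_filter(model, cand, inst,
                                                   1e-9)$candidate),
                  candidate_terms(cand))
})

test_that("verifier round-trips through its JSON + native persistence", {
  set.seed(8)
  inst <- tibble::as_tibble(matrix(runif(50 * 31), 50, 31,
                                   dimnames = list(NULL, feature_schema())))
  inst$query_id <- rep(paste0("q", 1:5), each = 10)
  inst$term_id <- rep(sprintf("GO:%07d", 1:10), 5)
  inst$label <- as.integer(inst$knn_frequency > 0.5)
  for (alg in c("lr", "xgb", "rf")) {
    model <- train_verifier(inst, alg, seed = 2)
    dir <- withr::local_tempdir()
    save_verifier(model, dir)
    back <- load_verifier(dir)
    expect_equal(back$algorithm, alg)
    expect_equal(score_instances(back, inst)$probability,
                 score_instances(model, inst)$probability, tolerance = 1e-7)
  }
})
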