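AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Names and order of the verification feature vector
#'
#' Thirty-one features in three blocks: a similarity block describing the
#' query's best homology hit and neighborhood (best-hit identity, coverage,
#' -log10 e-value, bit score, realized neighbor count, rank of the best hit
#' supporting the term), a composition block (the 20 relative amino-acid
#' frequencies of the query, with non-standard letters excluded from the
#' denominator), and a term-frequency block (knn_frequency, og_frequency,
#' the two source indicators, and the term's background frequency among
#' annotated reference proteins).
#'
#' @return character vector of length 31.
#' @export
feature_schema <- function() {
  c("best_hit_identity", "best_hit_coverage", "best_hit_neg_log10_evalue",
    "best_hit_bit_score", "n_neighbors", "best_support_rank",
    paste0("comp_", AA20),
    "knn_frequency", "og_frequency", "src_knn", "src_og",
    "term_background_freq")
}

#' Relative amino-acid composition of a sequence
#'
#' Frequencies of the 20 canonical residues; letters outside the canonical
#' alphabet (mapped to 'X') are excluded from the denominator, so the
#' vector sums to 1 for any sequence containing at least one canonical
#' residue.
#'
#' @param seq amino-acid string.
#' @return numeric vector of length 20, named `comp_A` .. `comp_Y`.
#' @export
aa_composition <- function(seq) {
  chars <- strsplit(clean_aa(seq), "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = AA20))
  denom <- sum(counts)
  out <- if (denom > 0) as.numeric(counts) / denom else rep(0, 20)
  stats::setNames(out, paste0("comp_", AA20))
}

#' Extract verification features for every candidate term of a query
#'
#' Builds one term instance (a fixed-order 31-feature vector, see
#' [feature_schema()]) per candidate term. The similarity block is
#' query-level (its best surviving hit) except `best_support_rank`, which is
#' term-specific: the rank of the best neighbor annotated with the term, or
#' `n_neighbors + 1` for terms contributed only by the orthogroup route.
#' E-values are floored at 1e-300 before the -log10 transform so all
#' features stay finite.
#'
#' @param candidate a `candidate_annotation`.
#' @param top_hits the ranked hits the candidate was built from.
#' @param db a [reference_db()].
#' @param query_seq the query's amino-acid sequence (required: the
#'   composition block is computed from it).
#' @return tibble with columns `query_id`, `term_id` and the 31 features.
#' @export
extract_features <- function(candidate, top_hits, db, query_seq) {
  stopifnot(inherits(candidate, "candidate_annotation"),
            inherits(db, "reference_db"))
  if (missing(query_seq) || is.null(query_seq) || !nzchar(query_seq)) {
    stop("query sequence unavailable for ", candidate$query_id,
         "; the composition block requires it")
  }
  terms <- candidate$terms
  n_terms <- nrow(terms)
  if (n_terms == 0) {
    out <- tibble::as_tibble(
      c(list(query_id = character(), term_id = character()),
        stats::setNames(rep(list(numeric()), 31), feature_schema())))
    return(out)
  }
  n_nb <- candidate$n_neighbors
  if (nrow(top_hits) > 0) {
    best <- top_hits[which.min(top_hits$rank), , drop = FALSE]
    sim <- c(best$identity_pct, best$query_coverage_pct,
             -log10(max(best$evalue, 1e-300)), best$bit_score, n_nb)
  } else {
    sim <- c(0, 0, 0, 0, 0)
  }
  support_rank <- ifelse(is.na(terms$best_support_rank), n_nb + 1,
                         terms$best_support_rank)
  comp <- aa_composition(query_seq)
  bg <- term_background_frequency(db, terms$term_id)

  feat <- matrix(0, nrow = n_terms, ncol = 31,
                 dimnames = list(NULL, feature_schema()))
  feat[, 1:5] <- matrix(sim, nrow = n_terms, ncol = 5, byrow = TRUE)
  feat[, "best_support_rank"] <- support_rank
  feat[, paste0("comp_", AA20)] <- matrix(comp, nrow = n_terms, ncol = 20,
                                          byrow = TRUE)
  feat[, "knn_frequency"] <- terms$knn_frequency
  feat[, "og_frequency"] <- terms$og_frequency
  feat[, "src_knn"] <- as.numeric(terms$src_knn)
  feat[, "src_og"] <- as.numeric(terms$src_og)
  feat[, "term_background_freq"] <- bg
  tibble::as_tibble(cbind(
    tibble::tibble(query_id = candidate$query_id, term_id = terms$term_id),
    tibble::as_tibble(feat)))
}

#' Label term instances and split them 80/20 at the protein level
#'
#' Every instance of one query lands on the same side of the split (no
#' leakage of a protein's own instances between train and test). An
#' instance's label is 1 iff its term is present in the query's reference
#' GO annotation. Queries without a reference annotation are excluded with
#' a warning. The split is reproducible from `seed`.
#'
#' @param instances tibble of term instances (from [extract_features()],
#'   possibly row-bound over many queries).
#' @param reference named list: query_id -> character vector of true GO ids.
#' @param split fraction of queries assigned to training (default 0.8).
#' @param seed integer seed for the query shuffle.
#' @return list with `train` and `test` instance tibbles, each with a
#'   `label` column, plus `train_queries` / `test_queries`.
#' @export
build_training_set <- function(instances, reference, split = 0.8, seed = 1) {
  stopifnot(split > 0, split < 1)
  qids <- unique(instances$query_id)
  has_ref <- qids %in% names(reference)
  if (any(!has_ref)) {
    warning(sum(!has_ref), " quer(ies) without reference annotation excluded: ",
            paste(utils::head(qids[!has_ref], 5), collapse = ", "))
    qids <- qids[has_ref]
    instances <- instances[instances$query_id %in% qids, , drop = FALSE]
  }
  labels <- mapply(function(q, t) t %in% reference[[q]],
                   instances$query_id, instances$term_id, USE.NAMES = FALSE)
  instances$label <- as.integer(labels)
  shuffled <- withr_seed(seed, sample(qids))
  n_train <- floor(split * length(shuffled))
  train_q <- shuffled[seq_len(n_train)]
  test_q <- setdiff(shuffled, train_q)
  list(train = instances[instances$query_id %in% train_q, , drop = FALSE],
       test = instances[instances$query_id %in% test_q, , drop = FALSE],
       train_queries = train_q, test_queries = test_q)
}

# run expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

feature_matrix <- function(instances) {
  schema <- feature_schema()
  missing <- setdiff(schema, names(instances))
  if (length(missing) > 0) {
    stop("instances violate the feature schema; missing: ",
         paste(missing, collapse = ", "))
  }
  m <- as.matrix(instances[, schema])
  storage.mode(m) <- "double"
  m
}

#' Train a verification classifier
#'
#' Fits a binary classifier on labeled term instances. `"lr"` is an
#' unregularized logistic regression (`stats::glm`, binomial family),
#' `"xgb"` gradient boosting (`xgboost`: 200 rounds, depth 6, eta 0.1,
#' logistic objective), `"rf"` a random forest (`randomForest`: 500 trees,
#' sqrt-features per split). Tree learners are seeded, so training is
#' deterministic given `seed`.
#'
#' @param train labeled instance tibble (needs a 0/1 `label` column with
#'   both classes present).
#' @param algorithm `"xgb"`, `"lr"` or `"rf"`.
#' @param hyperparams named list overriding the defaults above
#'   (`nrounds`, `max_depth`, `eta` for xgb; `ntree`, `mtry` for rf).
#' @param seed integer seed.
#' @param pos_weight weight on positive-class instances (default 1,
#'   i.e. unweighted).
#' @return a `verifier_model` (algorithm, fit, feature schema, seed, sizes).
#' @export
train_verifier <- function(train, algorithm = c("xgb", "lr", "rf"),
                           hyperparams = list(), seed = 1, pos_weight = 1) {
  algorithm <- match.arg(algorithm)
  if (!"label" %in% names(train)) {
    stop("training instances must carry a `label` column")
  }
  y <- as.integer(train$label)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; cannot fit a verifier")
  }
  x <- feature_matrix(train)
  w <- ifelse(y == 1, pos_weight, 1)
  fit <- switch(algorithm,
    lr = {
      df <- as.data.frame(x)
      df$.label <- y
      suppressWarnings(stats::glm(.label ~ ., data = df, family = stats::binomial,
                                  weights = w))
    },
    xgb = {
      hp <- utils::modifyList(list(nrounds = 200, max_depth = 6, eta = 0.1),
                              hyperparams)
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y, weight = w)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                      eta = hp$eta, nthread = 1, seed = seed),
        data = dtrain, nrounds = hp$nrounds, verbose = 0)
    },
    rf = {
      hp <- utils::modifyList(
        list(ntree = 500, mtry = floor(sqrt(ncol(x)))), hyperparams)
      set.seed(seed)
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = hp$ntree, mtry = hp$mtry)
    })
  structure(list(algorithm = algorithm, fit = fit,
                 feature_names = feature_schema(), seed = seed,
                 n_train = nrow(train), n_pos = sum(y)),
            class = "verifier_model")
}

#' @export
print.verifier_model <- function(x, ...) {
  cat("<verifier_model> ", toupper(x$algorithm), ", trained on ", x$n_train,
      " instances (", x$n_pos, " positive), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Score term instances with a trained verifier
#'
#' @param model a `verifier_model`.
#' @param instances instance tibble conforming to the model's feature
#'   schema.
#' @return the instances with a `probability` column in \[0, 1\].
#' @export
score_instances <- function(model, instances) {
  stopifnot(inherits(model, "verifier_model"))
  if (nrow(instances) == 0) {
    instances$probability <- numeric(0)
    return(instances)
  }
  x <- feature_matrix(instances)
  p <- switch(model$algorithm,
    # collinear feature blocks (e.g. constant source indicators) make the
    # unregularized fit rank-deficient; predictions remain well-defined
    lr = as.numeric(suppressWarnings(
      stats::predict(model$fit, as.data.frame(x), type = "response"))),
    xgb = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(x))),
    rf = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]))
  instances$probability <- pmin(pmax(p, 0), 1)
  instances
}

#' Verify a candidate annotation at a probability threshold
#'
#' Scores every candidate term and retains those with probability strictly
#' greater than `threshold`. Verification filters: the retained set is
#' always a subset of the candidate set (terms are never added), and raising
#' the threshold can only shrink it.
#'
#' @param model a `verifier_model`.
#' @param candidate a `candidate_annotation`.
#' @param instances the candidate's term instances ([extract_features()]);
#'   scored in place if they lack a `probability` column.
#' @param threshold cutoff t in (0, 1); retain iff p > t.
#' @return list with `candidate` (the filtered annotation, method suffixed
#'   `"+ML"`) and `instances` (scored).
#' @export
score_and_filter <- function(model, candidate, instances, threshold) {
  stopifnot(inherits(candidate, "candidate_annotation"),
            threshold > 0, threshold < 1)
  if (!"probability" %in% names(instances)) {
    instances <- score_instances(model, instances)
  }
  if (nrow(instances) > 0 &&
      !setequal(instances$term_id, candidate$terms$term_id)) {
    stop("instances do not match the candidate's term set")
  }
  keep_terms <- instances$term_id[instances$probability > threshold]
  filtered <- candidate
  filtered$terms <- candidate$terms[candidate$terms$term_id %in% keep_terms, ,
                                    drop = FALSE]
  filtered$method <- paste0(candidate$method, "+ML")
  list(candidate = filtered, instances = instances)
}

#' Save / load a verifier model
#'
#' Persistence uses a versioned JSON header (schema, algorithm, seed, sizes)
#' plus the algorithm-native payload, both inside one directory.
#'
#' @param model a `verifier_model`.
#' @param dir directory to write to (created if needed).
#' @return `save_verifier`: invisibly, the directory; `load_verifier`: the
#'   restored `verifier_model`.
#' @export
save_verifier <- function(model, dir) {
  stopifnot(inherits(model, "verifier_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- list(format_version = 1L, algorithm = model$algorithm,
                 feature_names = model$feature_names, seed = model$seed,
                 n_train = model$n_train, n_pos = model$n_pos)
  jsonlite::write_json(header, file.path(dir, "model.json"), auto_unbox = TRUE)
  payload <- file.path(dir, "payload")
  switch(model$algorithm,
    xgb = xgboost::xgb.save(model$fit, paste0(payload, ".ubj")),
    saveRDS(model$fit, paste0(payload, ".rds")))
  invisible(dir)
}

#' @rdname save_verifier
#' @param dir directory written by [save_verifier()].
#' @export
load_verifier <- function(dir) {
  header <- jsonlite::read_json(file.path(dir, "model.json"), simplifyVector = TRUE)
  fit <- if (header$algorithm == "xgb") {
    xgboost::xgb.load(file.path(dir, "payload.ubj"))
  } else {
    readRDS(file.path(dir, "payload.rds"))
  }
  structure(list(algorithm = header$algorithm, fit = fit,
                 feature_names = header$feature_names, seed = header$seed,
                 n_train = header$n_train, n_pos = header$n_pos),
            class = "verifier_model")
}
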