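#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run: the reference database (an
#' in-memory [reference_db()] or the paths to load one), the queries (named
#' character vector or FASTA path), the reference annotations used for
#' training/evaluation (named list or TSV path), an optional precomputed
#' tabular hits file (skips the built-in search), the search filters, the
#' annotation method, optional verifier settings, and evaluation options.
#'
#' @param db a [reference_db()], or a named list of paths
#'   (`fasta`, `annotations`, `memberships`, optionally `aspects`).
#' @param queries named character vector of query sequences, or a FASTA path.
#' @param reference named list query_id -> GO ids, or a TSV path
#'   (query_id, go_term); optional when neither verification nor evaluation
#'   is requested.
#' @param hits_file optional blast6-style tabular hits file.
#' @param search a [search_config()].
#' @param method `"combined"`, `"knn"` or `"og"`.
#' @param verify `NULL` (skip verification) or a list with any of
#'   `algorithm` ("xgb"/"lr"/"rf", default "xgb"), `split` (default 0.8),
#'   `threshold` (default: the Fmax-optimal threshold on the test split),
#'   `hyperparams`, `pos_weight`.
#' @param grid_step Fmax threshold grid step (default 0.1).
#' @param micro use micro instead of per-protein macro averaging.
#' @param out_dir output directory; `NULL` runs in memory only.
#' @param seed integer seed driving every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(db, queries, reference = NULL, hits_file = NULL,
                            search = search_config(),
                            method = c("combined", "knn", "og"),
                            verify = NULL, grid_step = 0.1, micro = FALSE,
                            out_dir = NULL, seed = 1) {
  method <- match.arg(method)
  if (!is.null(verify)) {
    verify <- utils::modifyList(
      list(algorithm = "xgb", split = 0.8, threshold = NULL,
           hyperparams = list(), pos_weight = 1), verify)
  }
  for (p in c(hits_file,
              if (!inherits(db, "reference_db")) unlist(db),
              if (is.character(queries) && length(queries) == 1 &&
                  file.exists(queries)) queries)) {
    if (is.character(p) && length(p) == 1 && !file.exists(p)) {
      stop("configured path does not exist: ", p)
    }
  }
  structure(list(db = db, queries = queries, reference = reference,
                 hits_file = hits_file, search = search, method = method,
                 verify = verify, grid_step = grid_step, micro = micro,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

resolve_db <- function(db) {
  if (inherits(db, "reference_db")) {
    return(db)
  }
  load_reference(db$fasta, db$annotations, db$memberships,
                 aspect_path = db$aspects)
}

resolve_queries <- function(queries) {
  if (length(queries) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  if (is.character(queries) && length(queries) == 1 && file.exists(queries)) {
    return(read_fasta_named(queries))
  }
  if (is.null(names(queries))) {
    stop("queries must be a named vector or a FASTA path")
  }
  queries
}

resolve_reference <- function(reference) {
  if (is.null(reference)) {
    return(NULL)
  }
  if (is.character(reference) && length(reference) == 1) {
    return(read_annotation_list(reference))
  }
  reference
}

#' Run the full annotation pipeline
#'
#' Executes search -> annotate -> (optionally) verify -> evaluate on one
#' configuration and, when `out_dir` is set, writes stage outputs with
#' stable filenames plus a manifest recording the package version, seed,
#' config hash and md5 checksums of every output, so a rerun with an
#' identical config is checkable for bitwise reproducibility.
#'
#' Verification, when requested, splits the queries at the protein level
#' (fraction `verify$split` for training), trains the verifier on the
#' training side, and reports threshold-swept Fmax on the held-out side;
#' the filtered annotations use the Fmax-optimal threshold unless one is
#' given. Evaluation of unverified annotations covers all queries with a
#' reference set.
#'
#' @param config a [pipeline_config()].
#' @return list with `candidates` (per-query `candidate_annotation`s),
#'   `hits`, `report` (unfiltered `eval_report` or NULL), `fmax` (verified
#'   Fmax result or NULL), `report_verified` (eval of the filtered
#'   annotations on the test split, or NULL), `verifier`, `scored`
#'   (instances with probabilities), `per_aspect` (when the DB has an
#'   aspect map), `manifest`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  db <- resolve_db(config$db)
  queries <- resolve_queries(config$queries)
  reference <- resolve_reference(config$reference)
  say("stage load: ", length(queries), " queries vs ", nrow(db$proteins),
      " reference proteins")

  hits <- if (!is.null(config$hits_file)) {
    raw <- parse_tabular_hits(config$hits_file, queries)
    say("stage search: ", nrow(raw), " tabular hits read")
    filter_and_rank(raw, config$search, db, queries)
  } else {
    builtin_search(queries, db, config$search)
  }
  say("stage search: ", nrow(hits), " hits pass filters")

  by_q <- hits_by_query(hits, names(queries))
  candidates <- lapply(names(queries), function(q) {
    annotate_query(q, by_q[[q]], db, method = config$method,
                   k = config$search$k)
  })
  names(candidates) <- names(queries)
  n_terms <- sum(vapply(candidates, function(x) nrow(x$terms), numeric(1)))
  say("stage annotate (", config$method, ", k=", config$search$k, "): ",
      n_terms, " candidate terms over ", length(candidates), " queries")

  predicted <- lapply(candidates, candidate_terms)
  report <- NULL
  aspect_reports <- NULL
  if (!is.null(reference)) {
    report <- evaluate_annotations(predicted, reference, micro = config$micro)
    say("stage evaluate (unfiltered): F1 = ",
        round(report$aggregate[["f1"]], 4), " over ", report$n_proteins,
        " proteins [", report$averaging, "]")
    if (!is.null(db$aspect_map)) {
      aspect_reports <- per_aspect(predicted, reference, db$aspect_map,
                                   micro = config$micro)
    }
  }

  verifier <- NULL
  scored <- NULL
  fmax_res <- NULL
  report_verified <- NULL
  filtered <- NULL
  if (!is.null(config$verify)) {
    if (is.null(reference)) {
      stop("verification requires reference annotations for training")
    }
    instances <- do.call(rbind, lapply(names(candidates), function(q) {
      extract_features(candidates[[q]], by_q[[q]], db, queries[[q]])
    }))
    sets <- build_training_set(instances, reference,
                               split = config$verify$split, seed = config$seed)
    say("stage verify: ", nrow(sets$train), " train / ", nrow(sets$test),
        " test instances (protein-level split, seed ", config$seed, ")")
    verifier <- train_verifier(sets$train, config$verify$algorithm,
                               hyperparams = config$verify$hyperparams,
                               seed = config$seed,
                               pos_weight = config$verify$pos_weight)
    scored <- score_instances(verifier, sets$test)
    fmax_res <- f_max(scored, reference[sets$test_queries],
                      grid = fmax_grid(config$grid_step), micro = config$micro)
    say("stage verify: held-out Fmax = ", round(fmax_res$fmax, 4),
        " at t* = ", fmax_res$t_star)
    thr <- if (!is.null(config$verify$threshold)) config$verify$threshold
           else fmax_res$t_star
    test_cands <- candidates[sets$test_queries]
    filtered <- lapply(sets$test_queries, function(q) {
      inst_q <- scored[scored$query_id == q, , drop = FALSE]
      score_and_filter(verifier, candidates[[q]], inst_q, thr)$candidate
    })
    names(filtered) <- sets$test_queries
    retained <- sum(vapply(filtered, function(x) nrow(x$terms), numeric(1)))
    say("stage verify: ", retained, " terms retained at t = ", thr)
    report_verified <- evaluate_annotations(lapply(filtered, candidate_terms),
                                            reference[sets$test_queries],
                                            micro = config$micro)
  }

  files <- character(0)
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    files <- write_pipeline_outputs(config, candidates, filtered, scored,
                                    report, report_verified, fmax_res,
                                    aspect_reports, log_lines)
    manifest <- jsonlite::read_json(files[["manifest"]])
  }

  invisible(list(candidates = candidates, hits = hits, report = report,
                 per_aspect = aspect_reports, verifier = verifier,
                 scored = scored, fmax = fmax_res,
                 report_verified = report_verified, filtered = filtered,
                 manifest = manifest, files = files, log = log_lines))
}

report_to_list <- function(report) {
  if (is.null(report)) {
    return(NULL)
  }
  list(aggregate = as.list(report$aggregate), n_proteins = report$n_proteins,
       averaging = report$averaging)
}

write_pipeline_outputs <- function(config, candidates, filtered, scored,
                                   report, report_verified, fmax_res,
                                   aspect_reports, log_lines) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  files <- c(annotations = path("annotations.tsv"))
  utils::write.table(candidates_to_table(candidates), files[["annotations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(scored)) {
    files[["scored_terms"]] <- path("scored_terms.tsv")
    cols <- intersect(c("query_id", "term_id", "probability", "label"),
                      names(scored))
    utils::write.table(as.data.frame(scored[, cols]), files[["scored_terms"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(filtered)) {
    files[["annotations_verified"]] <- path("annotations_verified.tsv")
    utils::write.table(candidates_to_table(filtered),
                       files[["annotations_verified"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report)) {
    files[["per_protein"]] <- path("report_per_protein.tsv")
    utils::write.table(as.data.frame(report$per_protein),
                       files[["per_protein"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files[["report"]] <- path("report.json")
  jsonlite::write_json(list(
    unfiltered = report_to_list(report),
    verified = report_to_list(report_verified),
    fmax = if (!is.null(fmax_res)) list(fmax = fmax_res$fmax,
                                        t_star = fmax_res$t_star),
    per_aspect = if (!is.null(aspect_reports)) {
      lapply(aspect_reports, report_to_list)
    }), files[["report"]], auto_unbox = TRUE, pretty = TRUE, digits = NA,
    null = "null")
  files[["log"]] <- path("run.log")
  writeLines(log_lines, files[["log"]])

  # resolved config + manifest with checksums; in-memory objects are
  # summarized by content and the output location is dropped, so two runs
  # of the same analysis hash identically wherever they are written
  cfg <- config
  cfg$out_dir <- NULL
  cfg$db <- if (inherits(cfg$db, "reference_db")) {
    list(in_memory = TRUE, n_proteins = nrow(cfg$db$proteins),
         n_orthogroups = length(cfg$db$og_members))
  } else cfg$db
  cfg$queries <- if (is.character(cfg$queries) && length(cfg$queries) > 1) {
    list(in_memory = TRUE, n = length(cfg$queries),
         ids = paste(names(cfg$queries), collapse = ","))
  } else cfg$queries
  cfg$reference <- if (is.list(cfg$reference)) {
    list(in_memory = TRUE, n = length(cfg$reference))
  } else cfg$reference
  files[["config"]] <- path("resolved_config.json")
  jsonlite::write_json(unclass(cfg), files[["config"]], auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE, null = "null")

  files[["manifest"]] <- path("manifest.json")
  sums <- tools::md5sum(unname(files[names(files) != "manifest"]))
  names(sums) <- basename(names(sums))
  jsonlite::write_json(list(
    package = "orthogo",
    version = as.character(utils::packageVersion("orthogo")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(files[["config"]])),
    outputs = as.list(sums)), files[["manifest"]], auto_unbox = TRUE,
    pretty = TRUE)
  files
}
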