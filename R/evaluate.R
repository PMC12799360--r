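#' Confusion counts between predicted and reference GO term sets
#'
#' @param predicted character vector of predicted GO ids (treated as a set).
#' @param reference character vector of reference (true) GO ids.
#' @return list with integers `tp` (terms in both), `fp` (predicted only),
#'   `fn` (reference only).
#' @export
confusion <- function(predicted, reference) {
  predicted <- unique(as.character(predicted))
  reference <- unique(as.character(reference))
  tp <- sum(predicted %in% reference)
  list(tp = tp, fp = length(predicted) - tp, fn = length(reference) - tp)
}

#' Precision, recall, accuracy and F-score from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`, accuracy is the
#' arithmetic mean of precision and recall, and the F-score their harmonic
#' mean. Degenerate denominators follow the package's conventions:
#' precision is 0 when nothing was predicted, recall is 0 when the
#' reference is empty, and F is 0 when precision + recall = 0.
#'
#' @param counts list with `tp`, `fp`, `fn` (see [confusion()]).
#' @return named numeric vector `precision`, `recall`, `accuracy`, `f1`.
#' @export
annotation_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, accuracy = (pr + rc) / 2, f1 = f1)
}

#' Evaluate predicted annotations against a reference
#'
#' Computes per-protein confusion counts and metrics, and an aggregate
#' under either averaging scheme. The default is the CAFA-style per-protein
#' macro average: precision and recall are averaged over evaluated proteins
#' and combined into accuracy (arithmetic mean) and F (harmonic mean);
#' `micro = TRUE` instead pools the tp/fp/fn counts first. Proteins with an
#' empty reference and an empty prediction carry no information and are
#' excluded from averaging.
#'
#' @param predicted named list: query_id -> predicted GO ids.
#' @param reference named list: query_id -> reference GO ids. Evaluation
#'   runs over the queries named here.
#' @param micro use micro (pooled-count) averaging.
#' @return list of class `eval_report`: `per_protein` tibble (query_id, tp,
#'   fp, fn, precision, recall, accuracy, f1), `aggregate` named vector,
#'   `n_proteins`, `averaging`.
#' @export
evaluate_annotations <- function(predicted, reference, micro = FALSE) {
  qids <- names(reference)
  rows <- lapply(qids, function(q) {
    pred <- predicted[[q]]
    if (is.null(pred)) pred <- character(0)
    cts <- confusion(pred, reference[[q]])
    if (cts$tp + cts$fp + cts$fn == 0) {
      return(NULL)  # empty vs empty: excluded
    }
    m <- annotation_metrics(cts)
    tibble::tibble(query_id = q, tp = cts$tp, fp = cts$fp, fn = cts$fn,
                   precision = m[["precision"]], recall = m[["recall"]],
                   accuracy = m[["accuracy"]], f1 = m[["f1"]])
  })
  per_protein <- do.call(rbind, rows)
  if (is.null(per_protein)) {
    per_protein <- tibble::tibble(query_id = character(), tp = integer(),
                                  fp = integer(), fn = integer(),
                                  precision = numeric(), recall = numeric(),
                                  accuracy = numeric(), f1 = numeric())
  }
  aggregate <- aggregate_metrics(per_protein, micro)
  structure(list(per_protein = per_protein, aggregate = aggregate,
                 n_proteins = nrow(per_protein),
                 averaging = if (micro) "micro" else "macro (per-protein)"),
            class = "eval_report")
}

aggregate_metrics <- function(per_protein, micro = FALSE) {
  if (nrow(per_protein) == 0) {
    return(c(precision = 0, recall = 0, accuracy = 0, f1 = 0))
  }
  if (micro) {
    return(annotation_metrics(list(tp = sum(per_protein$tp),
                                   fp = sum(per_protein$fp),
                                   fn = sum(per_protein$fn))))
  }
  pr <- mean(per_protein$precision)
  rc <- mean(per_protein$recall)
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  c(precision = pr, recall = rc, accuracy = (pr + rc) / 2, f1 = f1)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> ", x$n_proteins, " protein(s), ", x$averaging,
      " averaging\n", sep = "")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Threshold grid for Fmax
#'
#' The open interval (0, 1) stepped by `step`; with the default step 0.1
#' this is exactly \{0.1, ..., 0.9\}.
#'
#' @param step grid step in (0, 1).
#' @return numeric vector of thresholds.
#' @export
fmax_grid <- function(step = 0.1) {
  stopifnot(step > 0, step < 1)
  seq(step, 1 - step / 2, by = step)
}

#' Fmax over a threshold grid
#'
#' For each threshold t in the grid, the predicted set of a protein is the
#' terms with probability strictly greater than t; the F-score of the
#' resulting annotation is computed under the configured averaging, and
#' Fmax is the maximum over the grid (reported with the smallest argmax
#' threshold).
#'
#' @param scored tibble of scored instances with columns `query_id`,
#'   `term_id`, `probability`.
#' @param reference named list: query_id -> reference GO ids. Proteins with
#'   scored instances but no reference set are excluded with a warning.
#' @param grid threshold grid (default [fmax_grid()]).
#' @param micro use micro averaging.
#' @return list: `fmax`, `t_star`, `table` (tibble threshold / precision /
#'   recall / accuracy / f1).
#' @export
f_max <- function(scored, reference, grid = fmax_grid(), micro = FALSE) {
  missing_ref <- setdiff(unique(scored$query_id), names(reference))
  if (length(missing_ref) > 0) {
    warning(length(missing_ref),
            " protein(s) without a reference set excluded from Fmax")
    scored <- scored[!scored$query_id %in% missing_ref, , drop = FALSE]
  }
  rows <- lapply(grid, function(t) {
    kept <- scored[scored$probability > t, , drop = FALSE]
    pred <- split(kept$term_id, kept$query_id)
    agg <- evaluate_annotations(pred, reference, micro = micro)$aggregate
    tibble::tibble(threshold = t, precision = agg[["precision"]],
                   recall = agg[["recall"]], accuracy = agg[["accuracy"]],
                   f1 = agg[["f1"]])
  })
  tab <- do.call(rbind, rows)
  i <- which.max(tab$f1)  # smallest argmax: which.max takes the first
  list(fmax = tab$f1[i], t_star = tab$threshold[i], table = tab)
}

#' Per-aspect evaluation (BP / MF / CC / unknown)
#'
#' Restricts predicted and reference sets to one GO aspect at a time before
#' confusion counting; terms absent from the aspect map fall into the
#' `"unknown"` aspect. Within an aspect, proteins whose restricted
#' reference and prediction are both empty are excluded from that aspect's
#' averaging.
#'
#' @param predicted named list: query_id -> predicted GO ids.
#' @param reference named list: query_id -> reference GO ids.
#' @param aspect_map named character vector term -> BP/MF/CC.
#' @param micro use micro averaging.
#' @return named list of `eval_report`s: BP, MF, CC, unknown.
#' @export
per_aspect <- function(predicted, reference, aspect_map, micro = FALSE) {
  aspect_of <- function(terms) {
    a <- aspect_map[terms]
    a[is.na(a)] <- "unknown"
    a
  }
  out <- lapply(c(BP = "BP", MF = "MF", CC = "CC", unknown = "unknown"),
                function(asp) {
    pred_a <- lapply(predicted, function(p) p[aspect_of(p) == asp])
    ref_a <- lapply(reference, function(r) r[aspect_of(r) == asp])
    evaluate_annotations(pred_a, ref_a, micro = micro)
  })
  out
}

#' Sweep the neighbor count k
#'
#' Reruns annotation at each k of a grid on a fixed hit set and reports the
#' aggregate metrics per k, plus the argmax k by F-score. Hits are searched
#' (or supplied) once; only the truncation to k varies.
#'
#' @param queries named character vector of query sequences.
#' @param db a [reference_db()].
#' @param reference named list of reference GO sets.
#' @param k_grid integer grid (default \{5, 10, 15, 20, 25, 30\}).
#' @param method annotation method (`"combined"`, `"knn"`, `"og"`).
#' @param config a [search_config()] (its `k` is ignored; the grid rules).
#' @param hits optional precomputed filtered hits (skips the built-in
#'   search).
#' @param micro use micro averaging.
#' @return list: `table` (tibble k / precision / recall / accuracy / f1),
#'   `best_k`.
#' @export
sweep_k <- function(queries, db, reference, k_grid = c(5L, 10L, 15L, 20L, 25L, 30L),
                    method = "combined", config = search_config(), hits = NULL,
                    micro = FALSE) {
  stopifnot(all(k_grid >= 1))
  if (is.null(hits)) {
    hits <- builtin_search(queries, db, config)
  }
  by_q <- hits_by_query(hits, names(queries))
  rows <- lapply(k_grid, function(k) {
    pred <- lapply(names(queries), function(q) {
      candidate_terms(annotate_query(q, by_q[[q]], db, method = method, k = k))
    })
    names(pred) <- names(queries)
    agg <- evaluate_annotations(pred, reference, micro = micro)$aggregate
    tibble::tibble(k = as.integer(k), precision = agg[["precision"]],
                   recall = agg[["recall"]], accuracy = agg[["accuracy"]],
                   f1 = agg[["f1"]])
  })
  tab <- do.call(rbind, rows)
  list(table = tab, best_k = tab$k[which.max(tab$f1)])
}
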