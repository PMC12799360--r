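#' @importFrom tibble tibble as_tibble
NULL

term_columns <- c("term_id", "src_knn", "src_og", "knn_frequency",
                  "og_frequency", "n_supporting_hits", "best_support_rank",
                  "best_support_identity", "best_support_evalue")

empty_terms <- function() {
  tibble::tibble(term_id = character(), src_knn = logical(), src_og = logical(),
                 knn_frequency = numeric(), og_frequency = numeric(),
                 n_supporting_hits = integer(), best_support_rank = integer(),
                 best_support_identity = numeric(), best_support_evalue = numeric())
}

new_candidate <- function(query_id, method, terms = empty_terms(),
                          voted_orthogroup = NA_character_, vote_count = 0L,
                          n_neighbors = 0L) {
  structure(list(query_id = query_id, method = method,
                 voted_orthogroup = voted_orthogroup,
                 vote_count = as.integer(vote_count),
                 n_neighbors = as.integer(n_neighbors),
                 terms = terms),
            class = "candidate_annotation")
}

#' @export
print.candidate_annotation <- function(x, ...) {
  cat("<candidate_annotation> query ", x$query_id, " [", x$method, "]: ",
      nrow(x$terms), " candidate term(s)", sep = "")
  if (!is.na(x$voted_orthogroup)) {
    cat("; voted orthogroup ", x$voted_orthogroup, " (", x$vote_count,
        " vote(s))", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Candidate term ids of an annotation
#' @param x a `candidate_annotation`.
#' @return character vector of GO ids.
#' @export
candidate_terms <- function(x) {
  stopifnot(inherits(x, "candidate_annotation"))
  x$terms$term_id
}

#' Annotate a query by k-nearest-homolog GO transfer (KNN)
#'
#' The query is assigned the union (duplicates removed) of the GO terms of
#' its k most similar reference homologs. Each term's `knn_frequency` is the
#' fraction of the realized neighbors (min(k, available), not nominal k)
#' annotated with it, and supporting-hit evidence records the best
#' (lowest-rank) neighbor carrying the term.
#'
#' @param query_id query identifier.
#' @param top_hits ranked hits for this query, already filtered and
#'   truncated to k (see [top_k()]).
#' @param db a [reference_db()].
#' @return a `candidate_annotation` with `method = "KNN"`. Zero hits yield
#'   an empty term table (the query is unannotatable by KNN).
#' @export
knn_annotate <- function(query_id, top_hits, db) {
  stopifnot(inherits(db, "reference_db"))
  n <- nrow(top_hits)
  if (n == 0) {
    return(new_candidate(query_id, "KNN"))
  }
  if (any(top_hits$query_id != query_id)) {
    stop("top_hits do not belong to query ", query_id)
  }
  per_hit_terms <- db$annotations[top_hits$subject_id]
  lens <- lengths(per_hit_terms)
  if (sum(lens) == 0) {
    return(new_candidate(query_id, "KNN", n_neighbors = n))
  }
  long <- data.frame(
    term_id = unlist(per_hit_terms, use.names = FALSE),
    rank = rep(top_hits$rank, lens),
    identity = rep(top_hits$identity_pct, lens),
    evalue = rep(top_hits$evalue, lens),
    stringsAsFactors = FALSE)
  long <- long[order(long$term_id, long$rank), , drop = FALSE]
  first <- !duplicated(long$term_id)
  counts <- table(long$term_id)
  terms <- tibble::tibble(
    term_id = long$term_id[first],
    src_knn = TRUE,
    src_og = FALSE,
    knn_frequency = as.numeric(counts[long$term_id[first]]) / n,
    og_frequency = 0,
    n_supporting_hits = as.integer(counts[long$term_id[first]]),
    best_support_rank = as.integer(long$rank[first]),
    best_support_identity = long$identity[first],
    best_support_evalue = long$evalue[first])
  new_candidate(query_id, "KNN", terms, n_neighbors = n)
}

#' Vote the query's orthogroup from its nearest homologs
#'
#' Each neighbor contributes the orthogroup of its most ancient ancestral
#' taxon ([most_ancient_orthogroup()]); neighbors without any membership
#' abstain. The winner is the modal orthogroup; ties are broken in favor of
#' the orthogroup containing the best-ranked (rank-1-most) hit among the
#' tied groups.
#'
#' @param top_hits ranked hits for one query, filtered and truncated to k.
#' @param db a [reference_db()].
#' @return list with `orthogroup_id` (or `NA_character_` when every neighbor
#'   abstains) and `vote_count` (0 in that case).
#' @export
vote_orthogroup <- function(top_hits, db) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(top_hits) == 0) {
    return(list(orthogroup_id = NA_character_, vote_count = 0L))
  }
  ogs <- vapply(top_hits$subject_id, function(p) most_ancient_orthogroup(db, p),
                character(1))
  voting <- !is.na(ogs)
  if (!any(voting)) {
    return(list(orthogroup_id = NA_character_, vote_count = 0L))
  }
  votes <- table(ogs[voting])
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    # earliest-ranked hit among the tied orthogroups decides
    ranks <- top_hits$rank[voting]
    groups <- ogs[voting]
    best_rank <- vapply(top, function(g) min(ranks[groups == g]), numeric(1))
    top <- top[order(best_rank, top)][1]
  }
  list(orthogroup_id = top[1], vote_count = as.integer(max(votes)))
}

#' Annotate a query from its voted orthogroup (OG)
#'
#' Pools the GO terms of every member of the orthogroup elected by
#' [vote_orthogroup()] and assigns them to the query; `og_frequency` per
#' term is the fraction of the orthogroup's members annotated with it.
#'
#' @inheritParams knn_annotate
#' @return a `candidate_annotation` with `method = "OG"`; empty when the
#'   vote abstains.
#' @export
og_annotate <- function(query_id, top_hits, db) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(top_hits) > 0 && any(top_hits$query_id != query_id)) {
    stop("top_hits do not belong to query ", query_id)
  }
  vote <- vote_orthogroup(top_hits, db)
  if (is.na(vote$orthogroup_id)) {
    return(new_candidate(query_id, "OG", n_neighbors = nrow(top_hits)))
  }
  freqs <- orthogroup_term_frequencies(db, vote$orthogroup_id)
  if (length(freqs) == 0) {
    return(new_candidate(query_id, "OG", voted_orthogroup = vote$orthogroup_id,
                         vote_count = vote$vote_count,
                         n_neighbors = nrow(top_hits)))
  }
  terms <- tibble::tibble(
    term_id = names(freqs),
    src_knn = FALSE,
    src_og = TRUE,
    knn_frequency = 0,
    og_frequency = as.numeric(freqs),
    n_supporting_hits = 0L,
    best_support_rank = NA_integer_,
    best_support_identity = NA_real_,
    best_support_evalue = NA_real_)
  new_candidate(query_id, "OG", terms, voted_orthogroup = vote$orthogroup_id,
                vote_count = vote$vote_count, n_neighbors = nrow(top_hits))
}

#' Combine KNN and OG candidate annotations (KNN+OG)
#'
#' Key-union of the two term sets, duplicates removed: terms found by both
#' routes carry both sources and both frequencies; terms unique to one side
#' keep that side's evidence.
#'
#' @param knn_ann a `candidate_annotation` from [knn_annotate()].
#' @param og_ann a `candidate_annotation` from [og_annotate()] for the same
#'   query.
#' @return a `candidate_annotation` with `method = "KNN+OG"`.
#' @export
combine_knn_og <- function(knn_ann, og_ann) {
  stopifnot(inherits(knn_ann, "candidate_annotation"),
            inherits(og_ann, "candidate_annotation"))
  if (!identical(knn_ann$query_id, og_ann$query_id)) {
    stop("cannot combine annotations of different queries: ",
         knn_ann$query_id, " vs ", og_ann$query_id)
  }
  kt <- knn_ann$terms
  ot <- og_ann$terms
  all_ids <- sort(unique(c(kt$term_id, ot$term_id)))
  ki <- match(all_ids, kt$term_id)
  oi <- match(all_ids, ot$term_id)
  pick <- function(col, default) {
    kv <- ifelse(is.na(ki), default, kt[[col]][ki])
    ov <- ifelse(is.na(oi), default, ot[[col]][oi])
    list(k = kv, o = ov)
  }
  kf <- pick("knn_frequency", 0)
  of <- pick("og_frequency", 0)
  terms <- tibble::tibble(
    term_id = all_ids,
    src_knn = !is.na(ki),
    src_og = !is.na(oi),
    knn_frequency = kf$k,
    og_frequency = of$o,
    n_supporting_hits = ifelse(is.na(ki), 0L, kt$n_supporting_hits[ki]),
    best_support_rank = ifelse(is.na(ki), NA_integer_, kt$best_support_rank[ki]),
    best_support_identity = ifelse(is.na(ki), NA_real_,
                                   kt$best_support_identity[ki]),
    best_support_evalue = ifelse(is.na(ki), NA_real_, kt$best_support_evalue[ki]))
  if (nrow(terms) == 0) terms <- empty_terms()
  new_candidate(knn_ann$query_id, "KNN+OG", terms,
                voted_orthogroup = og_ann$voted_orthogroup,
                vote_count = og_ann$vote_count,
                n_neighbors = max(knn_ann$n_neighbors, og_ann$n_neighbors))
}

#' Annotate one query end to end
#'
#' Convenience wrapper: truncates the query's filtered hits to k and runs
#' the requested algorithm.
#'
#' @param query_id query identifier.
#' @param hits filtered, ranked hits for this query (all ranks).
#' @param db a [reference_db()].
#' @param method `"knn"`, `"og"` or `"combined"`.
#' @param k neighbor count.
#' @return a `candidate_annotation`.
#' @export
annotate_query <- function(query_id, hits, db, method = c("combined", "knn", "og"),
                           k = 15) {
  method <- match.arg(method)
  th <- top_k(hits, k)
  switch(method,
         knn = knn_annotate(query_id, th, db),
         og = og_annotate(query_id, th, db),
         combined = combine_knn_og(knn_annotate(query_id, th, db),
                                   og_annotate(query_id, th, db)))
}

#' Flatten candidate annotations to a table
#'
#' One row per (query, term) with provenance, for TSV export.
#'
#' @param candidates list of `candidate_annotation` objects.
#' @return tibble with columns query_id, method, term_id, sources,
#'   knn_frequency, og_frequency, best_support_identity, voted_orthogroup.
#' @export
candidates_to_table <- function(candidates) {
  rows <- lapply(candidates, function(cand) {
    if (nrow(cand$terms) == 0) {
      return(NULL)
    }
    tibble::tibble(
      query_id = cand$query_id,
      method = cand$method,
      term_id = cand$terms$term_id,
      sources = paste0(ifelse(cand$terms$src_knn, "KNN", ""),
                       ifelse(cand$terms$src_knn & cand$terms$src_og, "+", ""),
                       ifelse(cand$terms$src_og, "OG", "")),
      knn_frequency = cand$terms$knn_frequency,
      og_frequency = cand$terms$og_frequency,
      best_support_identity = cand$terms$best_support_identity,
      voted_orthogroup = cand$voted_orthogroup)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- tibble::tibble(query_id = character(), method = character(),
                          term_id = character(), sources = character(),
                          knn_frequency = numeric(), og_frequency = numeric(),
                          best_support_identity = numeric(),
                          voted_orthogroup = character())
  }
  out
}
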