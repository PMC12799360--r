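#' Homology search configuration
#'
#' Defaults follow the filter set used for local homology searches in this
#' pipeline: amino-acid identity >= 50 %, query coverage >= 70 %,
#' e-value <= 1e-6, and k = 15 nearest homologs. Thresholds are inclusive.
#' `exclude_identical` drops hits whose subject sequence is exactly the
#' query string (the query itself, when it is present in the database) as
#' well as any hit with `subject_id == query_id`.
#'
#' @param min_identity_pct minimum percent identity, in \[0, 100\].
#' @param min_coverage_pct minimum percent query coverage, in \[0, 100\].
#' @param max_evalue maximum e-value (> 0).
#' @param k number of nearest homologs to keep (>= 1).
#' @param exclude_identical drop identical-sequence and self-id hits.
#' @return a `search_config` list.
#' @export
search_config <- function(min_identity_pct = 50, min_coverage_pct = 70,
                          max_evalue = 1e-6, k = 15, exclude_identical = TRUE) {
  stopifnot(min_identity_pct >= 0, min_identity_pct <= 100,
            min_coverage_pct >= 0, min_coverage_pct <= 100,
            max_evalue > 0, k >= 1)
  structure(list(min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct,
                 max_evalue = max_evalue,
                 k = as.integer(k),
                 exclude_identical = isTRUE(exclude_identical)),
            class = "search_config")
}

hit_columns <- c("query_id", "subject_id", "identity_pct", "query_coverage_pct",
                 "evalue", "bit_score", "rank")

empty_hits <- function() {
  tibble::tibble(query_id = character(), subject_id = character(),
                 identity_pct = numeric(), query_coverage_pct = numeric(),
                 evalue = numeric(), bit_score = numeric(), rank = integer())
}

# Total deterministic ranking: bit score desc, then e-value asc, then
# identity desc, then subject id in C-locale lexicographic order.
rank_hits <- function(hits) {
  if (nrow(hits) == 0) {
    hits$rank <- integer(0)
    return(hits)
  }
  ord <- order(hits$query_id, -hits$bit_score, hits$evalue, -hits$identity_pct,
               hits$subject_id, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  hits$rank <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                          FUN = seq_along)
  hits$rank <- as.integer(hits$rank)
  tibble::as_tibble(hits)
}

#' Parse blast6-style tabular search output
#'
#' Reads 12-column tabular hits (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), as written by
#' `usearch -usearch_local ... -blast6out` or `blastp -outfmt 6`. Query
#' coverage is computed from the aligned query span as
#' `100 * (qend - qstart + 1) / query_length`, so the query sequences (or
#' their lengths) must be supplied. Hits are grouped per query, sorted by
#' the package's ranking key and assigned ranks 1..n.
#'
#' @param path tabular hits file.
#' @param queries named character vector of query sequences, or a named
#'   numeric vector of query lengths.
#' @return tibble of hits with columns `query_id`, `subject_id`,
#'   `identity_pct`, `query_coverage_pct`, `evalue`, `bit_score`, `rank`.
#'   Hits for ids absent from `queries` are skipped with one warning.
#' @export
parse_tabular_hits <- function(path, queries) {
  qlen <- if (is.character(queries)) nchar(queries) else as.numeric(queries)
  names(qlen) <- names(queries)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_hits())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("'", path, "': expected 12 tab-separated columns at line ",
         which(nf != 12)[1], ", got ", nf[nf != 12][1])
  }
  m <- do.call(rbind, fields)
  qid <- m[, 1]
  known <- qid %in% names(qlen)
  if (any(!known)) {
    warning(sum(!known), " hit line(s) with unknown query id skipped")
  }
  m <- m[known, , drop = FALSE]
  if (nrow(m) == 0) {
    return(empty_hits())
  }
  qid <- m[, 1]
  hits <- tibble::tibble(
    query_id = qid,
    subject_id = m[, 2],
    identity_pct = as.numeric(m[, 3]),
    query_coverage_pct = 100 * (as.numeric(m[, 8]) - as.numeric(m[, 7]) + 1) /
      unname(qlen[qid]),
    evalue = as.numeric(m[, 11]),
    bit_score = as.numeric(m[, 12]))
  rank_hits(hits)
}

# Ungapped BLOSUM62 Karlin-Altschul constants, applied to gapped scores as a
# ranking/filtering approximation. m = query length, n = database residues.
ka_lambda <- 0.267
ka_K <- 0.041

ka_evalue <- function(score, m, n) ka_K * m * n * exp(-ka_lambda * score)
ka_bit_score <- function(score) (ka_lambda * score - log(ka_K)) / log(2)

#' Built-in Smith-Waterman homolog search
#'
#' Desk-scale local-alignment search used when no external tabular hits are
#' supplied: every query is aligned against every reference protein with
#' Smith-Waterman (BLOSUM62, affine gaps: a gap of length L costs 11 + L),
#' computed by a compiled Gotoh kernel. Per hit, `identity_pct` = matches /
#' alignment columns * 100, coverage = aligned query span / query length *
#' 100, and the e-value comes from the Karlin-Altschul formula
#' `E = K * m * n * exp(-lambda * S)` with ungapped BLOSUM62 constants
#' (lambda = 0.267, K = 0.041) applied to the gapped raw score; `n` is the
#' total residue count of the reference. Alignments with non-positive score
#' are discarded before filtering. Filtering and ranking follow
#' [filter_and_rank()].
#'
#' @param queries named character vector of query amino-acid sequences.
#' @param db a [reference_db()].
#' @param config a [search_config()].
#' @param filter apply [filter_and_rank()] (default) or return all
#'   positive-scoring hits ranked but unfiltered.
#' @return tibble of ranked hits (see [parse_tabular_hits()] for columns).
#' @export
builtin_search <- function(queries, db, config = search_config(), filter = TRUE) {
  stopifnot(inherits(db, "reference_db"))
  if (length(queries) == 0) {
    return(empty_hits())
  }
  if (is.null(names(queries)) || any(!nzchar(names(queries)))) {
    stop("queries must be a named character vector")
  }
  if (any(!nzchar(queries))) {
    stop("empty query sequence: ",
         paste(names(queries)[!nzchar(queries)], collapse = ", "))
  }
  ref_ids <- db$proteins$protein_id
  n_db <- sum(nchar(db$proteins$sequence))
  blosum <- get_blosum62()
  ref_enc <- lapply(db$proteins$sequence, encode_aa, blosum = blosum)

  per_query <- lapply(names(queries), function(qid) {
    qseq <- clean_aa(queries[[qid]])
    # when filtering, scores below the e-value ceiling's implied minimum
    # can never survive, so the kernel skips their traceback entirely
    smin <- if (filter) {
      max(1L, as.integer(ceiling(
        (log(ka_K * nchar(qseq) * n_db) - log(config$max_evalue)) / ka_lambda)))
    } else 1L
    aln <- .sw_batch(encode_aa(qseq, blosum), ref_enc, blosum, 11L, 1L, smin)
    keep <- aln[, "score"] >= smin
    if (!any(keep)) {
      return(NULL)
    }
    aln <- aln[keep, , drop = FALSE]
    tibble::tibble(
      query_id = qid,
      subject_id = ref_ids[keep],
      identity_pct = 100 * aln[, "matches"] / aln[, "columns"],
      query_coverage_pct = 100 * (aln[, "qend"] - aln[, "qstart"] + 1) /
        nchar(qseq),
      evalue = ka_evalue(aln[, "score"], nchar(qseq), n_db),
      bit_score = ka_bit_score(aln[, "score"]))
  })
  hits <- do.call(rbind, c(per_query, list(empty_hits())))
  hits <- rank_hits(hits)
  if (filter) {
    hits <- filter_and_rank(hits, config, db, queries)
  }
  hits
}

get_blosum62 <- function() {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  storage.mode(m) <- "integer"
  m
}

# 0-based indices into the substitution matrix; non-standard letters were
# already mapped to X by clean_aa()
encode_aa <- function(seq, blosum) {
  idx <- match(strsplit(clean_aa(seq), "", fixed = TRUE)[[1]],
               rownames(blosum)) - 1L
  idx
}

# Non-standard residues are mapped to X so composition features and the
# aligner (X scores the matrix minimum against everything) treat them
# uniformly.
clean_aa <- function(seq) {
  seq <- toupper(seq)
  gsub("[^ACDEFGHIKLMNPQRSTVWY]", "X", seq)
}

#' Filter and re-rank homology hits
#'
#' Keeps hits passing all of: `identity_pct >= min_identity_pct`,
#' `query_coverage_pct >= min_coverage_pct`, `evalue <= max_evalue`
#' (thresholds inclusive). With `exclude_identical`, hits whose subject
#' sequence string equals the query sequence string, and hits with
#' `subject_id == query_id`, are removed, so that a query present in the
#' database never appears among its own homologs. Survivors are re-sorted
#' and re-ranked 1..n per query.
#'
#' @param hits hit tibble (one or several queries).
#' @param config a [search_config()].
#' @param db the [reference_db()] (needed to compare subject sequences).
#' @param query_seqs named character vector of query sequences; required
#'   when `exclude_identical` is set.
#' @return filtered, re-ranked hit tibble.
#' @export
filter_and_rank <- function(hits, config, db, query_seqs = NULL) {
  if (nrow(hits) == 0) {
    return(empty_hits())
  }
  keep <- hits$identity_pct >= config$min_identity_pct &
    hits$query_coverage_pct >= config$min_coverage_pct &
    hits$evalue <= config$max_evalue
  hits <- hits[keep, , drop = FALSE]
  if (config$exclude_identical && nrow(hits) > 0) {
    hits <- hits[hits$subject_id != hits$query_id, , drop = FALSE]
    if (!is.null(query_seqs) && nrow(hits) > 0) {
      ref_seq <- stats::setNames(db$proteins$sequence, db$proteins$protein_id)
      subj <- ref_seq[hits$subject_id]
      qry <- query_seqs[hits$query_id]
      same <- !is.na(subj) & !is.na(qry) & subj == qry
      hits <- hits[!same, , drop = FALSE]
    }
  }
  rank_hits(hits)
}

#' Top-k hits of one query
#'
#' The first `min(k, n)` hits of an already filtered and ranked hit list.
#' Ties in the ranking key were already resolved deterministically by
#' [filter_and_rank()] (e-value ascending, identity descending, subject id
#' lexicographic within equal bit scores).
#'
#' @param hits ranked hit tibble for a single query.
#' @param k number of neighbors (>= 1).
#' @return the leading rows, ranks 1..min(k, n).
#' @export
top_k <- function(hits, k) {
  if (k < 1) {
    stop("k must be >= 1")
  }
  if (nrow(hits) == 0) {
    return(hits)
  }
  if (length(unique(hits$query_id)) > 1) {
    stop("top_k expects hits of a single query; use hits_by_query()")
  }
  hits[hits$rank <= k, , drop = FALSE]
}

#' Split a multi-query hit table into per-query tables
#'
#' @param hits ranked hit tibble.
#' @param query_ids queries to report (guarantees an entry, possibly empty,
#'   for each); defaults to the queries present in `hits`.
#' @return named list of per-query hit tibbles.
#' @export
hits_by_query <- function(hits, query_ids = NULL) {
  if (is.null(query_ids)) {
    query_ids <- unique(hits$query_id)
  }
  out <- lapply(query_ids, function(q) hits[hits$query_id == q, , drop = FALSE])
  names(out) <- query_ids
  out
}
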