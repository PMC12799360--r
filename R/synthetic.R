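#' Configuration for the synthetic orthology benchmark
#'
#' The generator emulates the statistical structure the annotation pipeline
#' relies on: families of related sequences that form nested orthogroups at
#' ordered taxonomic levels, coherent within-family GO annotation, and
#' controlled annotation noise. Each family descends from a random root
#' sequence along a star-shaped hierarchy: subgroup ancestors at level rank
#' l are copies of their parent mutated at rate
#' `root_mutation_rate * 2^(n_levels - 1 - l)` (so the most recent level
#' mutates at `root_mutation_rate` and each more ancient level doubles it),
#' and members mutate once more at `root_mutation_rate` from their finest
#' subgroup ancestor. Mutations are uniform substitutions; no indels.
#'
#' @param n_orthogroups number of families (rank-0 orthogroups).
#' @param members_per_group mean members per family.
#' @param member_jitter half-width of the uniform jitter on members (>= 0;
#'   realized size never drops below 2).
#' @param n_levels nested taxonomic levels (ranks 0 .. n_levels-1).
#' @param seq_length mean root sequence length.
#' @param length_jitter half-width of the uniform length jitter.
#' @param root_mutation_rate per-site substitution probability at the most
#'   recent level.
#' @param terms_per_group core GO terms shared by a family's members.
#' @param term_dropout probability a member lacks one of its family's core
#'   terms.
#' @param noise_terms_mean Poisson mean of spurious terms per protein, drawn
#'   from the global pool outside the family's core set.
#' @param query_divergence per-site substitution rate of a query from its
#'   source member.
#' @param n_queries queries to generate.
#' @param noise_pool_size size of the global spurious-term pool on top of
#'   the core terms.
#' @param seed integer; the full fixture is reproducible byte-for-byte
#'   from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_orthogroups = 20, members_per_group = 10,
                         member_jitter = 0, n_levels = 3, seq_length = 150,
                         length_jitter = 20, root_mutation_rate = 0.05,
                         terms_per_group = 5, term_dropout = 0.2,
                         noise_terms_mean = 1, query_divergence = 0.15,
                         n_queries = 2 * n_orthogroups,
                         noise_pool_size = 100, seed = 1) {
  stopifnot(n_orthogroups >= 1, members_per_group >= 2, n_levels >= 1,
            seq_length > length_jitter,
            root_mutation_rate >= 0, root_mutation_rate <= 1,
            term_dropout >= 0, term_dropout <= 1,
            noise_terms_mean >= 0,
            query_divergence >= 0, query_divergence <= 1)
  structure(as.list(environment()), class = "synth_config")
}

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) {
    return(seq)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(AA20, a), 1)
    }, character(1))
  }
  paste(chars, collapse = "")
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference database
#'
#' Builds the reference side of the benchmark: sequences, nested orthogroup
#' memberships at `n_levels` ranks (each finer level splits a family's
#' members into twice as many contiguous subgroups), and GO annotations
#' equal to the family's core terms minus dropout plus Poisson noise terms.
#' Core GO ids are synthesized as zero-padded `GO:` identifiers partitioned
#' round-robin into the three aspects, so per-aspect evaluation is
#' exercised.
#'
#' @param config a [synth_config()].
#' @return a `synth_fixture`: list with `db` (a [reference_db()]),
#'   `core_terms` (named list: family orthogroup id -> core GO ids),
#'   `member_family` (named character: protein id -> family orthogroup id),
#'   and `config`.
#' @export
generate_refdb <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_core <- config$n_orthogroups * config$terms_per_group
  n_terms <- n_core + config$noise_pool_size
  pool <- sprintf("GO:%07d", seq_len(n_terms))
  aspect_map <- stats::setNames(rep(c("BP", "MF", "CC"), length.out = n_terms),
                                pool)
  core_by_group <- split(pool[seq_len(n_core)],
                         rep(seq_len(config$n_orthogroups),
                             each = config$terms_per_group))

  proteins <- list()
  annotations <- list()
  memberships <- list()
  core_terms <- list()
  member_family <- character(0)
  counter <- 0L

  for (g in seq_len(config$n_orthogroups)) {
    family_og <- sprintf("OG%04d", g)
    core <- core_by_group[[g]]
    core_terms[[family_og]] <- core
    m <- config$members_per_group
    if (config$member_jitter > 0) {
      m <- max(2, m + sample(-config$member_jitter:config$member_jitter, 1))
    }
    len <- config$seq_length
    if (config$length_jitter > 0) {
      len <- len + sample(-config$length_jitter:config$length_jitter, 1)
    }
    root <- random_sequence(len)

    # subgroup ancestors per level: level l has 2^l contiguous subgroups
    node_seq <- list(root)           # level 0: one node
    sub_of_member <- list(rep(1L, m))
    for (l in seq_len(config$n_levels - 1)) {
      rate <- config$root_mutation_rate * 2^(config$n_levels - 1 - l)
      n_sub <- 2^l
      assign_sub <- as.integer(pmin(ceiling(seq_len(m) / (m / n_sub)), n_sub))
      parent_assign <- sub_of_member[[l]]
      parents <- vapply(seq_len(n_sub), function(s) {
        idx <- which(assign_sub == s)[1]
        if (is.na(idx)) 1L else parent_assign[idx]  # empty subgroup: unused
      }, integer(1))
      node_seq[[l + 1]] <- vapply(seq_len(n_sub), function(s) {
        mutate_sequence(node_seq[[l]][[parents[s]]], rate)
      }, character(1))
      sub_of_member[[l + 1]] <- assign_sub
    }

    noise_pool <- setdiff(pool, core)
    for (i in seq_len(m)) {
      counter <- counter + 1L
      pid <- sprintf("P%05d", counter)
      finest <- sub_of_member[[config$n_levels]][i]
      seq_i <- mutate_sequence(node_seq[[config$n_levels]][[finest]],
                               config$root_mutation_rate)
      proteins[[pid]] <- data.frame(
        protein_id = pid, species_id = sprintf("sp%02d", (i - 1) %% 10 + 1),
        sequence = seq_i, stringsAsFactors = FALSE)
      kept <- core[stats::runif(length(core)) >= config$term_dropout]
      n_noise <- stats::rpois(1, config$noise_terms_mean)
      noise <- if (n_noise > 0) sample(noise_pool, min(n_noise, length(noise_pool)))
               else character(0)
      annotations[[pid]] <- sort(unique(c(kept, noise)))
      member_family[[pid]] <- family_og
      mem_rows <- data.frame(
        protein_id = pid,
        orthogroup_id = c(family_og,
                          if (config$n_levels > 1) {
                            sprintf("%s.L%d.%d", family_og,
                                    seq_len(config$n_levels - 1),
                                    vapply(2:config$n_levels,
                                           function(l) sub_of_member[[l]][i],
                                           integer(1)))
                          }),
        level_rank = 0:(config$n_levels - 1), stringsAsFactors = FALSE)
      memberships[[pid]] <- mem_rows
    }
  }

  db <- reference_db(do.call(rbind, proteins), annotations,
                     do.call(rbind, memberships), aspect_map)
  structure(list(db = db, core_terms = core_terms,
                 member_family = member_family, config = config),
            class = "synth_fixture")
}

#' @export
print.synth_fixture <- function(x, ...) {
  cat("<synth_fixture> ", length(x$core_terms), " families, ",
      nrow(x$db$proteins), " reference proteins (seed ", x$config$seed,
      ")\n", sep = "")
  invisible(x)
}

#' Generate annotated queries from a synthetic fixture
#'
#' Each query is a mutated copy (at `query_divergence`) of a randomly
#' chosen reference member; its ground-truth annotation is the source
#' family's core term set (pre-noise, pre-dropout). Queries are not
#' inserted into the database.
#'
#' @param fixture a `synth_fixture` from [generate_refdb()].
#' @param n_queries number of queries (default: the config's).
#' @param seed RNG seed for query generation; defaults to the fixture seed
#'   offset by 1 so queries are independent of, but reproducible with, the
#'   reference draw.
#' @return list with `sequences` (named character), `truth` (named list:
#'   query id -> core GO ids) and `source_member` (named character).
#' @export
generate_queries <- function(fixture, n_queries = fixture$config$n_queries,
                             seed = fixture$config$seed + 1) {
  stopifnot(inherits(fixture, "synth_fixture"))
  set.seed(seed)
  members <- fixture$db$proteins$protein_id
  seqs <- stats::setNames(fixture$db$proteins$sequence, members)
  src <- sample(members, n_queries, replace = TRUE)
  qids <- sprintf("Q%04d", seq_len(n_queries))
  out_seq <- vapply(src, function(p) {
    mutate_sequence(seqs[[p]], fixture$config$query_divergence)
  }, character(1))
  names(out_seq) <- qids
  truth <- lapply(src, function(p) fixture$core_terms[[fixture$member_family[[p]]]])
  names(truth) <- qids
  list(sequences = out_seq, truth = truth,
       source_member = stats::setNames(src, qids))
}

#' Write a complete synthetic fixture directory
#'
#' Emits the reference files ([write_reference()]) plus `queries.fasta`,
#' `truth.tsv` (query_id, go_term) and `config.json`. Identical seeds
#' produce byte-identical files.
#'
#' @param fixture a `synth_fixture`.
#' @param queries output of [generate_queries()].
#' @param dir output directory.
#' @return invisibly, named vector of paths written.
#' @export
write_fixture <- function(fixture, queries, dir) {
  paths <- write_reference(fixture$db, dir)
  paths[["queries"]] <- file.path(dir, "queries.fasta")
  writeLines(as.vector(rbind(paste0(">", names(queries$sequences)),
                             unname(queries$sequences))), paths[["queries"]])
  paths[["truth"]] <- file.path(dir, "truth.tsv")
  truth_tab <- data.frame(
    query_id = rep(names(queries$truth), lengths(queries$truth)),
    go_term = unlist(queries$truth, use.names = FALSE))
  utils::write.table(truth_tab, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths[["config"]] <- file.path(dir, "config.json")
  cfg <- unclass(fixture$config)
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read a ground-truth / reference annotation TSV
#'
#' Two columns (query_id, go_term), headerless by default; returns the
#' named-list form used by the evaluation functions.
#'
#' @param path TSV path.
#' @param header skip one header line.
#' @return named list: query_id -> character vector of GO ids.
#' @export
read_annotation_list <- function(path, header = FALSE) {
  tab <- read_tsv_cols(path, c("query_id", "go_term"), header)
  lapply(split(tab$go_term, tab$query_id), function(x) sort(unique(x)))
}
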