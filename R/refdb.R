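#' Construct a reference database of annotated proteins and orthogroups
#'
#' A `reference_db` bundles the three pieces of information the annotation
#' pipeline draws on: protein sequences, their GO annotations, and their
#' orthogroup memberships at one or more taxonomic levels. Levels are
#' encoded by an integer `level_rank`, where rank 0 is the most ancient
#' (broadest) ancestral taxon and larger ranks are more recent levels.
#'
#' @param proteins data frame with columns `protein_id`, `species_id`,
#'   `sequence` (amino-acid strings; non-standard letters are tolerated and
#'   treated as 'X' where composition matters). `protein_id` must be unique
#'   and sequences non-empty.
#' @param annotations either a named list mapping `protein_id` to a character
#'   vector of GO term ids, or a data frame with columns
#'   (`protein_id`, `go_term`). Proteins absent here get an empty term set.
#' @param memberships data frame with columns `protein_id`, `orthogroup_id`,
#'   `level_rank` (integer >= 0). A protein may have at most one orthogroup
#'   per level; rows referencing unknown proteins are an error.
#' @param aspect_map optional named character vector mapping GO term ids to
#'   an aspect in `c("BP", "MF", "CC")`; terms missing from the map are
#'   reported under aspect `"unknown"` during evaluation.
#'
#' @return An object of class `reference_db` with elements `proteins`
#'   (tibble), `annotations` (named list of character vectors), `memberships`
#'   (tibble), `og_members` (named list: orthogroup id -> member protein ids,
#'   the exact inverse of `memberships`), and `aspect_map`.
#' @export
reference_db <- function(proteins, annotations = list(), memberships = NULL,
                         aspect_map = NULL) {
  proteins <- as.data.frame(proteins, stringsAsFactors = FALSE)
  need <- c("protein_id", "species_id", "sequence")
  if (!all(need %in% names(proteins))) {
    stop("`proteins` must have columns: ", paste(need, collapse = ", "))
  }
  ids <- as.character(proteins$protein_id)
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!nzchar(proteins$sequence))) {
    stop("empty sequence for protein: ",
         paste(ids[!nzchar(proteins$sequence)], collapse = ", "))
  }

  ann <- empty_annotation_list(ids)
  if (is.data.frame(annotations)) {
    if (nrow(annotations) > 0) {
      if (!all(c("protein_id", "go_term") %in% names(annotations))) {
        stop("annotation table must have columns (protein_id, go_term)")
      }
      unknown <- setdiff(unique(annotations$protein_id), ids)
      if (length(unknown) > 0) {
        warning(length(unknown), " annotation row(s) reference unknown proteins; dropped")
        annotations <- annotations[annotations$protein_id %in% ids, , drop = FALSE]
      }
      by_prot <- split(as.character(annotations$go_term),
                       as.character(annotations$protein_id))
      for (p in names(by_prot)) ann[[p]] <- sort(unique(by_prot[[p]]))
    }
  } else if (length(annotations) > 0) {
    unknown <- setdiff(names(annotations), ids)
    if (length(unknown) > 0) {
      stop("annotations given for unknown proteins: ",
           paste(unknown, collapse = ", "))
    }
    for (p in names(annotations)) {
      ann[[p]] <- sort(unique(as.character(annotations[[p]])))
    }
  }

  if (is.null(memberships)) {
    memberships <- data.frame(protein_id = character(), orthogroup_id = character(),
                              level_rank = integer(), stringsAsFactors = FALSE)
  }
  memberships <- as.data.frame(memberships, stringsAsFactors = FALSE)
  if (nrow(memberships) > 0) {
    if (!all(c("protein_id", "orthogroup_id", "level_rank") %in% names(memberships))) {
      stop("membership table must have columns (protein_id, orthogroup_id, level_rank)")
    }
    memberships$protein_id <- as.character(memberships$protein_id)
    memberships$orthogroup_id <- as.character(memberships$orthogroup_id)
    memberships$level_rank <- as.integer(memberships$level_rank)
    if (any(is.na(memberships$level_rank)) || any(memberships$level_rank < 0)) {
      stop("level_rank must be a non-negative integer")
    }
    unknown <- setdiff(unique(memberships$protein_id), ids)
    if (length(unknown) > 0) {
      stop("membership rows reference unknown proteins: ",
           paste(unknown, collapse = ", "))
    }
    key <- paste(memberships$protein_id, memberships$level_rank)
    if (anyDuplicated(key)) {
      stop("a protein may have at most one orthogroup per level; duplicates: ",
           paste(unique(key[duplicated(key)]), collapse = "; "))
    }
  }

  if (!is.null(aspect_map)) {
    aspect_map <- validate_aspect_map(aspect_map)
  }

  structure(list(
    proteins = tibble::as_tibble(proteins[, need]),
    annotations = ann,
    memberships = tibble::as_tibble(memberships),
    og_members = split(memberships$protein_id, memberships$orthogroup_id),
    aspect_map = aspect_map
  ), class = "reference_db")
}

empty_annotation_list <- function(ids) {
  ann <- rep(list(character(0)), length(ids))
  names(ann) <- ids
  ann
}

validate_aspect_map <- function(aspect_map) {
  aspect_map <- vapply(aspect_map, as.character, character(1))
  bad <- !aspect_map %in% c("BP", "MF", "CC")
  if (any(bad)) {
    stop("aspects must be BP, MF or CC; offending terms: ",
         paste(names(aspect_map)[bad], collapse = ", "))
  }
  aspect_map
}

#' @export
print.reference_db <- function(x, ...) {
  n_ann <- sum(lengths(x$annotations) > 0)
  cat("<reference_db> ", nrow(x$proteins), " proteins (", n_ann, " annotated), ",
      length(x$og_members), " orthogroups across ",
      length(unique(x$memberships$level_rank)), " level(s)\n", sep = "")
  invisible(x)
}

#' Load a reference database from FASTA + TSV dumps
#'
#' Reads the on-disk layout used throughout this package: a protein FASTA,
#' a two-column annotation TSV (`protein_id`, `go_term`), a three-column
#' membership TSV (`protein_id`, `orthogroup_id`, `level_rank`), and an
#' optional aspect map (two-column TSV `term_id`, `aspect`, or an OBO 1.2
#' file from which `id`/`namespace`/`alt_id` fields are taken). TSVs are
#' headerless by default.
#'
#' @param fasta_path protein FASTA; record ids up to the first whitespace are
#'   the `protein_id`s, and a `species=<id>` token in the description, if
#'   present, sets `species_id` (otherwise `"unknown"`).
#' @param annotations_path TSV of (protein_id, go_term); may be empty.
#' @param memberships_path TSV of (protein_id, orthogroup_id, level_rank).
#' @param aspect_path optional aspect TSV or OBO file.
#' @param header logical; skip one header line in the TSVs.
#' @return a [reference_db()].
#' @export
load_reference <- function(fasta_path, annotations_path, memberships_path,
                           aspect_path = NULL, header = FALSE) {
  seqs <- read_fasta_named(fasta_path)
  desc <- attr(seqs, "descriptions")
  species <- sub(".*species=([^ ]+).*", "\\1", desc)
  species[!grepl("species=", desc)] <- "unknown"
  proteins <- data.frame(protein_id = names(seqs), species_id = species,
                         sequence = as.vector(unname(seqs)),
                         stringsAsFactors = FALSE)

  ann <- read_tsv_cols(annotations_path, c("protein_id", "go_term"), header)
  mem <- read_tsv_cols(memberships_path,
                       c("protein_id", "orthogroup_id", "level_rank"), header)
  aspect_map <- if (!is.null(aspect_path)) read_aspect_map(aspect_path, header) else NULL
  reference_db(proteins, ann, mem, aspect_map)
}

read_fasta_named <- function(path) {
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- as.character(set)
  names(out) <- ids
  attr(out, "descriptions") <- full
  out
}

read_tsv_cols <- function(path, cols, header = FALSE) {
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = header, quote = "",
                      comment.char = "", colClasses = "character",
                      col.names = if (header) NULL else cols),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(NULL)
      }
      stop("cannot parse '", path, "': ", conditionMessage(e))
    })
  if (is.null(raw) || nrow(raw) == 0) {
    raw <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  if (ncol(raw) != length(cols)) {
    stop("'", path, "': expected ", length(cols), " tab-separated columns, got ",
         ncol(raw))
  }
  names(raw) <- cols
  raw
}

#' Read a GO-aspect map from a two-column TSV or an OBO 1.2 file
#'
#' OBO parsing is deliberately shallow: only `id:`, `alt_id:` and
#' `namespace:` fields of `[Term]` stanzas are used (the pipeline never
#' traverses the ontology graph). Namespaces are mapped to BP / MF / CC.
#'
#' @param path TSV of (term_id, aspect) or an OBO file (detected by an
#'   `.obo` extension or a `format-version:` first line).
#' @param header skip one header line (TSV only).
#' @return named character vector: term id -> "BP" / "MF" / "CC".
#' @export
read_aspect_map <- function(path, header = FALSE) {
  first <- readLines(path, n = 1L)
  is_obo <- grepl("\\.obo$", path, ignore.case = TRUE) ||
    (length(first) == 1L && grepl("^format-version:", first))
  if (is_obo) {
    return(parse_obo_aspects(path))
  }
  tab <- read_tsv_cols(path, c("term_id", "aspect"), header)
  validate_aspect_map(stats::setNames(tab$aspect, tab$term_id))
}

parse_obo_aspects <- function(path) {
  lines <- readLines(path)
  ns_map <- c(biological_process = "BP", molecular_function = "MF",
              cellular_component = "CC")
  out <- character(0)
  ids <- character(0)
  ns <- NA_character_
  in_term <- FALSE
  flush <- function() {
    if (in_term && length(ids) > 0 && !is.na(ns) && ns %in% names(ns_map)) {
      out[ids] <<- ns_map[[ns]]
    }
  }
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      in_term <- identical(ln, "[Term]")
      ids <- character(0)
      ns <- NA_character_
    } else if (in_term) {
      if (grepl("^id: ", ln)) ids <- c(ids, sub("^id: *", "", ln))
      if (grepl("^alt_id: ", ln)) ids <- c(ids, sub("^alt_id: *", "", ln))
      if (grepl("^namespace: ", ln)) ns <- sub("^namespace: *", "", ln)
    }
  }
  flush()
  out
}

#' Orthogroup at the most ancient ancestral taxon
#'
#' Among a protein's orthogroup memberships, returns the one at the
#' broadest (evolutionarily oldest) taxonomic level, i.e. the membership
#' with minimal `level_rank`.
#'
#' @param db a [reference_db()].
#' @param protein_id a protein present in `db`.
#' @return the orthogroup id (character scalar), or `NA_character_` if the
#'   protein has no memberships.
#' @export
most_ancient_orthogroup <- function(db, protein_id) {
  stopifnot(inherits(db, "reference_db"))
  if (!protein_id %in% db$proteins$protein_id) {
    stop("unknown protein_id: ", protein_id)
  }
  m <- db$memberships[db$memberships$protein_id == protein_id, , drop = FALSE]
  if (nrow(m) == 0) {
    return(NA_character_)
  }
  m$orthogroup_id[which.min(m$level_rank)]
}

#' Pooled GO terms of an orthogroup
#'
#' The union of the GO annotations of every member protein, deduplicated.
#'
#' @param db a [reference_db()].
#' @param orthogroup_id an orthogroup present in `db`.
#' @return sorted character vector of GO term ids (possibly empty).
#' @export
orthogroup_term_pool <- function(db, orthogroup_id) {
  stopifnot(inherits(db, "reference_db"))
  members <- db$og_members[[orthogroup_id]]
  if (is.null(members)) {
    stop("unknown orthogroup_id: ", orthogroup_id)
  }
  sort(unique(unlist(db$annotations[members], use.names = FALSE)))
}

#' Per-term annotation frequency within an orthogroup
#'
#' For each term in the orthogroup's pooled term set, the fraction of member
#' proteins annotated with it (denominator = all members, annotated or not).
#'
#' @inheritParams orthogroup_term_pool
#' @return named numeric vector in (0, 1], named by term id.
#' @export
orthogroup_term_frequencies <- function(db, orthogroup_id) {
  stopifnot(inherits(db, "reference_db"))
  members <- db$og_members[[orthogroup_id]]
  if (is.null(members)) {
    stop("unknown orthogroup_id: ", orthogroup_id)
  }
  terms <- unlist(db$annotations[members], use.names = FALSE)
  if (length(terms) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  tab <- table(terms)
  freqs <- as.numeric(tab) / length(members)
  stats::setNames(freqs, names(tab))[sort(names(tab))]
}

#' Background frequency of GO terms in the reference
#'
#' Fraction of annotated reference proteins (those with at least one GO
#' term) carrying each term. Used as a verification feature.
#'
#' @param db a [reference_db()].
#' @param term_ids character vector of GO ids.
#' @return numeric vector aligned with `term_ids` (0 for unseen terms).
#' @export
term_background_frequency <- function(db, term_ids) {
  stopifnot(inherits(db, "reference_db"))
  annotated <- db$annotations[lengths(db$annotations) > 0]
  n <- length(annotated)
  if (n == 0) {
    return(rep(0, length(term_ids)))
  }
  counts <- table(unlist(annotated, use.names = FALSE))
  out <- as.numeric(counts[term_ids]) / n
  out[is.na(out)] <- 0
  out
}

#' Write a reference database to the package's on-disk layout
#'
#' Inverse of [load_reference()]: emits `proteins.fasta`, `annotations.tsv`,
#' `memberships.tsv` and, if present, `aspects.tsv` under `dir`.
#'
#' @param db a [reference_db()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named character vector of the paths written.
#' @export
write_reference <- function(db, dir) {
  stopifnot(inherits(db, "reference_db"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "proteins.fasta"),
             annotations = file.path(dir, "annotations.tsv"),
             memberships = file.path(dir, "memberships.tsv"))
  headers <- paste0(">", db$proteins$protein_id, " species=", db$proteins$species_id)
  writeLines(as.vector(rbind(headers, db$proteins$sequence)), paths[["fasta"]])
  ann <- db$annotations[lengths(db$annotations) > 0]
  ann_tab <- data.frame(
    protein_id = rep(names(ann), lengths(ann)),
    go_term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  utils::write.table(ann_tab, paths[["annotations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(db$memberships), paths[["memberships"]],
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(db$aspect_map)) {
    paths[["aspects"]] <- file.path(dir, "aspects.tsv")
    utils::write.table(
      data.frame(term_id = names(db$aspect_map), aspect = unname(db$aspect_map)),
      paths[["aspects"]], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  invisible(paths)
}
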