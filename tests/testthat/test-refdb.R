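test_that("construction validates invariants and fills empty annotation sets", {
  db <- tiny_db()
  expect_s3_class(db, "reference_db")
  # P6 appears in no annotation row -> empty set, not missing
  expect_identical(db$annotations$P6, character(0))
  expect_setequal(names(db$annotations), db$proteins$protein_id)

  proteins <- data.frame(protein_id = c("A", "A"), species_id = "s",
                         sequence = "MK", stringsAsFactors = FALSE)
  expect_error(reference_db(proteins), "duplicate protein_id")

  p <- data.frame(protein_id = "A", species_id = "s", sequence = "MK")
  expect_error(reference_db(p, memberships = data.frame(
    protein_id = "B", orthogroup_id = "g", level_rank = 0)), "unknown proteins")
  expect_error(reference_db(p, memberships = data.frame(
    protein_id = c("A", "A"), orthogroup_id = c("g", "h"),
    level_rank = c(1, 1))), "one orthogroup per level")
})

test_that("og_members is the exact inverse of memberships", {
  db <- tiny_db()
  for (g in names(db$og_members)) {
    for (p in db$og_members[[g]]) {
      expect_true(any(db$memberships$protein_id == p &
                        db$memberships$orthogroup_id == g))
    }
  }
  for (i in seq_len(nrow(db$memberships))) {
    expect_true(db$memberships$protein_id[i] %in%
                  db$og_members[[db$memberships$orthogroup_id[i]]])
  }
})

test_that("most_ancient_orthogroup picks the minimal level rank", {
  db <- tiny_db()
  # P5 has ranks {0: OGb, 1: OGb.1}
  expect_identical(most_ancient_orthogroup(db, "P5"), "OGb")
  expect_identical(most_ancient_orthogroup(db, "P1"), "OGa")
  expect_true(is.na(most_ancient_orthogroup(db, "P6")))
  expect_error(most_ancient_orthogroup(db, "nope"), "unknown protein_id")
})

test_that("most_ancient_orthogroup equals a brute-force scan on a random DB and
          is invariant under membership permutation", {
  fx <- shared_fixture()$fx
  db <- fx$db
  set.seed(5)
  perm <- sample(nrow(db$memberships))
  db_perm <- reference_db(as.data.frame(db$proteins),
                          db$annotations, as.data.frame(db$memberships)[perm, ])
  for (p in sample(db$proteins$protein_id, min(50, nrow(db$proteins)))) {
    mem <- db$memberships[db$memberships$protein_id == p, ]
    expected <- if (nrow(mem) == 0) NA_character_ else {
      mem$orthogroup_id[which(mem$level_rank == min(mem$level_rank))]
    }
    expect_identical(most_ancient_orthogroup(db, p), expected)
    expect_identical(most_ancient_orthogroup(db_perm, p), expected)
  }
})

test_that("orthogroup_term_pool is the member-annotation union", {
  db <- tiny_db()
  expect_setequal(orthogroup_term_pool(db, "OGa"),
                  c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_error(orthogroup_term_pool(db, "nope"), "unknown orthogroup_id")

  # unannotated-only orthogroup
  p <- data.frame(protein_id = c("A", "B"), species_id = "s",
                  sequence = c("MK", "ML"))
  m <- data.frame(protein_id = c("A", "B"), orthogroup_id = "g", level_rank = 0)
  expect_identical(orthogroup_term_pool(reference_db(p, memberships = m), "g"),
                   character(0))

  # random DB: equals a naive double loop; pool always covers each member
  rdb <- shared_fixture()$fx$db
  for (g in sample(names(rdb$og_members), 20)) {
    naive <- character(0)
    for (p in rdb$og_members[[g]]) {
      for (term in rdb$annotations[[p]]) {
        if (!term %in% naive) naive <- c(naive, term)
      }
    }
    pool <- orthogroup_term_pool(rdb, g)
    expect_setequal(pool, naive)
    for (p in rdb$og_members[[g]]) {
      expect_true(all(rdb$annotations[[p]] %in% pool))
    }
  }
})

test_that("orthogroup term frequencies use all members as denominator", {
  db <- tiny_db()
  f <- orthogroup_term_frequencies(db, "OGb")  # P4 {10,11}, P5 {10}
  expect_equal(unname(f["GO:0000010"]), 1)
  expect_equal(unname(f["GO:0000011"]), 0.5)
})

test_that("term_background_frequency counts annotated proteins only", {
  db <- tiny_db()  # 5 annotated of 6
  expect_equal(term_background_frequency(db, "GO:0000001"), 2 / 5)
  expect_equal(term_background_frequency(db, "GO:0000099"), 0)
  # oracle on the random db
  rdb <- shared_fixture()$fx$db
  annotated <- rdb$annotations[lengths(rdb$annotations) > 0]
  terms <- sample(unique(unlist(rdb$annotations)), 10)
  manual <- sapply(terms, function(t) {
    mean(vapply(annotated, function(a) t %in% a, logical(1)))
  })
  expect_equal(term_background_frequency(rdb, terms), unname(manual))
})

test_that("load_reference round-trips a written fixture and rejects bad input", {
  dir <- withr::local_tempdir()
  fx <- shared_fixture()$fx
  paths <- write_reference(fx$db, dir)
  db2 <- load_reference(paths[["fasta"]], paths[["annotations"]],
                        paths[["memberships"]], paths[["aspects"]])
  expect_equal(db2$proteins, fx$db$proteins)
  expect_equal(db2$annotations, fx$db$annotations)
  expect_equal(as.data.frame(db2$memberships)[order(db2$memberships$protein_id,
                                                    db2$memberships$level_rank), ],
               as.data.frame(fx$db$memberships)[order(fx$db$memberships$protein_id,
                                                      fx$db$memberships$level_rank), ],
               ignore_attr = TRUE)
  expect_equal(db2$aspect_map[names(fx$db$aspect_map)], fx$db$aspect_map)

  # empty annotations file -> all-empty term sets
  empty <- file.path(dir, "empty.tsv")
  file.create(empty)
  db3 <- load_reference(paths[["fasta"]], empty, paths[["memberships"]])
  expect_true(all(lengths(db3$annotations) == 0))

  bad <- file.path(dir, "bad.fasta")
  writeLines(c(">x", "MK", ">x", "ML"), bad)
  expect_error(load_reference(bad, empty, paths[["memberships"]]), "duplicate")
})

test_that("OBO aspect parsing reads id, alt_id and namespace only", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2",
    "", "[Term]", "id: GO:0000001", "name: something",
    "namespace: biological_process", "alt_id: GO:0099999",
    "", "[Term]", "id: GO:0000002", "namespace: molecular_function",
    "", "[Typedef]", "id: part_of"), obo)
  m <- read_aspect_map(obo)
  expect_identical(unname(m["GO:0000001"]), "BP")
  expect_identical(unname(m["GO:0099999"]), "BP")
  expect_identical(unname(m["GO:0000002"]), "MF")
  expect_false("part_of" %in% names(m))
})
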