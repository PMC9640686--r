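test_that("spec validation names the offending field", {
  expect_error(pangenome_spec(n_genomes = 1), "n_genomes")
  expect_error(pangenome_spec(within_group_identity = 0), "within_group_identity")
  expect_error(pangenome_spec(within_group_identity = 1.2), "within_group_identity")
  expect_error(pangenome_spec(n_core_groups = -1), "n_core_groups")
  expect_error(pangenome_spec(paralog_rate = 1), "paralog_rate")
  expect_error(pangenome_spec(protein_length_range = c(50, 10)),
               "protein_length_range")
  expect_error(pangenome_spec(accessory = data.frame(prevalence = 1.5,
                                                     n_groups = 1)),
               "accessory")
})

test_that("identity-1 core-only spec gives exact copies in every genome", {
  sp <- pangenome_spec(n_genomes = 3, n_core_groups = 5,
                       n_unique_per_genome = 0, within_group_identity = 1,
                       seed = 3)
  pg <- generate_pangenome(sp)
  expect_equal(nrow(pg$proteins), 15)
  expect_equal(nrow(pg$truth), 5)
  expect_true(all(pg$truth$prevalence == 3))
  # identical sequences within each group
  for (g in unique(pg$proteins$group_id)) {
    expect_length(unique(pg$proteins$sequence[pg$proteins$group_id == g]), 1)
  }
})

test_that("same spec and seed give byte-identical outputs", {
  sp <- pangenome_spec(n_genomes = 3, n_core_groups = 4,
                       n_unique_per_genome = 2, seed = 7,
                       protein_length_range = c(50L, 80L))
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  write_pangenome(generate_pangenome(sp), d1)
  write_pangenome(generate_pangenome(sp), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("mutate_sequence honours its substitution contract", {
  expect_identical(mutate_sequence("ACDEFGHIKL", 1.0), "ACDEFGHIKL")
  set.seed(1)
  m <- mutate_sequence("ACDEFGHIKL", 0.8)
  diffs <- sum(strsplit(m, "")[[1]] != strsplit("ACDEFGHIKL", "")[[1]])
  expect_equal(diffs, 2)
  expect_equal(nchar(m), 10)
  expect_error(mutate_sequence("", 0.9), "non-empty")
  expect_error(mutate_sequence("ACDE", 0), "target_identity")
})

test_that("mutated sequences hit the target identity under the DP oracle", {
  set.seed(42)
  parent <- paste(sample(amino_acids(), 100, TRUE), collapse = "")
  child <- mutate_sequence(parent, 0.5)
  al <- sw_oracle(parent, child)
  # substitution-only: oracle identity equals the planted 50% within slack
  # for local-alignment trimming
  expect_gt(al$percent_identity, 48)
  expect_lt(al$percent_identity, 60)
})

test_that("pairwise identity of group members matches within_group_identity", {
  pg <- small_protein_set(n_groups = 4, size = 3, n_unique = 0,
                          identity = 0.9, len_range = c(80, 120), seed = 5)
  ids <- split(seq_len(nrow(pg$proteins)), pg$proteins$group_id)
  pids <- c()
  for (members in ids) {
    for (i in seq_along(members)[-length(members)]) {
      for (j in (i + 1):length(members)) {
        al <- sw_oracle(pg$proteins$sequence[members[i]],
                        pg$proteins$sequence[members[j]])
        pids <- c(pids, al$percent_identity)
      }
    }
  }
  expect_gt(mean(pids) / 100, 0.85)
  expect_lt(mean(pids) / 100, 0.95)
})

test_that("planted truth prevalence matches a recomputation from the table", {
  sp <- pangenome_spec(n_genomes = 5, n_core_groups = 3,
                       accessory = data.frame(prevalence = 0.5, n_groups = 2),
                       n_unique_per_genome = 2, seed = 9,
                       protein_length_range = c(50L, 60L))
  pg <- generate_pangenome(sp)
  recomputed <- tapply(pg$proteins$genome_id, pg$proteins$group_id,
                       function(g) length(unique(g)))
  expect_equal(as.integer(recomputed[pg$truth$group_id]),
               pg$truth$prevalence)
  # every protein appears exactly once
  expect_false(anyDuplicated(pg$proteins$protein_id) > 0)
})

test_that("paralogs are planted at the requested rate", {
  sp <- pangenome_spec(n_genomes = 4, n_core_groups = 30,
                       n_unique_per_genome = 0, paralog_rate = 0.5,
                       protein_length_range = c(50L, 60L), seed = 2)
  pg <- generate_pangenome(sp)
  cn <- table(pg$proteins$group_id, pg$proteins$genome_id)
  expect_gt(mean(cn == 2), 0.3)  # ~half the genome-group cells duplicated
  expect_lt(mean(cn == 2), 0.7)
})

test_that("generate_annotations labels every member and validates groups", {
  pg <- small_protein_set(n_groups = 2, size = 3, n_unique = 0,
                          identity = 1, seed = 1)
  gid <- pg$truth$group_id[1]
  ann <- generate_annotations(pg, data.frame(group_id = gid,
                                             label_type = "domain",
                                             label = "PF03777"))
  members <- pg$proteins$protein_id[pg$proteins$group_id == gid]
  expect_setequal(ann$domain$protein_id, members)
  expect_true(all(ann$domain$accession == "PF03777"))
  # empty profile -> header-only tables
  empty <- generate_annotations(pg, data.frame(group_id = character(0),
                                               label_type = character(0),
                                               label = character(0)))
  expect_true(all(vapply(empty, nrow, integer(1)) == 0))
  expect_error(generate_annotations(pg, data.frame(group_id = "nope",
                                                   label_type = "COG",
                                                   label = "K")),
               "unknown group_id")
})

test_that("KO annotations can straddle the relaxed-rule boundary", {
  pg <- small_protein_set(n_groups = 2, size = 2, n_unique = 0,
                          identity = 1, seed = 4)
  prof <- data.frame(group_id = pg$truth$group_id,
                     label_type = "KO", label = c("K00001", "K00002"),
                     score = c(50, 200), threshold = c(100, 100),
                     evalue = c(1e-90, 1e-12))
  ann <- generate_annotations(pg, prof)
  koa <- assign_ko(ann$ko, relaxed = TRUE)
  expect_setequal(unique(koa$mode), c("standard", "relaxed"))
})
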