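test_that("self alignment gives full identity and coverage", {
  al <- local_align("PELICAN", "PELICAN")
  expect_equal(al$percent_identity, 100)
  expect_equal(al$query_coverage, 1)
  expect_equal(al$subject_coverage, 1)
})

test_that("all-mismatch pair has no positive local alignment", {
  expect_null(local_align("AAAA", "WWWW"))
})

test_that("invalid residues are rejected with their position", {
  expect_error(local_align("PELICAN", "COELACANTH"), "position 2")
  expect_error(local_align("ACdE", "ACDE"), "invalid residue")
})

test_that("local_align matches the independent DP oracle", {
  # the score is unique; identity/coverage are compared on pairs whose
  # optimal alignment is unambiguous (co-optimal tracebacks may differ)
  score_only <- list(c("HEAGAWGHEE", "PAWHEAE"))   # two co-optimal alignments
  full <- list(
    c("PELICAN", "CELACANTH"),
    c("MKLVAAAAGTWDER", "MKLVGTWDER"),       # forces a gap
    c("MSTNPKPQRKTKRNTNRRPQDVKFPGG", "MSTNPKPQRKTKRNTNRRPQDVKFPGG"))
  for (cs in c(full, score_only)) {
    got <- local_align(cs[1], cs[2])
    want <- sw_oracle(cs[1], cs[2])
    expect_equal(got$score, want$score, label = paste(cs, collapse = "/"))
  }
  for (cs in full) {
    got <- local_align(cs[1], cs[2])
    want <- sw_oracle(cs[1], cs[2])
    expect_equal(got$percent_identity, want$percent_identity, tolerance = 1e-9)
    expect_equal(got$alignment_length, want$alignment_length)
    expect_equal(got$query_coverage, want$query_coverage)
    expect_equal(got$subject_coverage, want$subject_coverage)
  }
  set.seed(8)
  for (i in 1:10) {
    a <- paste(sample(amino_acids(), 60, TRUE), collapse = "")
    b <- mutate_sequence(a, 0.85)
    got <- local_align(a, b)
    want <- sw_oracle(a, b)
    expect_equal(got$score, want$score)
  }
})

test_that("hit boundary semantics: >= for identity/coverage, < for E-value", {
  crit <- orthologue_criteria()
  hit <- function(pid, cq, cs, ev)
    data.frame(query_id = "a", subject_id = "b", percent_identity = pid,
               alignment_length = 100L, query_coverage = cq,
               subject_coverage = cs, evalue = ev, bitscore = 100)
  expect_true(hit_passes(hit(85, 0.9, 0.8, 1e-20), crit))
  expect_true(hit_passes(hit(80.0, 0.70, 0.70, 9.9e-6), crit))
  expect_false(hit_passes(hit(85, 0.9, 0.69, 1e-20), crit))  # both sides
  expect_false(hit_passes(hit(79.999, 0.9, 0.9, 1e-20), crit))
  expect_false(hit_passes(hit(85, 0.69, 0.9, 1e-20), crit))
  expect_false(hit_passes(hit(85, 0.9, 0.9, 1e-5), crit))    # E strict
  expect_true(hit_passes(hit(85, 0.9, 0.9, 0.99e-5), crit))
})

test_that("tightening any criterion never adds a qualifying pair", {
  pg <- small_protein_set(n_groups = 4, size = 3, n_unique = 5,
                          identity = 0.85, seed = 10)
  hits <- all_vs_all(pg)
  base <- sum(hit_passes(hits, orthologue_criteria()))
  for (crit in list(orthologue_criteria(min_identity = 90),
                    orthologue_criteria(min_coverage_both = 0.9),
                    orthologue_criteria(max_evalue = 1e-30))) {
    expect_lte(sum(hit_passes(hits, crit)), base)
  }
})

test_that("two identical proteins produce exactly two directed hits", {
  prot <- data.frame(
    protein_id = c("gA_p1", "gB_p1"), genome_id = c("gA", "gB"),
    sequence = rep(paste(rep("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ", 4),
                         collapse = ""), 2))
  hits <- all_vs_all(prot)
  expect_equal(nrow(hits), 2)
  expect_setequal(hits$query_id, c("gA_p1", "gB_p1"))
  expect_true(all(hits$percent_identity == 100))
  expect_true(all(hits$query_coverage == 1))
})

test_that("planted 90%-identity pairs are reported near 90% identity", {
  set.seed(21)
  parent <- paste(sample(amino_acids(), 150, TRUE), collapse = "")
  prot <- data.frame(protein_id = c("a", "b"), genome_id = c("g1", "g2"),
                     sequence = c(parent, mutate_sequence(parent, 0.9)))
  hits <- all_vs_all(prot, prefilter = FALSE)
  expect_equal(nrow(hits), 2)
  expect_gt(hits$percent_identity[1], 88)
  expect_lt(hits$percent_identity[1], 92)
})

test_that("prefiltered all-vs-all equals the exhaustive DP oracle", {
  # 50 proteins: 10 planted triplets at 90% identity + 20 unrelated
  pg <- small_protein_set(n_groups = 10, size = 3, n_unique = 20,
                          identity = 0.9, len_range = c(60, 90), seed = 12)
  prot <- pg$proteins
  expect_lte(nrow(prot), 52)
  crit <- orthologue_criteria(max_evalue = Inf)  # oracle has no E-value model
  hits <- all_vs_all(prot, prefilter = TRUE)
  got <- hits[hit_passes(hits, crit), ]
  got_pairs <- sort(unique(paste(pmin(got$query_id, got$subject_id),
                                 pmax(got$query_id, got$subject_id))))
  want_pairs <- oracle_qualifying_pairs(prot)
  expect_identical(got_pairs, want_pairs)
})

test_that("prefilter on and off give identical qualifying pairs", {
  pg <- small_protein_set(n_groups = 8, size = 3, n_unique = 15,
                          identity = 0.88, len_range = c(60, 100), seed = 13)
  crit <- orthologue_criteria()
  key <- function(h) {
    q <- h[hit_passes(h, crit), ]
    sort(unique(paste(q$query_id, q$subject_id)))
  }
  expect_identical(key(all_vs_all(pg$proteins, prefilter = TRUE)),
                   key(all_vs_all(pg$proteins, prefilter = FALSE)))
})

test_that("BLAST tabular ingestion computes coverage and skips self hits", {
  rows <- c(
    "q1\ts1\t85.0\t70\t10\t0\t1\t70\t5\t74\t1e-30\t120\t100\t90",
    "q1\tq1\t100\t100\t0\t0\t1\t100\t1\t100\t0.0\t200\t100\t100",
    "q2\ts2\t92.5\t50\t4\t0\t11\t60\t1\t50\t1e-10\t80\t120\t50")
  f <- tempfile(fileext = ".tsv")
  writeLines(rows, f)
  hits <- read_blast_tab(f)
  expect_equal(nrow(hits), 2)
  expect_equal(attr(hits, "skipped_self"), 1)
  expect_equal(hits$query_coverage[1], 0.70)
  expect_equal(hits$subject_coverage[1], 70 / 90)
  expect_equal(hits$evalue[1], 1e-30)
  # malformed row reports its line number
  writeLines(c(rows[1], "q3\ts3\tbroken"), f)
  expect_error(read_blast_tab(f), "line 2")
  # 12-column dialect cannot express dual coverage
  expect_error(read_blast_tab(f, dialect = "std12"), "qlen/slen")
  unlink(f)
})
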