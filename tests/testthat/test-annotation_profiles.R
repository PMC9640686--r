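# pangenome with known conservation structure for profile tests:
# 10 genomes; grp1 prevalence 10 (core), grp2 prevalence 5, grp3 prevalence 1
profile_fixture <- function() {
  df <- truth_table(10, prevalences = c(10, 5, 1))
  pg <- pangenome_from_truth(df)
  # map planted groups to recovered ids via any member protein
  member <- function(i) df$protein_id[df$group_id == sprintf("grp%03d", i)]
  list(pg = pg, df = df, member = member)
}

test_that("loading applies per-type thresholds and accounts for every row", {
  dom <- data.frame(protein_id = c("p1", "p2", "p2"),
                    accession = c("PF00001", "PF00002", "PF00002"),
                    name = "x", ievalue = c(0.5, 1e-12, 1e-12),
                    start = 1, end = 50)
  cog <- data.frame(protein_id = c("p1", "p2"), category = c("K", "T"),
                    evalue = c(1e-12, 1e-5))
  ann <- load_annotations(domain = dom, cog = cog)
  # Pfam row at E = 0.5 fails the 1e-1 threshold; duplicate deduplicated
  expect_equal(nrow(ann$domain), 1)
  expect_equal(ann$domain$protein_id, "p2")
  # raw table keeps the failing row for rules with their own thresholds
  expect_equal(nrow(ann$domain_raw), 2)
  # EggNOG row at 1e-12 kept, 1e-5 dropped (threshold 1e-10)
  expect_equal(ann$cog$protein_id, "p1")
  # kept + dropped = input for every table
  lg <- ann$log
  expect_true(all(lg$kept + lg$dropped_duplicate + lg$dropped_threshold ==
                  lg$input))
})

test_that("category profile recovers planted bin composition exactly", {
  fx <- profile_fixture()
  cz <- data.frame(protein_id = c(fx$member(1), fx$member(2)),
                   family = "GH5")
  ann <- load_annotations(cazy = cz)
  prof <- category_profile(fx$pg, ann, "CAZy_family")
  expect_equal(sum(prof$n_proteins), 15)   # 10 + 5 members annotated
  top <- prof[prof$bin == 20, ]
  mid <- prof[prof$bin == 10, ]
  expect_equal(top$n_proteins, 10)
  expect_equal(mid$n_proteins, 5)          # 5/10 = 50% -> bin (0.45, 0.5]
  # within-label percentages sum to 100 (up to rounding)
  expect_equal(sum(prof$pct), 100, tolerance = 0.2)
  # independent tally oracle
  frac <- fx$pg$groups$fraction[match(
    fx$pg$membership$group_id[match(cz$protein_id,
                                    fx$pg$membership$protein_id)],
    fx$pg$groups$group_id)]
  oracle_bins <- table(ceiling(frac / 0.05 - 1e-9))
  for (b in names(oracle_bins)) {
    expect_equal(prof$n_proteins[prof$bin == as.integer(b)],
                 as.integer(oracle_bins[[b]]))
  }
})

test_that("multi-letter COG strings split into one contribution per letter", {
  fx <- profile_fixture()
  cg <- data.frame(protein_id = fx$member(1)[1], category = "KT",
                   evalue = 1e-20)
  ann <- load_annotations(cog = cg)
  split_prof <- category_profile(fx$pg, ann, "COG_category")
  expect_setequal(split_prof$label, c("K", "T"))
  first_prof <- category_profile(fx$pg, ann, "COG_category",
                                 cog_mode = "first")
  expect_equal(first_prof$label, "K")
})

test_that("KEGG rollup uses the supplied mapping and exclusion list", {
  fx <- profile_fixture()
  ko <- data.frame(protein_id = c(fx$member(1)[1], fx$member(1)[2]),
                   ko = c("K00001", "K00002"), score = 300, threshold = 100,
                   evalue = 1e-50)
  ann <- load_annotations(ko = ko)
  map <- data.frame(ko = c("K00001", "K00002"),
                    category = c("metabolism", "secondary_metabolites"))
  prof <- category_profile(fx$pg, ann, "KEGG_category", ko_map = map,
                           kegg_exclude = "secondary_metabolites")
  expect_equal(unique(prof$label), "metabolism")
  expect_error(category_profile(fx$pg, ann, "KEGG_category"), "ko_map")
})

test_that("CAZyme class statistics use the population-SD convention", {
  fx <- profile_fixture()
  # plant GH counts 1/2/3 in three genomes via singleton-ish assignments
  pids <- fx$pg$membership$protein_id
  gmap <- fx$pg$membership$genome_id
  pick <- function(g, n) pids[gmap == g][seq_len(n)]
  # g001 holds 3 proteins (grp1+grp2+grp3), g002 holds 2, g003 holds 2
  cz <- data.frame(protein_id = c(pick("g003", 1), pick("g002", 2),
                                  pick("g001", 3)),
                   family = "GH13")
  ann <- load_annotations(cazy = cz)
  st <- class_count_stats(ann, fx$pg)$stats
  gh <- st[st$class == "GH", ]
  counts <- c(1, 2, 3, rep(0, 7))   # 10 genomes, 7 with zero GH
  expect_equal(gh$mean, mean(counts))
  expect_equal(gh$sd, sqrt(mean((counts - mean(counts))^2)))
  expect_equal(gh$cv, gh$sd / gh$mean)
  # absent class: undefined CV
  expect_true(is.na(st$cv[st$class == "PL"]))
})

test_that("identical per-genome counts give a zero CV", {
  fx <- profile_fixture()
  cz <- data.frame(protein_id = fx$member(1), family = "PL1")
  ann <- load_annotations(cazy = cz)
  st <- class_count_stats(ann, fx$pg)$stats
  expect_equal(st$cv[st$class == "PL"], 0)
})

test_that("BGC core-enzyme profile isolates core enzymes by type", {
  fx <- profile_fixture()
  bgc <- rbind(
    data.frame(protein_id = fx$member(1), bgc_type = "ectoine-like",
               core_enzyme = 1),
    data.frame(protein_id = fx$member(3), bgc_type = "butyrolactone-like",
               core_enzyme = 1),
    data.frame(protein_id = fx$member(2), bgc_type = "butyrolactone-like",
               core_enzyme = 0))          # not a core enzyme: excluded
  ann <- load_annotations(bgc = bgc)
  prof <- bgc_core_enzyme_profile(fx$pg, ann)
  ect <- prof[prof$label == "ectoine-like", ]
  but <- prof[prof$label == "butyrolactone-like", ]
  expect_equal(ect$bin, 20)
  expect_equal(ect$pct, 100)
  # strain-specific type: all members in a prevalence-1 group (1/10 -> bin 2)
  expect_equal(but$bin, conservation_bin_oracle(1 / 10))
  expect_equal(but$pct, 100)
  # empty BGC table -> empty profile
  ann0 <- load_annotations(bgc = bgc[bgc$core_enzyme > 1, ])
  expect_equal(nrow(bgc_core_enzyme_profile(fx$pg, ann0)), 0)
})
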