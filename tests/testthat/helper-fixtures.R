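# Shared fixture builders. Fixtures are constructed in code; nothing is read
# from disk except through the package's own writers.

# a pangenome object built from a planted membership table, bypassing the
# aligner: members of a group are chained with perfect qualifying hits
pangenome_from_truth <- function(df) {
  stopifnot(all(c("protein_id", "genome_id", "group_id") %in% names(df)))
  edges <- do.call(rbind, lapply(split(df$protein_id, df$group_id),
                                 function(p) {
    p <- sort(p)
    if (length(p) < 2) return(NULL)
    data.frame(query_id = p[-length(p)], subject_id = p[-1])
  }))
  hits <- if (is.null(edges)) {
    data.frame(query_id = character(0), subject_id = character(0),
               percent_identity = numeric(0), alignment_length = integer(0),
               query_coverage = numeric(0), subject_coverage = numeric(0),
               evalue = numeric(0), bitscore = numeric(0))
  } else {
    data.frame(edges, percent_identity = 100, alignment_length = 100L,
               query_coverage = 1, subject_coverage = 1, evalue = 1e-50,
               bitscore = 200)
  }
  g <- build_graph(hits, df$protein_id, orthologue_criteria())
  extract_groups(g, df[, c("protein_id", "genome_id")])
}

# membership table with groups at given prevalences over n genomes;
# copies = per-genome copy number of each group
truth_table <- function(n_genomes, prevalences, copies = 1) {
  genomes <- sprintf("g%03d", seq_len(n_genomes))
  rows <- list()
  pid <- 0
  for (i in seq_along(prevalences)) {
    member_genomes <- genomes[seq_len(prevalences[i])]
    for (g in member_genomes) {
      for (cp in seq_len(copies)) {
        pid <- pid + 1
        rows[[pid]] <- data.frame(protein_id = sprintf("p%05d", pid),
                                  genome_id = g,
                                  group_id = sprintf("grp%03d", i))
      }
    }
  }
  do.call(rbind, rows)
}

# small divergent protein set: n_groups planted groups of `size` members at
# `identity`, plus n_unique unrelated proteins; lengths drawn in len_range
small_protein_set <- function(n_groups = 5, size = 3, n_unique = 10,
                              identity = 0.9, len_range = c(60, 100),
                              seed = 1) {
  sp <- pangenome_spec(
    n_genomes = max(size, 2), n_core_groups = n_groups,
    n_unique_per_genome = ceiling(n_unique / max(size, 2)),
    within_group_identity = identity,
    protein_length_range = as.integer(len_range), seed = seed)
  generate_pangenome(sp)
}

# block-structured binary presence-absence matrix: k row blocks with
# disjoint column support plus sprinkled within-block noise
planted_block_matrix <- function(n_strains = 40, n_blocks = 2, n_cols = 30,
                                 flip_rate = 0.05, seed = 1) {
  set.seed(seed)
  block <- rep(seq_len(n_blocks), length.out = n_strains)
  block <- sort(block)
  m <- matrix(0L, n_strains, n_blocks * n_cols,
              dimnames = list(sprintf("s%03d", seq_len(n_strains)), NULL))
  for (b in seq_len(n_blocks)) {
    cols <- (b - 1) * n_cols + seq_len(n_cols)
    m[block == b, cols] <- 1L
  }
  flips <- which(stats::runif(length(m)) < flip_rate)
  m[flips] <- 1L - m[flips]
  attr(m, "block") <- block
  m
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# canonical form of a partition: cluster ids renumbered by first appearance,
# so two labelings describe the same partition iff their forms are identical
partition_form <- function(labels) match(labels, unique(labels))
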