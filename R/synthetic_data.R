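#' Specification for a synthetic pangenome
#'
#' Describes the planted structure of a simulated bacterial pangenome:
#' how many genomes, how many core orthologous groups (present in every
#' genome), accessory groups at controlled prevalence, strain-specific
#' singletons, and how divergent the members of a group are from each other.
#'
#' `within_group_identity` is the target *pairwise* sequence identity between
#' two members of the same group: every member is derived from a common
#' ancestor sequence by substituting `(1 - identity)/2` of its positions, so
#' that two siblings differ at roughly `1 - identity` of their positions.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_core_groups number of groups planted in every genome.
#' @param accessory `NULL`, or a data frame with columns `prevalence`
#'   (fraction of genomes in (0, 1) carrying the group) and `n_groups`
#'   (how many groups at that prevalence).
#' @param n_unique_per_genome number of strain-specific proteins planted per
#'   genome; each is an independent random sequence with no orthologues.
#' @param within_group_identity target pairwise identity of group members,
#'   in (0, 1].
#' @param paralog_rate probability that a group member is duplicated within
#'   its genome (a paralogue), in \[0, 1).
#' @param protein_length_range integer `c(min, max)` residue lengths.
#' @param seed integer seed; identical spec + seed gives byte-identical output.
#' @return an object of class `pangenome_spec`.
#' @examples
#' sp <- pangenome_spec(n_genomes = 3, n_core_groups = 5,
#'                      n_unique_per_genome = 0, within_group_identity = 1)
#' @export
pangenome_spec <- function(n_genomes = 20, n_core_groups = 100,
                           accessory = NULL, n_unique_per_genome = 10,
                           within_group_identity = 0.9, paralog_rate = 0,
                           protein_length_range = c(100L, 300L), seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
      stop_config("field '", nm, "' must be a single non-negative integer")
  }
  chk_count(n_genomes, "n_genomes")
  if (n_genomes < 2) stop_config("field 'n_genomes' must be >= 2")
  chk_count(n_core_groups, "n_core_groups")
  chk_count(n_unique_per_genome, "n_unique_per_genome")
  if (!is.numeric(within_group_identity) ||
      within_group_identity <= 0 || within_group_identity > 1)
    stop_config("field 'within_group_identity' must be in (0, 1]")
  if (!is.numeric(paralog_rate) || paralog_rate < 0 || paralog_rate >= 1)
    stop_config("field 'paralog_rate' must be in [0, 1)")
  if (length(protein_length_range) != 2L ||
      any(protein_length_range < 1) ||
      protein_length_range[1] > protein_length_range[2])
    stop_config("field 'protein_length_range' must be c(min, max) with 1 <= min <= max")
  if (!is.null(accessory)) {
    if (!is.data.frame(accessory) ||
        !all(c("prevalence", "n_groups") %in% names(accessory)))
      stop_config("field 'accessory' must be a data frame with columns prevalence, n_groups")
    if (any(accessory$prevalence <= 0) || any(accessory$prevalence >= 1))
      stop_config("field 'accessory' prevalence values must be in (0, 1)")
    if (any(accessory$n_groups < 0))
      stop_config("field 'accessory' n_groups values must be >= 0")
  }
  chk_count(abs(seed), "seed")
  structure(list(n_genomes = as.integer(n_genomes),
                 n_core_groups = as.integer(n_core_groups),
                 accessory = accessory,
                 n_unique_per_genome = as.integer(n_unique_per_genome),
                 within_group_identity = within_group_identity,
                 paralog_rate = paralog_rate,
                 protein_length_range = as.integer(protein_length_range),
                 seed = as.integer(seed)),
            class = "pangenome_spec")
}

random_protein <- function(len) {
  paste(sample(amino_acids(), len, replace = TRUE), collapse = "")
}

#' Mutate a protein sequence to a target identity
#'
#' Substitutes `round((1 - target_identity) * nchar(parent))` distinct
#' positions of `parent` with residues different from the original, so the
#' result differs from the parent at exactly that many positions and keeps
#' its length. Draws from R's global random number stream.
#'
#' @param parent amino-acid string (non-empty).
#' @param target_identity fraction in (0, 1].
#' @return mutated amino-acid string.
#' @examples
#' set.seed(1)
#' mutate_sequence("ACDEFGHIKL", 0.8)  # differs at exactly 2 positions
#' @export
mutate_sequence <- function(parent, target_identity) {
  if (!is.character(parent) || length(parent) != 1L || nchar(parent) == 0L)
    stop("'parent' must be a single non-empty amino-acid string")
  if (target_identity <= 0 || target_identity > 1)
    stop("'target_identity' must be in (0, 1]")
  len <- nchar(parent)
  k <- round((1 - target_identity) * len)
  if (k == 0L) return(parent)
  res <- strsplit(parent, "", fixed = TRUE)[[1L]]
  pos <- sample.int(len, k)
  aa <- amino_acids()
  for (p in pos) {
    res[p] <- sample(setdiff(aa, res[p]), 1L)
  }
  paste(res, collapse = "")
}

#' Generate a synthetic pangenome with planted ground truth
#'
#' Materialises every planted orthologous group as one random ancestor
#' sequence plus per-genome mutated copies, adds independent strain-specific
#' proteins, and optionally duplicates members within a genome as paralogues.
#' Because unrelated proteins are drawn i.i.d. uniform over the 20 residues,
#' two unrelated sequences of length >= 100 essentially never reach the 80%
#' identity / 70% coverage orthologue criteria, so planted groups are
#' separable by construction.
#'
#' @param spec a [pangenome_spec()].
#' @return an object of class `synthetic_pangenome`: a list with
#'   \describe{
#'     \item{proteins}{data frame `protein_id`, `genome_id`, `group_id`,
#'       `sequence` — one row per generated protein (`group_id` is the planted
#'       truth).}
#'     \item{truth}{data frame `group_id`, `prevalence`, `n_members`.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_pangenome <- function(spec) {
  if (!inherits(spec, "pangenome_spec")) stop("'spec' must be a pangenome_spec")
  set.seed(spec$seed)
  genomes <- sprintf("G%02d", seq_len(spec$n_genomes))
  copy_identity <- 1 - (1 - spec$within_group_identity) / 2

  group_sizes <- integer(0)   # genomes per planted group
  if (spec$n_core_groups > 0)
    group_sizes <- rep(spec$n_genomes, spec$n_core_groups)
  if (!is.null(spec$accessory)) {
    for (i in seq_len(nrow(spec$accessory))) {
      npg <- max(2L, round(spec$accessory$prevalence[i] * spec$n_genomes))
      group_sizes <- c(group_sizes, rep(npg, spec$accessory$n_groups[i]))
    }
  }

  rows <- vector("list", length(group_sizes) + spec$n_genomes)
  for (g in seq_along(group_sizes)) {
    gid <- sprintf("PG%04d", g)
    len <- sample(seq(spec$protein_length_range[1],
                      spec$protein_length_range[2]), 1L)
    ancestor <- random_protein(len)
    members <- if (group_sizes[g] == spec$n_genomes) genomes
               else sort(sample(genomes, group_sizes[g]))
    seqs <- vapply(members, function(gn) mutate_sequence(ancestor, copy_identity),
                   character(1))
    df <- data.frame(genome_id = members, group_id = gid, sequence = unname(seqs),
                     stringsAsFactors = FALSE)
    if (spec$paralog_rate > 0) {
      dup <- members[stats::runif(length(members)) < spec$paralog_rate]
      if (length(dup) > 0) {
        df <- rbind(df, data.frame(
          genome_id = dup, group_id = gid,
          sequence = vapply(dup, function(gn)
            mutate_sequence(ancestor, copy_identity), character(1)),
          stringsAsFactors = FALSE))
      }
    }
    rows[[g]] <- df
  }
  # strain-specific proteins: independent sequences, singleton groups
  uq <- 0L
  for (i in seq_along(genomes)) {
    if (spec$n_unique_per_genome == 0) break
    lens <- sample(seq(spec$protein_length_range[1],
                       spec$protein_length_range[2]),
                   spec$n_unique_per_genome, replace = TRUE)
    gids <- sprintf("UQ%04d", uq + seq_len(spec$n_unique_per_genome))
    uq <- uq + spec$n_unique_per_genome
    rows[[length(group_sizes) + i]] <- data.frame(
      genome_id = genomes[i], group_id = gids,
      sequence = vapply(lens, random_protein, character(1)),
      stringsAsFactors = FALSE)
  }
  proteins <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  proteins <- proteins[order(proteins$genome_id, proteins$group_id), ,
                       drop = FALSE]
  # per-genome sequential protein ids
  idx <- stats::ave(seq_len(nrow(proteins)), proteins$genome_id,
                    FUN = seq_along)
  proteins$protein_id <- sprintf("%s_P%04d", proteins$genome_id, idx)
  proteins <- proteins[order(proteins$protein_id),
                       c("protein_id", "genome_id", "group_id", "sequence")]
  rownames(proteins) <- NULL

  prev <- tapply(proteins$genome_id, proteins$group_id,
                 function(g) length(unique(g)))
  truth <- data.frame(group_id = names(prev),
                      prevalence = as.integer(prev),
                      n_members = as.integer(table(proteins$group_id)[names(prev)]),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$group_id), ]
  rownames(truth) <- NULL
  structure(list(proteins = proteins, truth = truth, spec = spec),
            class = "synthetic_pangenome")
}

#' @export
print.synthetic_pangenome <- function(x, ...) {
  cat("Synthetic pangenome:", length(unique(x$proteins$genome_id)),
      "genomes,", nrow(x$proteins), "proteins,",
      nrow(x$truth), "planted groups\n")
  invisible(x)
}

# sample an E-value with log10 uniform over [lo, hi] exponents
sample_evalue <- function(n, lo, hi) 10^stats::runif(n, lo, hi)

#' Generate synthetic annotation tables for a planted pangenome
#'
#' Emits functional-annotation tables in the dialects the loaders consume
#' (`domain`, `cog`, `ko`, `cazy`, `bgc`), labelling every member protein of
#' each profiled group. Where a profile row does not pin an E-value or score,
#' values are sampled on both sides of the downstream filter thresholds so
#' that filtering code paths are exercised.
#'
#' @param pg a `synthetic_pangenome`.
#' @param profile data frame with columns `group_id`, `label_type` (one of
#'   `"domain"`, `"COG"`, `"KO"`, `"CAZy"`, `"BGC"`), `label`, and optional
#'   `evalue`, `score`, `threshold` (KO-specific score threshold),
#'   `core_enzyme` (BGC rows), `start`, `end` (domain rows).
#' @return named list of data frames: `domain`, `cog`, `ko`, `cazy`, `bgc`.
#' @export
generate_annotations <- function(pg, profile) {
  stopifnot(inherits(pg, "synthetic_pangenome"))
  need <- c("group_id", "label_type", "label")
  if (!is.data.frame(profile) || !all(need %in% names(profile)))
    stop("'profile' needs columns group_id, label_type, label")
  unknown <- setdiff(unique(profile$group_id), pg$proteins$group_id)
  if (length(unknown) > 0)
    stop("unknown group_id in profile: ", paste(unknown, collapse = ", "))

  domain <- data.frame(protein_id = character(0), accession = character(0),
                       name = character(0), ievalue = numeric(0),
                       start = numeric(0), end = numeric(0))
  cog <- data.frame(protein_id = character(0), category = character(0),
                    evalue = numeric(0))
  ko <- data.frame(protein_id = character(0), ko = character(0),
                   score = numeric(0), threshold = numeric(0),
                   evalue = numeric(0))
  cazy <- data.frame(protein_id = character(0), family = character(0))
  bgc <- data.frame(protein_id = character(0), bgc_type = character(0),
                    core_enzyme = numeric(0))

  opt <- function(row, col, default) {
    v <- if (col %in% names(profile)) row[[col]] else NA
    if (is.null(v) || is.na(v)) default else v
  }
  for (i in seq_len(nrow(profile))) {
    row <- profile[i, ]
    pids <- pg$proteins$protein_id[pg$proteins$group_id == row$group_id]
    n <- length(pids)
    switch(as.character(row$label_type),
      domain = {
        ev <- opt(row, "evalue", sample_evalue(n, -15, 0.5))
        st <- opt(row, "start", 1)
        en <- opt(row, "end", 60)
        domain <- rbind(domain, data.frame(
          protein_id = pids, accession = row$label, name = row$label,
          ievalue = rep_len(ev, n), start = rep_len(st, n),
          end = rep_len(en, n)))
      },
      COG = {
        ev <- opt(row, "evalue", sample_evalue(n, -20, -5))
        cog <- rbind(cog, data.frame(protein_id = pids,
                                      category = row$label,
                                      evalue = rep_len(ev, n)))
      },
      KO = {
        sc <- opt(row, "score", stats::runif(n, 50, 500))
        th <- opt(row, "threshold", 100)
        ev <- opt(row, "evalue", sample_evalue(n, -120, -40))
        ko <- rbind(ko, data.frame(protein_id = pids, ko = row$label,
                                    score = rep_len(sc, n),
                                    threshold = rep_len(th, n),
                                    evalue = rep_len(ev, n)))
      },
      CAZy = {
        cazy <- rbind(cazy, data.frame(protein_id = pids,
                                        family = row$label))
      },
      BGC = {
        ce <- opt(row, "core_enzyme", 1)
        bgc <- rbind(bgc, data.frame(protein_id = pids,
                                      bgc_type = row$label,
                                      core_enzyme = rep_len(ce, n)))
      },
      stop("unknown label_type: ", row$label_type)
    )
  }
  lapply(list(domain = domain, cog = cog, ko = ko, cazy = cazy, bgc = bgc),
         function(d) { rownames(d) <- NULL; d })
}

#' Write a synthetic pangenome to disk
#'
#' Writes one protein FASTA per genome (headers `genome|protein`), the planted
#' truth as TSV (`protein_id`, `genome_id`, `group_id`) and a JSON run
#' manifest recording the spec and seed.
#'
#' @param pg a `synthetic_pangenome`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome <- function(pg, dir) {
  stopifnot(inherits(pg, "synthetic_pangenome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (gn in sort(unique(pg$proteins$genome_id))) {
    sub <- pg$proteins[pg$proteins$genome_id == gn, ]
    ss <- Biostrings::AAStringSet(sub$sequence)
    names(ss) <- paste0(gn, "|", sub$protein_id)
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(gn, ".faa")))
  }
  write_tsv(pg$proteins[, c("protein_id", "genome_id", "group_id")],
            file.path(dir, "truth.tsv"))
  sp <- pg$spec
  manifest <- list(
    n_genomes = sp$n_genomes, n_core_groups = sp$n_core_groups,
    accessory = sp$accessory, n_unique_per_genome = sp$n_unique_per_genome,
    within_group_identity = sp$within_group_identity,
    paralog_rate = sp$paralog_rate,
    protein_length_range = sp$protein_length_range, seed = sp$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write annotation tables to disk as TSV
#'
#' @param ann list as returned by [generate_annotations()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotations <- function(ann, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(ann)) write_tsv(ann[[nm]], file.path(dir, paste0(nm, ".tsv")))
  invisible(dir)
}
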