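#' Read one protein FASTA proteome
#'
#' Headers may be `genome|protein`; otherwise the genome id is taken from
#' `genome_id` or inferred from the file name. Sequences are upper-cased.
#' Duplicate protein ids and empty sequences are errors.
#'
#' @param path FASTA file.
#' @param genome_id genome id override when headers carry none.
#' @return data frame `protein_id`, `genome_id`, `sequence`.
#' @export
read_fasta_proteome <- function(path, genome_id = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  has_bar <- grepl("|", hdr, fixed = TRUE)
  gid <- ifelse(has_bar, sub("\\|.*$", "", hdr),
                genome_id %||% sub("\\.[^.]*$", "", basename(path)))
  pid <- ifelse(has_bar, sub("^[^|]*\\|", "", hdr), hdr)
  dups <- pid[duplicated(pid)]
  if (length(dups) > 0)
    stop(path, ": duplicate protein id(s): ",
         paste(unique(dups), collapse = ", "))
  seqs <- toupper(as.character(ss))
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0)
    stop(path, ": empty sequence for id ", pid[empty[1L]])
  data.frame(protein_id = pid, genome_id = gid, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Read a directory of proteome FASTA files
#'
#' @param dir directory containing `.faa`/`.fa`/`.fasta` files.
#' @return combined data frame `protein_id`, `genome_id`, `sequence`.
#' @export
read_proteomes <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(faa|fa|fasta)$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no FASTA files in ", dir)
  out <- do.call(rbind, lapply(files, read_fasta_proteome))
  dups <- out$protein_id[duplicated(out$protein_id)]
  if (length(dups) > 0)
    stop("duplicate protein id(s) across proteomes: ",
         paste(unique(dups), collapse = ", "))
  out
}

#' Pipeline configuration
#'
#' Collects and validates every input path and tunable of the end-to-end
#' pangenome pipeline. All thresholds default to the values the analysis is
#' built around: orthologue criteria 80% identity / 70% dual coverage /
#' E < 1e-5; Pfam 1e-1 and COG 1e-10 loading thresholds; KO 1e-10 with the
#' adaptive score threshold plus the 1e-80 relaxed rule; CAZyme family band
#' \[0.05, 0.55\] at 70% membership with a 5% column floor.
#'
#' @param fasta_dir directory of per-genome protein FASTA files.
#' @param out_dir output directory.
#' @param hits `"compute"` (all-vs-all with the built-in aligner) or a path
#'   to a 14-column BLAST tabular file.
#' @param annotations named list of annotation TSV paths or data frames
#'   (`domain`, `cog`, `ko`, `cazy`, `bgc`), or `NULL`.
#' @param tf_rules transcription-factor rule TSV (`NULL` = the example
#'   catalogue shipped with the package).
#' @param pathway_definitions list of [pathway_definition()]s (default:
#'   beta-ketoadipate branches).
#' @param criteria an [orthologue_criteria()].
#' @param n_permutations accumulation-curve permutations.
#' @param seed master seed for all stochastic stages.
#' @param embed_method embedding for the CAZyme landscape.
#' @return validated config object (class `pipeline_config`).
#' @export
pipeline_config <- function(fasta_dir, out_dir, hits = "compute",
                            annotations = NULL, tf_rules = NULL,
                            pathway_definitions = beta_ketoadipate_definitions(),
                            criteria = orthologue_criteria(),
                            n_permutations = 100, seed = 1,
                            embed_method = "mds") {
  if (!dir.exists(fasta_dir)) stop_config("fasta_dir does not exist: ", fasta_dir)
  if (!identical(hits, "compute") && !file.exists(hits))
    stop_config("hits file does not exist: ", hits)
  if (!is.null(annotations)) {
    for (nm in names(annotations)) {
      a <- annotations[[nm]]
      if (is.character(a) && !file.exists(a))
        stop_config("annotation path does not exist: ", a)
    }
  }
  if (is.null(tf_rules))
    tf_rules <- system.file("extdata", "tf_rules.tsv", package = "streptopan")
  if (!file.exists(tf_rules)) stop_config("tf_rules does not exist: ", tf_rules)
  structure(list(fasta_dir = fasta_dir, out_dir = out_dir, hits = hits,
                 annotations = annotations, tf_rules = tf_rules,
                 pathway_definitions = pathway_definitions,
                 criteria = criteria, n_permutations = n_permutations,
                 seed = seed, embed_method = embed_method),
            class = "pipeline_config")
}

#' Run the full pangenome pipeline
#'
#' Stage order: load proteomes; similarity hits (computed or ingested);
#' orthologue graph and groups; conservation statistics (accumulation
#' curves, conservation histogram, per-genome profile, rare-vs-size
#' correlation); annotation conservation profiles; domain classifiers (sigma
#' factors, transcription factors, chaplins, PPTases); pathway completeness;
#' CAZyme landscape. Stages whose inputs are absent are skipped with a
#' notice. Every stage writes a TSV artefact into `out_dir` plus a row-count
#' log entry; a frozen copy of the resolved configuration and a
#' machine-readable JSON report are always written. Identical config + seed
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  note <- function(stage, n) {
    log[[length(log) + 1L]] <<- data.frame(stage = stage, rows = n)
    message("[", stage, "] ", n, " rows")
  }
  cfg_json <- list(fasta_dir = config$fasta_dir, hits = config$hits,
                   criteria = unclass(config$criteria),
                   n_permutations = config$n_permutations, seed = config$seed,
                   embed_method = config$embed_method)
  jsonlite::write_json(cfg_json, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  proteins <- read_proteomes(config$fasta_dir)
  note("load_proteomes", nrow(proteins))

  hits <- if (identical(config$hits, "compute")) all_vs_all(proteins)
          else read_blast_tab(config$hits)
  write_tsv(hits, file.path(config$out_dir, "hits.tsv"))
  note("similarity", nrow(hits))

  g <- build_graph(hits, proteins$protein_id, config$criteria)
  pg <- extract_groups(g, proteins[, c("protein_id", "genome_id")])
  cons <- classify_conservation(pg)
  write_tsv(merge(pg$groups, cons[, c("group_id", "strict_core", "core",
                                      "rare", "strain_specific", "singleton",
                                      "single_copy_core", "category")],
                  by = "group_id"),
            file.path(config$out_dir, "groups.tsv"))
  write_tsv(pg$membership, file.path(config$out_dir, "membership.tsv"))
  note("ortholog_clustering", nrow(pg$groups))

  curves <- accumulation_curves(pg, config$n_permutations, seed = config$seed)
  write_tsv(as.data.frame(curves), file.path(config$out_dir, "accumulation.tsv"))
  hist <- conservation_histogram(pg)
  write_tsv(hist, file.path(config$out_dir, "conservation_histogram.tsv"))
  prof <- per_genome_profile(pg)
  write_tsv(prof, file.path(config$out_dir, "per_genome_profile.tsv"))
  corr <- if (nrow(prof) >= 3 && stats::sd(prof$rare) > 0 &&
              stats::sd(prof$total) > 0)
    unique_vs_size_correlation(prof) else NULL
  note("pangenome_stats", nrow(curves))

  ann <- NULL; profiles <- list(); classifiers <- list(); pathways <- NULL
  landscape <- NULL
  if (!is.null(config$annotations)) {
    ann <- do.call(load_annotations, config$annotations)
    for (lt in c("COG_category", "CAZy_family", "CAZy_class")) {
      ok <- tryCatch({
        profiles[[lt]] <- category_profile(pg, ann, lt); TRUE
      }, error = function(e) FALSE)
      if (ok) write_tsv(as.data.frame(profiles[[lt]]),
                        file.path(config$out_dir,
                                  paste0("profile_", lt, ".tsv")))
    }
    if (!is.null(ann$bgc)) {
      profiles$BGC_type <- bgc_core_enzyme_profile(pg, ann)
      write_tsv(as.data.frame(profiles$BGC_type),
                file.path(config$out_dir, "profile_BGC_core_enzymes.tsv"))
    }
    note("annotation_profiles", length(profiles))

    if (!is.null(ann$domain)) {
      sig <- classify_sigma(ann$domain)
      rules <- read_tf_rules(config$tf_rules)
      tf <- classify_tf(ann$domain, rules, exclude = sig$protein_id)
      chap <- identify_chaplins(ann$domain)
      ppt <- identify_pptases(ann$domain_raw)
      classifiers <- list(sigma = sig, tf = tf, chaplins = chap,
                          pptases = ppt)
      write_tsv(sig, file.path(config$out_dir, "sigma_factors.tsv"))
      write_tsv(tf, file.path(config$out_dir, "transcription_factors.tsv"))
      write_tsv(data.frame(protein_id = chap),
                file.path(config$out_dir, "chaplins.tsv"))
      write_tsv(ppt, file.path(config$out_dir, "pptases.tsv"))
      note("feature_classifiers",
           nrow(sig) + nrow(tf) + length(chap) + nrow(ppt))
    } else message("[feature_classifiers] skipped: no domain table")

    if (!is.null(ann$ko)) {
      koa <- assign_ko(ann$ko, relaxed = TRUE)
      gmap <- pg$membership$genome_id[match(koa$protein_id,
                                            pg$membership$protein_id)]
      genome_kos <- split(koa$ko, gmap)
      genome_kos <- lapply(pg$genome_ids, function(g)
        unique(genome_kos[[g]] %||% character(0)))
      names(genome_kos) <- pg$genome_ids
      pathways <- branch_summary(genome_kos, config$pathway_definitions)
      write_tsv(pathways, file.path(config$out_dir, "pathway_completeness.tsv"))
      note("pathway_completeness", nrow(pathways))
    } else message("[pathway_completeness] skipped: no KO table")

    if (!is.null(ann$cazy)) {
      fams <- select_families(pg, ann)
      landscape <- tryCatch({
        pa <- build_pa_matrix(pg, ann, fams)
        emb <- embed_and_cluster(pa, method = config$embed_method,
                                 seed = config$seed)
        write_tsv(as.data.frame(emb),
                  file.path(config$out_dir, "cazyme_landscape.tsv"))
        note("cazyme_landscape", nrow(emb))
        list(families = fams, matrix = pa, embedding = emb)
      }, error = function(e) {
        message("[cazyme_landscape] skipped: ", conditionMessage(e))
        NULL
      })
    }
  } else {
    message("[annotation stages] skipped: no annotation tables configured")
  }

  report <- write_report(
    file.path(config$out_dir, "report.json"),
    pg = pg, conservation = cons, histogram = hist, profile = prof,
    correlation = corr, profiles = profiles, classifiers = classifiers,
    pathways = pathways, landscape = landscape)
  write_tsv(do.call(rbind, log), file.path(config$out_dir, "pipeline_log.tsv"))
  invisible(list(proteins = proteins, hits = hits, pangenome = pg,
                 conservation = cons, curves = curves, histogram = hist,
                 profile = prof, correlation = corr, annotations = ann,
                 profiles = profiles, classifiers = classifiers,
                 pathways = pathways, landscape = landscape,
                 report = report))
}

#' Write the machine-readable pipeline report
#'
#' Summarises the pangenome (group counts, strict/soft core, fractions via
#' [fraction_report()]), per-category core fractions, classifier tallies,
#' pathway labels and cluster sizes as JSON. Empty optional sections are
#' omitted.
#'
#' @param path output JSON path.
#' @param pg a `pangenome`.
#' @param conservation output of [classify_conservation()].
#' @param histogram output of [conservation_histogram()].
#' @param profile output of [per_genome_profile()].
#' @param correlation optional [unique_vs_size_correlation()] result.
#' @param profiles named list of `category_profile`s.
#' @param classifiers named list (sigma, tf, chaplins, pptases).
#' @param pathways optional [branch_summary()] result.
#' @param landscape optional CAZyme landscape result.
#' @return the report list, invisibly.
#' @export
write_report <- function(path, pg, conservation, histogram, profile,
                         correlation = NULL, profiles = list(),
                         classifiers = list(), pathways = NULL,
                         landscape = NULL) {
  n_prot <- nrow(pg$membership)
  core_prot <- sum(pg$groups$n_members[conservation$core])
  rare_prot <- sum(pg$groups$n_members[conservation$rare])
  rep <- list(
    n_genomes = pg$n_genomes,
    n_proteins = n_prot,
    n_groups = nrow(pg$groups),
    strict_core_groups = sum(conservation$strict_core),
    core_groups = sum(conservation$core),
    single_copy_core_groups = sum(conservation$single_copy_core),
    singletons = sum(conservation$singleton),
    core_proteins = core_prot,
    core_protein_pct = fraction_report(core_prot, n_prot),
    rare_proteins = rare_prot,
    rare_protein_pct = fraction_report(rare_prot, n_prot),
    histogram = histogram,
    per_genome = profile)
  if (!is.null(correlation)) rep$rare_vs_size_correlation <- correlation
  if (length(profiles) > 0)
    rep$category_core_pct <- lapply(profiles, function(p)
      attr(p, "core_fraction"))
  if (length(classifiers) > 0)
    rep$classifier_tallies <- list(
      sigma_factors = nrow(classifiers$sigma),
      sigma_groups = as.list(table(classifiers$sigma$group)),
      transcription_factors = nrow(classifiers$tf),
      chaplins = length(classifiers$chaplins),
      pptases = nrow(classifiers$pptases),
      pptase_types = as.list(table(classifiers$pptases$type)))
  if (!is.null(pathways))
    rep$pathway_labels <- as.list(attr(pathways, "counts"))
  if (!is.null(landscape))
    rep$cazyme_clusters <- cluster_sizes(landscape$embedding)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(rep)
}
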