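#' Default E-value thresholds for annotation tables
#'
#' Independent E-value thresholds applied when loading annotation tables:
#' 1e-1 for Pfam/SMART domain hits, 1e-10 for COG assignments. KO rows are
#' kept raw because KO assignment has its own two-tier rule (see
#' [assign_ko()]).
#'
#' @param domain domain-hit threshold (strict `<`).
#' @param cog COG threshold (strict `<`).
#' @return named list of thresholds.
#' @export
annotation_thresholds <- function(domain = 1e-1, cog = 1e-10) {
  list(domain = domain, cog = cog)
}

tbl_or_path <- function(x, cols, numeric_cols) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) {
    miss <- setdiff(cols, names(x))
    if (length(miss) > 0)
      stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
    return(x[, cols])
  }
  read_tsv_strict(x, cols, numeric_cols)
}

dedup <- function(df) {
  if (is.null(df)) return(list(df = NULL, removed = 0L))
  keep <- !duplicated(df)
  list(df = df[keep, , drop = FALSE], removed = sum(!keep))
}

#' Load functional annotation tables
#'
#' Reads (or accepts in-memory) the five annotation dialects — Pfam/SMART
#' domain hits, COG categories, KO assignments, CAZyme families and BGC
#' membership — deduplicates identical rows, and applies the per-type
#' independent E-value thresholds. Raw (unfiltered) domain hits are retained
#' alongside, because PPTase identification applies its own 1e-3 threshold.
#' Row accounting (`kept + dropped = input`) is kept in `$log`.
#'
#' @param domain path or data frame: `protein_id`, `accession`, `name`,
#'   `ievalue`, `start`, `end`.
#' @param cog path or data frame: `protein_id`, `category`, `evalue`.
#' @param ko path or data frame: `protein_id`, `ko`, `score`, `threshold`,
#'   `evalue`.
#' @param cazy path or data frame: `protein_id`, `family`.
#' @param bgc path or data frame: `protein_id`, `bgc_type`, `core_enzyme`.
#' @param thresholds an [annotation_thresholds()] list.
#' @return object of class `annotation_set` with elements `domain`
#'   (filtered), `domain_raw`, `cog`, `ko` (raw), `cazy`, `bgc`, `log`.
#' @export
load_annotations <- function(domain = NULL, cog = NULL, ko = NULL,
                             cazy = NULL, bgc = NULL,
                             thresholds = annotation_thresholds()) {
  dom <- tbl_or_path(domain, c("protein_id", "accession", "name", "ievalue",
                               "start", "end"),
                     c("ievalue", "start", "end"))
  cg <- tbl_or_path(cog, c("protein_id", "category", "evalue"), "evalue")
  k <- tbl_or_path(ko, c("protein_id", "ko", "score", "threshold", "evalue"),
                   c("score", "threshold", "evalue"))
  cz <- tbl_or_path(cazy, c("protein_id", "family"), character(0))
  bg <- tbl_or_path(bgc, c("protein_id", "bgc_type", "core_enzyme"),
                    "core_enzyme")
  log <- list()
  note <- function(table, input, dup, thr) {
    data.frame(table = table, input = input, dropped_duplicate = dup,
               dropped_threshold = thr, kept = input - dup - thr)
  }
  d <- dedup(dom); dom <- d$df
  dom_raw <- dom
  thr_dom <- 0L
  if (!is.null(dom)) {
    keep <- dom$ievalue < thresholds$domain
    thr_dom <- sum(!keep)
    dom <- dom[keep, , drop = FALSE]
    log$domain <- note("domain", nrow(dom_raw) + d$removed, d$removed, thr_dom)
  }
  d <- dedup(cg); cg <- d$df
  if (!is.null(cg)) {
    keep <- cg$evalue < thresholds$cog
    log$cog <- note("cog", nrow(cg) + d$removed, d$removed, sum(!keep))
    cg <- cg[keep, , drop = FALSE]
  }
  d <- dedup(k); k <- d$df
  if (!is.null(k)) {
    if (any(k$score < 0) || any(k$evalue < 0))
      stop("negative score or E-value in KO table")
    log$ko <- note("ko", nrow(k) + d$removed, d$removed, 0L)
  }
  d <- dedup(cz); cz <- d$df
  if (!is.null(cz)) log$cazy <- note("cazy", nrow(cz) + d$removed, d$removed, 0L)
  d <- dedup(bg); bg <- d$df
  if (!is.null(bg)) log$bgc <- note("bgc", nrow(bg) + d$removed, d$removed, 0L)
  structure(list(domain = dom, domain_raw = dom_raw, cog = cg, ko = k,
                 cazy = cz, bgc = bg,
                 log = do.call(rbind, unname(log))),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("Annotation set\n")
  if (!is.null(x$log)) print(x$log)
  invisible(x)
}

cazy_class_of <- function(family) {
  m <- regexpr("^(CBM|GH|GT|PL|CE|AA)", family)
  out <- rep(NA_character_, length(family))
  out[m > 0] <- substr(family[m > 0], 1L, attr(m, "match.length")[m > 0])
  out
}

# protein_id / label pairs for one label type
label_table <- function(ann, label_type, cog_mode = "split", ko_map = NULL,
                        kegg_exclude = character()) {
  switch(label_type,
    COG_category = {
      if (is.null(ann$cog)) stop("no COG table loaded")
      letters <- strsplit(ann$cog$category, "", fixed = TRUE)
      if (cog_mode == "first") letters <- lapply(letters, `[`, 1L)
      data.frame(protein_id = rep(ann$cog$protein_id, lengths(letters)),
                 label = unlist(letters), stringsAsFactors = FALSE)
    },
    KO_term = {
      if (is.null(ann$ko)) stop("no KO table loaded")
      data.frame(protein_id = ann$ko$protein_id, label = ann$ko$ko)
    },
    KEGG_category = {
      if (is.null(ann$ko)) stop("no KO table loaded")
      if (is.null(ko_map)) stop_config("KEGG_category needs a ko_map ",
                                       "(columns ko, category)")
      df <- merge(ann$ko[, c("protein_id", "ko")], ko_map, by = "ko")
      df <- df[!(df$category %in% kegg_exclude), , drop = FALSE]
      data.frame(protein_id = df$protein_id, label = df$category)
    },
    CAZy_family = {
      if (is.null(ann$cazy)) stop("no CAZy table loaded")
      data.frame(protein_id = ann$cazy$protein_id, label = ann$cazy$family)
    },
    CAZy_class = {
      if (is.null(ann$cazy)) stop("no CAZy table loaded")
      cl <- cazy_class_of(ann$cazy$family)
      data.frame(protein_id = ann$cazy$protein_id[!is.na(cl)],
                 label = cl[!is.na(cl)])
    },
    BGC_type = {
      if (is.null(ann$bgc)) stop("no BGC table loaded")
      data.frame(protein_id = ann$bgc$protein_id, label = ann$bgc$bgc_type)
    },
    domain_accession = {
      if (is.null(ann$domain)) stop("no domain table loaded")
      data.frame(protein_id = ann$domain$protein_id,
                 label = ann$domain$accession)
    },
    stop("unknown label_type: ", label_type)
  )
}

profile_from_labels <- function(pg, lab) {
  lab <- unique(lab)
  frac <- pg$groups$fraction[match(
    pg$membership$group_id[match(lab$protein_id, pg$membership$protein_id)],
    pg$groups$group_id)]
  known <- !is.na(frac)
  lab <- lab[known, , drop = FALSE]
  frac <- frac[known]
  if (nrow(lab) == 0L) {
    out <- data.frame(label = character(0), bin = integer(0),
                      bin_low = numeric(0), bin_high = numeric(0),
                      n_proteins = integer(0), pct = numeric(0))
    attr(out, "core_fraction") <- data.frame(label = character(0),
                                             core_pct = numeric(0))
    class(out) <- c("category_profile", "data.frame")
    return(out)
  }
  bin <- conservation_bin(frac)
  tab <- stats::aggregate(list(n_proteins = lab$protein_id),
                          by = list(label = lab$label, bin = bin), FUN = length)
  tot <- tapply(tab$n_proteins, tab$label, sum)
  tab$bin_low <- (tab$bin - 1) * 0.05
  tab$bin_high <- tab$bin * 0.05
  tab$pct <- round_half_up(100 * tab$n_proteins / as.numeric(tot[tab$label]), 1)
  tab <- tab[order(tab$label, tab$bin),
             c("label", "bin", "bin_low", "bin_high", "n_proteins", "pct")]
  rownames(tab) <- NULL
  core_n <- tapply(tab$n_proteins[tab$bin_high > 0.95],
                   tab$label[tab$bin_high > 0.95], sum)
  core_cnt <- unname(core_n[names(tot)])
  core_cnt[is.na(core_cnt)] <- 0
  cf <- data.frame(label = names(tot),
                   n_proteins = as.integer(tot),
                   core_pct = round_half_up(100 * core_cnt / as.numeric(tot),
                                            1),
                   stringsAsFactors = FALSE)
  rownames(cf) <- NULL
  attr(tab, "core_fraction") <- cf
  class(tab) <- c("category_profile", "data.frame")
  tab
}

#' Conservation profile of a functional category
#'
#' Joins annotated proteins to their orthologous group's conservation bin and
#' tallies, per label of the requested type, the number of proteins in each
#' of the twenty 5%-wide prevalence bins together with within-label
#' percentages (half-up at 0.1% resolution; they sum to 100% up to rounding).
#' A protein with several labels of the same type contributes once per label;
#' unannotated proteins are excluded. Multi-letter COG strings are split into
#' one contribution per letter by default (`cog_mode = "first"` keeps only
#' the first letter).
#'
#' @param pg a `pangenome`.
#' @param ann an `annotation_set`.
#' @param label_type one of `"COG_category"`, `"KO_term"`,
#'   `"KEGG_category"`, `"CAZy_family"`, `"CAZy_class"`, `"BGC_type"`,
#'   `"domain_accession"`.
#' @param cog_mode `"split"` or `"first"` (COG only).
#' @param ko_map data frame `ko`, `category`: KO-to-category rollup used for
#'   `KEGG_category` (the KO hierarchy is not bundled; supply your own
#'   mapping).
#' @param kegg_exclude categories to drop from the rollup (e.g.
#'   eukaryote-only pathways or "biosynthesis of secondary metabolites").
#' @return `category_profile` data frame `label`, `bin`, `bin_low`,
#'   `bin_high`, `n_proteins`, `pct`, with attribute `core_fraction` (per
#'   label: total proteins and percentage in core groups).
#' @export
category_profile <- function(pg, ann, label_type, cog_mode = c("split", "first"),
                             ko_map = NULL, kegg_exclude = character()) {
  stopifnot(inherits(pg, "pangenome"), inherits(ann, "annotation_set"))
  cog_mode <- match.arg(cog_mode)
  lab <- label_table(ann, label_type, cog_mode, ko_map, kegg_exclude)
  profile_from_labels(pg, lab)
}

#' Per-genome CAZyme class count statistics
#'
#' Per-genome counts of annotated proteins in each CAZyme class (GH, GT, PL,
#' CE, CBM, AA), with mean, population standard deviation and coefficient of
#' variation (CV = SD/mean) per class, plus per-genome CAZyme totals.
#' Genomes without any member of a class count as zero; a class absent from
#' every genome has an undefined CV, reported as `NA`.
#'
#' @param ann an `annotation_set` with a CAZy table.
#' @param pg a `pangenome` (source of the protein-to-genome map and genome
#'   universe).
#' @return list with `counts` (genome x class matrix), `stats` (data frame
#'   `class`, `mean`, `sd`, `cv`), `genome_totals` (named vector).
#' @export
class_count_stats <- function(ann, pg) {
  stopifnot(inherits(ann, "annotation_set"), inherits(pg, "pangenome"))
  if (is.null(ann$cazy)) stop("no CAZy table loaded")
  cl <- cazy_class_of(ann$cazy$family)
  gen <- pg$membership$genome_id[match(ann$cazy$protein_id,
                                       pg$membership$protein_id)]
  ok <- !is.na(cl) & !is.na(gen)
  classes <- c("GH", "GT", "PL", "CE", "CBM", "AA")
  counts <- matrix(0L, nrow = pg$n_genomes, ncol = length(classes),
                   dimnames = list(pg$genome_ids, classes))
  if (any(ok)) {
    t0 <- table(factor(gen[ok], levels = pg$genome_ids),
                factor(cl[ok], levels = classes))
    counts[] <- as.integer(t0)
  }
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  st <- data.frame(class = classes,
                   mean = colMeans(counts),
                   sd = apply(counts, 2, pop_sd))
  st$cv <- ifelse(st$mean > 0, st$sd / st$mean, NA_real_)
  rownames(st) <- NULL
  tot_tab <- table(factor(gen[ok], levels = pg$genome_ids))
  totals <- setNames(as.integer(tot_tab), pg$genome_ids)
  list(counts = counts, stats = st, genome_totals = totals)
}

#' Conservation profile of BGC core biosynthetic enzymes
#'
#' Same computation as [category_profile()] restricted to proteins flagged as
#' core biosynthetic enzymes in the BGC membership table, keyed by BGC type
#' — e.g. butyrolactone synthases concentrating in the lowest conservation
#' bin while ectoine enzymes sit near the core.
#'
#' @param pg a `pangenome`.
#' @param ann an `annotation_set` with a BGC table (`core_enzyme` 0/1).
#' @return a `category_profile` (possibly empty).
#' @export
bgc_core_enzyme_profile <- function(pg, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (is.null(ann$bgc)) stop("no BGC table loaded")
  core <- ann$bgc[ann$bgc$core_enzyme > 0, , drop = FALSE]
  lab <- data.frame(protein_id = core$protein_id, label = core$bgc_type,
                    stringsAsFactors = FALSE)
  profile_from_labels(pg, lab)
}
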