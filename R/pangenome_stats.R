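# group-by-genome logical presence matrix
presence_matrix <- function(pg) {
  stopifnot(inherits(pg, "pangenome"))
  gids <- pg$groups$group_id
  m <- matrix(FALSE, nrow = length(gids), ncol = pg$n_genomes,
              dimnames = list(gids, pg$genome_ids))
  m[cbind(match(pg$copy_number$group_id, gids),
          match(pg$copy_number$genome_id, pg$genome_ids))] <- TRUE
  m
}

#' Gene accumulation and core-genome curves
#'
#' For `n_permutations` random orderings of the genomes, computes after each
#' added genome k: the pangenome size (number of orthologous groups seen in
#' the first k genomes), the strict-core size (groups present in all k) and
#' the soft-core size (groups present in at least `soft_core_fraction` of the
#' k). Within any single ordering the pangenome size is non-decreasing and
#' the strict core non-increasing in k.
#'
#' @param pg a `pangenome`.
#' @param n_permutations number of random genome orderings (>= 1).
#' @param seed integer seed; same seed gives identical samples.
#' @param soft_core_fraction soft-core prevalence threshold (default 0.95).
#' @return object of class `accumulation_curve`: data frame `permutation`,
#'   `k`, `pangenome`, `strict_core`, `soft_core`.
#' @export
accumulation_curves <- function(pg, n_permutations = 100, seed = 1,
                                soft_core_fraction = 0.95) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  m <- presence_matrix(pg)
  n <- ncol(m)
  set.seed(seed)
  res <- vector("list", n_permutations)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(n)
    cum <- t(apply(m[, ord, drop = FALSE], 1L, cumsum))
    if (nrow(m) == 1L) cum <- matrix(cum, nrow = 1L)
    k <- seq_len(n)
    res[[p]] <- data.frame(
      permutation = p, k = k,
      pangenome = colSums(cum > 0L),
      strict_core = colSums(cum == rep(k, each = nrow(cum))),
      soft_core = colSums(cum >= rep(ceiling(soft_core_fraction * k) ,
                                     each = nrow(cum))))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "soft_core_fraction") <- soft_core_fraction
  class(out) <- c("accumulation_curve", "data.frame")
  out
}

# conservation bin of a prevalence fraction: 20 half-open intervals
# (0, 0.05], (0.05, 0.10], ..., (0.95, 1.0]
conservation_bin <- function(fraction) {
  stopifnot(all(fraction > 0), all(fraction <= 1))
  b <- ceiling(fraction / 0.05 - 1e-9)
  pmin(pmax(b, 1L), 20L)
}

#' Conservation histogram of the pangenome
#'
#' Bins every orthologous group by its prevalence fraction into twenty
#' half-open 5%-wide intervals `(0, 0.05], (0.05, 0.10], ..., (0.95, 1]`
#' (left-open, right-closed: at 205 genomes, prevalence 10 falls in the first
#' bin — "10 genomes or less is < 5%"). Protein counts weight each group by
#' its member count, so per-bin protein counts sum to the protein universe.
#'
#' @param pg a `pangenome`.
#' @return data frame `bin`, `bin_low`, `bin_high`, `n_groups`, `n_proteins`.
#' @export
conservation_histogram <- function(pg) {
  stopifnot(inherits(pg, "pangenome"))
  b <- conservation_bin(pg$groups$fraction)
  out <- data.frame(bin = 1:20,
                    bin_low = seq(0, 0.95, by = 0.05),
                    bin_high = seq(0.05, 1, by = 0.05))
  out$n_groups <- as.integer(tabulate(b, nbins = 20))
  out$n_proteins <- as.integer(
    vapply(1:20, function(i) sum(pg$groups$n_members[b == i]), numeric(1)))
  out
}

#' Per-genome conservation profile
#'
#' Counts, for each genome, its total proteins and how many fall in core
#' groups, rare groups, strain-specific groups (prevalence 1) and singleton
#' groups (one member). Totals equal the proteome sizes.
#'
#' @param pg a `pangenome`.
#' @param core_fraction,rare_fraction thresholds as in
#'   [classify_conservation()].
#' @return data frame `genome_id`, `total`, `core`, `rare`,
#'   `strain_specific`, `singletons`.
#' @export
per_genome_profile <- function(pg, core_fraction = 0.95, rare_fraction = 0.05) {
  cc <- classify_conservation(pg, core_fraction, rare_fraction)
  lab <- cc[match(pg$membership$group_id, cc$group_id), ]
  agg <- function(flag) {
    v <- tapply(flag, pg$membership$genome_id, sum)
    as.integer(v[pg$genome_ids])
  }
  data.frame(genome_id = pg$genome_ids,
             total = agg(rep(TRUE, nrow(lab))),
             core = agg(lab$core),
             rare = agg(lab$rare),
             strain_specific = agg(lab$strain_specific),
             singletons = agg(lab$singleton),
             stringsAsFactors = FALSE)
}

#' Correlation between rare-protein count and proteome size
#'
#' Rank (Spearman) correlation between the number of rare proteins each
#' genome encodes and its total protein count — larger genomes tend to carry
#' more low-prevalence proteins.
#'
#' @param profile output of [per_genome_profile()].
#' @param method correlation method, default `"spearman"`.
#' @return list with `estimate`, `p.value`, `method`, `n`.
#' @export
unique_vs_size_correlation <- function(profile, method = "spearman") {
  if (nrow(profile) < 3) stop("need at least 3 genomes")
  x <- profile$rare
  y <- profile$total
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant column")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n = nrow(profile))
}

#' Percentages from count pairs
#'
#' `100 * numerator / denominator` with half-up rounding, as percentages are
#' printed in pangenome reports: one decimal by default (`digits = 0` gives
#' integer percents).
#'
#' @param numerator,denominator non-negative counts (vectorised;
#'   `denominator` must be positive).
#' @param digits decimal places (default 1).
#' @return numeric vector of percentages.
#' @examples
#' fraction_report(65944, 1536567)   # 4.3
#' @export
fraction_report <- function(numerator, denominator, digits = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0)) stop("numerator must be >= 0")
  round_half_up(100 * numerator / denominator, digits)
}
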