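#' Assign KO terms to proteins
#'
#' Standard mode keeps rows passing the KofamKOALA-style two-part rule:
#' independent E-value strictly below `evalue_threshold` (1e-10) *and* bit
#' score at or above the KO-specific adaptive threshold; the best row per
#' protein is retained (highest score, ties broken by smaller E-value then
#' lexicographic KO). Relaxed mode additionally assigns, to proteins with no
#' standard-mode KO, their highest-score KO when its independent E-value is
#' strictly below `relaxed_evalue` (1e-80) — useful for pathway-completeness
#' calls where the adaptive threshold is too conservative. Relaxed mode is a
#' superset of standard mode.
#'
#' @param rows data frame `protein_id`, `ko`, `score`, `threshold` (the
#'   KO-specific score threshold), `evalue`.
#' @param relaxed apply the relaxed rule (default `TRUE`).
#' @param evalue_threshold standard-mode E-value bound (strict).
#' @param relaxed_evalue relaxed-mode E-value bound (strict).
#' @return data frame `protein_id`, `ko`, `score`, `evalue`, `mode`
#'   (`"standard"`/`"relaxed"`), one row per assigned protein.
#' @export
assign_ko <- function(rows, relaxed = TRUE, evalue_threshold = 1e-10,
                      relaxed_evalue = 1e-80) {
  stopifnot(all(c("protein_id", "ko", "score", "threshold", "evalue")
                %in% names(rows)))
  if (any(rows$score < 0) || any(rows$evalue < 0))
    stop("negative score or E-value in KO rows")
  best_of <- function(df) {
    df <- df[order(-df$score, df$evalue, df$ko), , drop = FALSE]
    df[1L, ]
  }
  std <- rows[rows$evalue < evalue_threshold & rows$score >= rows$threshold, ,
              drop = FALSE]
  out <- list()
  if (nrow(std) > 0L) {
    picked <- do.call(rbind, lapply(split(std, std$protein_id), best_of))
    picked$mode <- "standard"
    out$std <- picked
  }
  if (relaxed) {
    assigned <- if (is.null(out$std)) character(0) else out$std$protein_id
    rest <- rows[!(rows$protein_id %in% assigned), , drop = FALSE]
    if (nrow(rest) > 0L) {
      picked <- do.call(rbind, lapply(split(rest, rest$protein_id), best_of))
      picked <- picked[picked$evalue < relaxed_evalue, , drop = FALSE]
      if (nrow(picked) > 0L) {
        picked$mode <- "relaxed"
        out$rel <- picked
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(0), ko = character(0),
                      score = numeric(0), evalue = numeric(0),
                      mode = character(0)))
  res <- do.call(rbind, unname(out))
  res <- res[order(res$protein_id), c("protein_id", "ko", "score", "evalue",
                                      "mode")]
  rownames(res) <- NULL
  res
}

#' Define a stepwise metabolic pathway
#'
#' A pathway is an ordered list of reaction steps, each satisfiable by any
#' member of a set of acceptable KO terms (OR semantics — isoenzymes). Steps
#' shared with a sister pathway can be marked so branch summaries evaluate
#' them consistently.
#'
#' @param pathway_id identifier.
#' @param steps named list of non-empty character vectors of KO terms, in
#'   reaction order.
#' @param shared_with optional list `list(pathway = <id>, steps =
#'   <step indices>)` marking steps shared with another pathway.
#' @return object of class `pathway_definition`.
#' @export
pathway_definition <- function(pathway_id, steps, shared_with = NULL) {
  if (length(steps) < 1L) stop_config("pathway needs at least one step")
  if (any(lengths(steps) == 0L)) stop_config("every step needs >= 1 KO term")
  if (is.null(names(steps)) || any(!nzchar(names(steps))))
    names(steps) <- paste0("step", seq_along(steps))
  if (!is.null(shared_with)) {
    if (any(shared_with$steps < 1 | shared_with$steps > length(steps)))
      stop_config("shared_with references non-existent steps")
  }
  structure(list(pathway_id = pathway_id, steps = steps,
                 shared_with = shared_with),
            class = "pathway_definition")
}

#' Default 6-step beta-ketoadipate branch definitions
#'
#' The protocatechuate and catechol catabolic branches each comprise six
#' reactions of which the last three (enol-lactone hydrolase, beta-ketoadipate
#' CoA-transferase, thiolase) are shared. The KO terms filled in here are
#' conventional KEGG assignments for the canonical enzymes (pcaGH, pcaB,
#' pcaC; catA, catB, catC; shared pcaD, pcaIJ, pcaF) and are editable
#' defaults — verify them against the current KEGG release before drawing
#' biological conclusions. Each step accepts any listed KO (OR semantics),
#' including subunits of multimeric enzymes.
#'
#' @return named list of two [pathway_definition()]s:
#'   `protocatechuate`, `catechol`.
#' @export
beta_ketoadipate_definitions <- function() {
  shared <- list(
    enol_lactone_hydrolase = c("K01055", "K14727"),
    ketoadipate_coa_transferase = c("K01031", "K01032"),
    ketoadipyl_coa_thiolase = c("K00632", "K07823"))
  proto <- pathway_definition(
    "protocatechuate",
    c(list(protocatechuate_dioxygenase = c("K00448", "K00449"),
           carboxymuconate_cycloisomerase = "K01857",
           carboxymuconolactone_decarboxylase = "K01607"),
      shared),
    shared_with = list(pathway = "catechol", steps = 4:6))
  cat_ <- pathway_definition(
    "catechol",
    c(list(catechol_dioxygenase = "K03381",
           muconate_cycloisomerase = "K01856",
           muconolactone_isomerase = "K03464"),
      shared),
    shared_with = list(pathway = "protocatechuate", steps = 4:6))
  list(protocatechuate = proto, catechol = cat_)
}

#' Is a pathway complete in a genome?
#'
#' A pathway is complete iff every step has at least one of its acceptable
#' KO terms present in the genome's KO set — presence only, regardless of
#' copy number or gene order.
#'
#' @param kos character vector: the genome's assigned KO terms.
#' @param definition a [pathway_definition()].
#' @return list with `complete` (logical), `step_present` (named logical per
#'   step) and `missing` (names of absent steps).
#' @export
pathway_complete <- function(kos, definition) {
  stopifnot(inherits(definition, "pathway_definition"))
  present <- vapply(definition$steps, function(s) any(s %in% kos), logical(1))
  list(complete = all(present), step_present = present,
       missing = names(present)[!present])
}

#' Joint branch completeness summary
#'
#' Evaluates each genome's KO set against both beta-ketoadipate branch
#' definitions (or any pair of definitions) and labels the genome `both`,
#' one branch name, or `neither`.
#'
#' @param genome_kos named list: genome id -> character vector of KO terms.
#' @param definitions named list of two [pathway_definition()]s.
#' @return data frame with one logical column per pathway, a `label` column,
#'   and attribute `counts` (table of labels).
#' @export
branch_summary <- function(genome_kos, definitions = beta_ketoadipate_definitions()) {
  stopifnot(length(definitions) == 2L, !is.null(names(definitions)))
  p1 <- names(definitions)[1L]; p2 <- names(definitions)[2L]
  rows <- lapply(names(genome_kos), function(g) {
    c1 <- pathway_complete(genome_kos[[g]], definitions[[1L]])$complete
    c2 <- pathway_complete(genome_kos[[g]], definitions[[2L]])$complete
    lab <- if (c1 && c2) "both" else if (c1) p1 else if (c2) p2 else "neither"
    df <- data.frame(genome_id = g, a = c1, b = c2, label = lab,
                     stringsAsFactors = FALSE)
    names(df)[2:3] <- c(p1, p2)
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- table(factor(out$label,
                                      levels = c("both", p1, p2, "neither")))
  out
}
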