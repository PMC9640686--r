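# Pfam accessions used by the rule-based classifiers
PF_SIGMA70_R2 <- "PF04542"    # Sigma70_r2: region 2, required for any sigma70
PF_SIGMA70_R4 <- "PF04545"    # Sigma70_r4
PF_SIGMA70_R4_2 <- "PF08281"  # Sigma70_r4_2
PF_SIGMA70_R1_2 <- "PF00140"  # Sigma70_r1_2
PF_SIGMA70_R3 <- "PF04539"    # Sigma70_r3
PF_SIGMA54 <- c("PF00309", "PF04963", "PF04552")  # AID, CBD, DBD
PF_CHAPLIN <- "PF03777"
PF_PPTASE <- "PF01648"        # 4'-phosphopantetheinyl transferase

# split a domain-hit table into per-protein accession sets
domain_sets <- function(hits) {
  stopifnot(all(c("protein_id", "accession") %in% names(hits)))
  split(hits$accession, hits$protein_id)
}

#' Classify sigma factors from domain architectures
#'
#' A protein is a sigma-70-family sigma factor iff it carries Sigma70_r2
#' (PF04542) and either Sigma70_r4 (PF04545) or Sigma70_r4_2 (PF08281).
#' Sigma-70 factors carrying both Sigma70_r1_2 (PF00140) and Sigma70_r3
#' (PF04539) form "group 1 or 2" (the two groups share the same minimum
#' domain set and cannot be separated without functional data); those with
#' Sigma70_r3 but not Sigma70_r1_2 are group 3; all others group 4 (the
#' extracytoplasmic-function-like remainder). Proteins carrying any of
#' PF00309/PF04963/PF04552 are called sigma-54-family. A protein matching
#' both family rules is reported for both, with a conflict warning (none are
#' expected in streptomycetes).
#'
#' Hits are expected to be pre-filtered at the Pfam/SMART threshold
#' (independent E-value < 1e-1, see [load_annotations()]).
#'
#' @param hits data frame with `protein_id`, `accession`.
#' @return data frame `protein_id`, `family` (`"sigma70"`/`"sigma54"`),
#'   `group` (`"group_1_or_2"`, `"group_3"`, `"group_4"`, or `NA` for
#'   sigma54). Zero rows if nothing matches.
#' @export
classify_sigma <- function(hits) {
  sets <- domain_sets(hits)
  out <- list()
  for (pid in names(sets)) {
    dom <- sets[[pid]]
    is70 <- PF_SIGMA70_R2 %in% dom &&
      (PF_SIGMA70_R4 %in% dom || PF_SIGMA70_R4_2 %in% dom)
    is54 <- any(PF_SIGMA54 %in% dom)
    if (is70) {
      grp <- if (PF_SIGMA70_R1_2 %in% dom && PF_SIGMA70_R3 %in% dom)
        "group_1_or_2"
      else if (PF_SIGMA70_R3 %in% dom) "group_3"
      else "group_4"
      out[[length(out) + 1L]] <- data.frame(protein_id = pid,
                                            family = "sigma70", group = grp)
    }
    if (is54) {
      if (is70)
        warning("protein ", pid, " matches both sigma70 and sigma54 rules")
      out[[length(out) + 1L]] <- data.frame(protein_id = pid,
                                            family = "sigma54",
                                            group = NA_character_)
    }
  }
  if (length(out) == 0L)
    return(data.frame(protein_id = character(0), family = character(0),
                      group = character(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id, res$family), ]
  rownames(res) <- NULL
  res
}

#' Read a transcription-factor architecture rule table
#'
#' TSV with header `rule_id`, `family`, `priority`, `required`, `forbidden`;
#' `required`/`forbidden` are comma-separated Pfam accessions (`forbidden`
#' may be `-` for none). A small example catalogue covering a handful of
#' families ships with the package (`system.file("extdata", "tf_rules.tsv",
#' package = "streptopan")`); real analyses should supply a full
#' P2TF-style catalogue.
#'
#' @param path TSV path.
#' @return data frame with `required`/`forbidden` as list columns.
#' @export
read_tf_rules <- function(path) {
  df <- read_tsv_strict(path, c("rule_id", "family", "priority",
                                "required", "forbidden"), "priority")
  parse_set <- function(x) {
    lapply(x, function(s) if (s == "-" || s == "") character(0)
           else strsplit(s, ",", fixed = TRUE)[[1L]])
  }
  df$required <- parse_set(df$required)
  df$forbidden <- parse_set(df$forbidden)
  bad <- vapply(seq_len(nrow(df)), function(i)
    length(intersect(df$required[[i]], df$forbidden[[i]])) > 0, logical(1))
  if (any(bad))
    stop_config("rule(s) with overlapping required/forbidden sets: ",
                paste(df$rule_id[bad], collapse = ", "))
  df[order(df$priority), ]
}

#' Classify transcription factors by domain architecture
#'
#' Applies architecture rules (required domains all present, forbidden
#' domains all absent) in priority order; the first matching rule wins and
#' ties (several matching rules) are recorded in the `ties` attribute.
#' Proteins already called sigma factors must be passed via `exclude` and are
#' never classified as transcription factors.
#'
#' @param hits data frame `protein_id`, `accession`.
#' @param rules rule table from [read_tf_rules()] (or an equivalent data
#'   frame with list columns).
#' @param exclude protein ids to skip (typically sigma-factor calls).
#' @return data frame `protein_id`, `family`, `rule_id`; attribute `ties`.
#' @export
classify_tf <- function(hits, rules, exclude = character()) {
  if (is.null(rules) || nrow(rules) == 0L)
    stop_config("empty transcription-factor rule table")
  sets <- domain_sets(hits)
  sets <- sets[!(names(sets) %in% exclude)]
  out <- list(); ties <- list()
  for (pid in names(sets)) {
    dom <- sets[[pid]]
    match_i <- which(vapply(seq_len(nrow(rules)), function(i)
      all(rules$required[[i]] %in% dom) &&
        !any(rules$forbidden[[i]] %in% dom), logical(1)))
    if (length(match_i) == 0L) next
    if (length(match_i) > 1L)
      ties[[pid]] <- rules$rule_id[match_i]
    i <- match_i[1L]
    out[[length(out) + 1L]] <- data.frame(protein_id = pid,
                                          family = rules$family[i],
                                          rule_id = rules$rule_id[i])
  }
  res <- if (length(out) == 0L)
    data.frame(protein_id = character(0), family = character(0),
               rule_id = character(0))
  else do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "ties") <- ties
  res
}

#' Identify chaplins
#'
#' Chaplins — the amyloid proteins coating aerial hyphae and spores — are
#' proteins with at least one chaplin domain (PF03777) hit surviving the
#' Pfam threshold.
#'
#' @param hits threshold-filtered domain hits (`protein_id`, `accession`).
#' @return sorted character vector of protein ids.
#' @export
identify_chaplins <- function(hits) {
  sort(unique(hits$protein_id[hits$accession == PF_CHAPLIN]))
}

# maximum number of pairwise non-overlapping intervals (greedy by end)
max_disjoint <- function(start, end) {
  o <- order(end)
  n <- 0L; last_end <- -Inf
  for (i in o) {
    if (start[i] > last_end) { n <- n + 1L; last_end <- end[i] }
  }
  n
}

#' Identify phosphopantetheinyl transferases and type them
#'
#' A protein is a PPTase iff it has at least one 4'-phosphopantetheinyl
#' transferase domain (PF01648) hit with independent E-value strictly below
#' 1e-3 (this rule applies its own threshold, so pass *raw* domain hits).
#' Sfp-type PPTases carry a second transferase domain: proteins with two or
#' more envelope-non-overlapping qualifying hits (overlap = any shared
#' residue) are typed `Sfp`, the rest `AcpS`.
#'
#' @param hits raw domain hits: `protein_id`, `accession`, `ievalue`,
#'   `start`, `end`.
#' @param max_evalue PPTase E-value threshold (strict; default 1e-3).
#' @return data frame `protein_id`, `n_domains` (non-overlapping qualifying
#'   hits), `type` (`"AcpS"`/`"Sfp"`).
#' @export
identify_pptases <- function(hits, max_evalue = 1e-3) {
  stopifnot(all(c("protein_id", "accession", "ievalue", "start", "end")
                %in% names(hits)))
  q <- hits[hits$accession == PF_PPTASE & hits$ievalue < max_evalue, ,
            drop = FALSE]
  if (nrow(q) == 0L)
    return(data.frame(protein_id = character(0), n_domains = integer(0),
                      type = character(0)))
  byp <- split(q, q$protein_id)
  nd <- vapply(byp, function(d) max_disjoint(d$start, d$end), integer(1))
  out <- data.frame(protein_id = names(nd), n_domains = as.integer(nd),
                    type = ifelse(nd >= 2L, "Sfp", "AcpS"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id), ]
  rownames(out) <- NULL
  out
}
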