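#' Build the orthologue graph from qualifying hits
#'
#' Nodes are the full protein universe (proteins with no qualifying hit become
#' isolated nodes); an undirected edge joins two proteins iff at least one
#' direction of their hit pair qualifies under `criteria` (single direction is
#' enough — no reciprocal-best-hit requirement). Self loops are never added.
#'
#' @param hits hit data frame ([all_vs_all()] / [read_blast_tab()]).
#' @param universe character vector of all protein ids.
#' @param criteria `NULL` if `hits` is already filtered to qualifying hits,
#'   otherwise an [orthologue_criteria()] applied here.
#' @return an undirected [igraph::graph].
#' @export
build_graph <- function(hits, universe, criteria = NULL) {
  if (anyDuplicated(universe)) stop("duplicate ids in universe")
  if (!is.null(criteria)) hits <- hits[hit_passes(hits, criteria), , drop = FALSE]
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), universe)
  if (length(unknown) > 0)
    stop("hit references protein(s) not in universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  edges <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(universe))
  igraph::simplify(g)
}

#' Extract orthologous groups as connected components
#'
#' One orthologous group per connected component of the orthologue graph.
#' Group ids are deterministic: components are ranked by their
#' lexicographically smallest member id and named `OG000001`, `OG000002`, ...
#'
#' @param graph undirected graph from [build_graph()].
#' @param genome_map data frame `protein_id`, `genome_id` (or a named
#'   character vector protein -> genome) covering every node.
#' @return an object of class `pangenome`: a list with
#'   \describe{
#'     \item{membership}{data frame `protein_id`, `genome_id`, `group_id`.}
#'     \item{groups}{data frame `group_id`, `n_members`, `prevalence`,
#'       `fraction` (prevalence / n_genomes).}
#'     \item{copy_number}{data frame `group_id`, `genome_id`, `n_copies`.}
#'     \item{genome_ids, n_genomes}{the genome universe.}
#'   }
#' @export
extract_groups <- function(graph, genome_map) {
  if (is.data.frame(genome_map)) {
    gm <- setNames(genome_map$genome_id, genome_map$protein_id)
  } else gm <- genome_map
  ids <- igraph::V(graph)$name
  missing <- setdiff(ids, names(gm))
  if (length(missing) > 0)
    stop("no genome assignment for protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  comp <- igraph::components(graph)$membership
  # deterministic ids: rank components by smallest member id
  smallest <- tapply(names(comp), comp, min)
  newid <- sprintf("OG%06d", order(order(smallest)))
  names(newid) <- names(smallest)
  membership <- data.frame(protein_id = ids,
                           genome_id = unname(gm[ids]),
                           group_id = unname(newid[as.character(comp)]),
                           stringsAsFactors = FALSE)
  membership <- membership[order(membership$group_id, membership$protein_id), ]
  rownames(membership) <- NULL
  genome_ids <- sort(unique(unname(gm)))
  cn <- stats::aggregate(list(n_copies = membership$protein_id),
                         by = list(group_id = membership$group_id,
                                   genome_id = membership$genome_id),
                         FUN = length)
  cn <- cn[order(cn$group_id, cn$genome_id), ]
  rownames(cn) <- NULL
  prev <- tapply(cn$genome_id, cn$group_id, length)
  size <- tapply(cn$n_copies, cn$group_id, sum)
  gids <- sort(names(prev))
  groups <- data.frame(group_id = gids,
                       n_members = as.integer(size[gids]),
                       prevalence = as.integer(prev[gids]),
                       fraction = as.integer(prev[gids]) / length(genome_ids),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  structure(list(membership = membership, groups = groups, copy_number = cn,
                 genome_ids = genome_ids, n_genomes = length(genome_ids)),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat("Pangenome:", x$n_genomes, "genomes,", nrow(x$membership), "proteins,",
      nrow(x$groups), "orthologous groups\n")
  cc <- classify_conservation(x)
  cat("  strict core:", sum(cc$strict_core),
      " core (>=95%):", sum(cc$core),
      " rare (<5%):", sum(cc$rare),
      " singletons:", sum(cc$singleton), "\n")
  invisible(x)
}

#' One-call pangenome construction
#'
#' Convenience wrapper: [all_vs_all()] similarity, [hit_passes()] filtering,
#' [build_graph()] and [extract_groups()].
#'
#' @param proteins data frame `protein_id`, `genome_id`, `sequence` (or a
#'   `synthetic_pangenome`).
#' @param criteria an [orthologue_criteria()].
#' @param ... passed to [all_vs_all()].
#' @return a `pangenome`.
#' @export
cluster_pangenome <- function(proteins, criteria = orthologue_criteria(), ...) {
  if (inherits(proteins, "synthetic_pangenome")) proteins <- proteins$proteins
  hits <- all_vs_all(proteins, ...)
  g <- build_graph(hits, proteins$protein_id, criteria)
  extract_groups(g, proteins[, c("protein_id", "genome_id")])
}

#' Classify orthologous groups by conservation
#'
#' Applies the prevalence-based conservation labels: `strict_core` (present
#' in every genome), `core` (prevalence fraction >= `core_fraction`, computed
#' on the real-valued fraction with no rounding, so at 205 genomes "core"
#' means >= 195), `rare` (fraction < `rare_fraction`; at 205 genomes this is
#' 10 genomes or less), `strain_specific` (prevalence 1), `singleton` (single
#' member), and `single_copy_core` (present exactly once in every genome).
#' `rare`, `strain_specific` and `singleton` can co-occur. The `category`
#' column gives the mutually exclusive band: `core`, `rare` or
#' `intermediate`.
#'
#' @param pg a `pangenome`.
#' @param core_fraction core threshold (default 0.95), inclusive.
#' @param rare_fraction rare threshold (default 0.05), strict.
#' @return data frame: `group_id`, `prevalence`, `fraction`, the logical
#'   label columns, and `category`.
#' @export
classify_conservation <- function(pg, core_fraction = 0.95,
                                  rare_fraction = 0.05) {
  stopifnot(inherits(pg, "pangenome"))
  if (pg$n_genomes < 2) stop("need at least 2 genomes")
  gr <- pg$groups
  single_copy <- tapply(pg$copy_number$n_copies, pg$copy_number$group_id,
                        function(v) all(v == 1))
  out <- data.frame(
    group_id = gr$group_id,
    prevalence = gr$prevalence,
    fraction = gr$fraction,
    strict_core = gr$prevalence == pg$n_genomes,
    core = gr$fraction >= core_fraction,
    rare = gr$fraction < rare_fraction,
    strain_specific = gr$prevalence == 1L,
    singleton = gr$n_members == 1L,
    single_copy_core = gr$prevalence == pg$n_genomes &
      as.logical(single_copy[gr$group_id]),
    stringsAsFactors = FALSE)
  out$category <- ifelse(out$core, "core",
                         ifelse(out$rare, "rare", "intermediate"))
  out
}
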