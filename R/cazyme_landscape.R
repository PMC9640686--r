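#' Select mid-prevalence CAZyme families
#'
#' A family is selected iff at least `member_fraction` (default 70%) of its
#' annotated member proteins belong to orthologous groups whose prevalence
#' fraction lies inside `band` (default \[0.05, 0.55\], both ends inclusive).
#' These are the families conserved in "some but not most" strains, whose
#' presence patterns carry taxonomic signal. Families none of whose members
#' resolve to a group are skipped and recorded in the `skipped` attribute.
#'
#' @param pg a `pangenome`.
#' @param ann an `annotation_set` with a CAZy table.
#' @param member_fraction minimum in-band member share, inclusive.
#' @param band numeric `c(lo, hi)` prevalence-fraction band, inclusive.
#' @return character vector of selected family names; attributes `shares`
#'   (data frame family, n_members, in_band_share) and `skipped`.
#' @export
select_families <- function(pg, ann, member_fraction = 0.70,
                            band = c(0.05, 0.55)) {
  stopifnot(inherits(pg, "pangenome"), inherits(ann, "annotation_set"))
  if (is.null(ann$cazy)) stop("no CAZy table loaded")
  cz <- unique(ann$cazy[, c("protein_id", "family")])
  frac <- pg$groups$fraction[match(
    pg$membership$group_id[match(cz$protein_id, pg$membership$protein_id)],
    pg$groups$group_id)]
  known <- !is.na(frac)
  skipped <- setdiff(unique(cz$family), unique(cz$family[known]))
  cz <- cz[known, , drop = FALSE]; frac <- frac[known]
  if (nrow(cz) == 0L) {
    out <- character(0)
    attr(out, "shares") <- data.frame(family = character(0),
                                      n_members = integer(0),
                                      in_band_share = numeric(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  in_band <- frac >= band[1] & frac <= band[2]
  n <- tapply(rep(1L, nrow(cz)), cz$family, sum)
  nib <- tapply(as.integer(in_band), cz$family, sum)
  fam <- sort(names(n))
  share <- as.numeric(nib[fam]) / as.numeric(n[fam])
  sel <- fam[share >= member_fraction - 1e-12]
  attr(sel, "shares") <- data.frame(family = fam,
                                    n_members = as.integer(n[fam]),
                                    in_band_share = share,
                                    stringsAsFactors = FALSE)
  attr(sel, "skipped") <- skipped
  sel
}

#' Presence-absence matrix of CAZyme orthologous groups
#'
#' Rows are strains, columns are orthologous groups that (a) contain at
#' least one member annotated with a selected family and (b) have prevalence
#' fraction at least `min_prevalence`. An entry is 1 iff the strain holds at
#' least one member of the group.
#'
#' @param pg a `pangenome`.
#' @param ann an `annotation_set` with a CAZy table.
#' @param families selected family names ([select_families()]).
#' @param min_prevalence minimum group prevalence fraction, inclusive.
#' @return binary matrix (strains x groups) with attribute `column_meta`
#'   (data frame `group_id`, `families`, `fraction`).
#' @export
build_pa_matrix <- function(pg, ann, families, min_prevalence = 0.05) {
  stopifnot(inherits(pg, "pangenome"), inherits(ann, "annotation_set"))
  if (is.null(ann$cazy)) stop("no CAZy table loaded")
  cz <- ann$cazy[ann$cazy$family %in% families, , drop = FALSE]
  gid <- pg$membership$group_id[match(cz$protein_id, pg$membership$protein_id)]
  ok <- !is.na(gid)
  fam_by_group <- tapply(cz$family[ok], gid[ok],
                         function(f) paste(sort(unique(f)), collapse = ","))
  gids <- sort(unique(gid[ok]))
  frac <- pg$groups$fraction[match(gids, pg$groups$group_id)]
  keep <- frac >= min_prevalence - 1e-12
  gids <- gids[keep]; frac <- frac[keep]
  if (length(gids) == 0L)
    stop("empty presence-absence matrix; relax min_prevalence or the ",
         "family selection band")
  m <- matrix(0L, nrow = pg$n_genomes, ncol = length(gids),
              dimnames = list(pg$genome_ids, gids))
  cn <- pg$copy_number[pg$copy_number$group_id %in% gids, ]
  m[cbind(match(cn$genome_id, pg$genome_ids),
          match(cn$group_id, gids))] <- 1L
  attr(m, "column_meta") <- data.frame(
    group_id = gids,
    families = unname(fam_by_group[gids]),
    fraction = frac, stringsAsFactors = FALSE)
  m
}

# classic DBSCAN over a precomputed distance matrix; labels: -1 noise,
# clusters numbered 1.. in order of first (lowest-index) member
dbscan_labels <- function(d, eps, min_pts) {
  d <- as.matrix(d)
  n <- nrow(d)
  nbr <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))  # incl. self
  core <- vapply(nbr, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nbr[[i]], i)
    while (length(queue) > 0L) {
      j <- queue[[1L]]; queue <- queue[-1L]
      if (is.na(labels[j]) || labels[j] == -1L) {
        expand <- is.na(labels[j]) && core[j]
        labels[j] <- cl
        if (expand) queue <- union(queue, nbr[[j]][is.na(labels[nbr[[j]]])])
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

# default DBSCAN radius: when the sorted pairwise distances show one clear
# gap (well-separated clusters), put eps in the middle of that gap; otherwise
# fall back to 3x the median min_pts-nearest-neighbour distance. Floored to a
# small positive value so exactly coincident points still connect.
eps_heuristic <- function(d, min_pts) {
  v <- sort(as.vector(stats::as.dist(d)))
  if (length(v) == 0L || max(v) < 1e-12) return(1e-8)
  gaps <- diff(v)
  i <- which.max(gaps)
  if (gaps[i] > 0.25 * max(v)) return(v[i] + gaps[i] / 2)
  dm <- as.matrix(d)
  kd <- apply(dm, 1L, function(row) sort(row)[min(min_pts + 1L, length(row))])
  max(3 * stats::median(kd), 1e-8)
}

#' Embed strains from a presence-absence matrix and cluster them
#'
#' Strains are embedded in 2D from Jaccard distances between their binary
#' presence-absence rows, then clustered with DBSCAN (noise label -1).
#' Two embedders are provided: `"mds"` (classical metric multidimensional
#' scaling, fully deterministic) and `"graph"` (a seeded force-directed
#' layout of the `n_neighbors`-nearest-neighbour graph — the
#' neighbourhood-graph family of embeddings that UMAP belongs to). When
#' `eps` is `NULL`, the DBSCAN radius is set by a k-distance heuristic
#' (3x the median `min_cluster_size`-NN distance in the embedding).
#'
#' @param m binary matrix (strains x groups), e.g. [build_pa_matrix()].
#' @param method `"mds"` or `"graph"`.
#' @param n_neighbors neighbourhood size for the graph embedder.
#' @param min_cluster_size DBSCAN `minPts`.
#' @param eps DBSCAN radius; `NULL` for the heuristic.
#' @param seed integer seed (the graph layout is stochastic; same seed, same
#'   embedding and labels).
#' @return object of class `strain_embedding`: data frame `strain`, `x`,
#'   `y`, `cluster` (-1 = noise), with parameter attributes.
#' @export
embed_and_cluster <- function(m, method = c("mds", "graph"), n_neighbors = 15,
                              min_cluster_size = 5, eps = NULL, seed = 1) {
  method <- match.arg(method)
  if (nrow(m) < 5) stop("need at least 5 strains")
  d <- stats::dist(m, method = "binary")  # Jaccard distance on binary rows
  set.seed(seed)
  if (method == "mds") {
    xy <- suppressWarnings(stats::cmdscale(d, k = 2))
    if (ncol(xy) < 2)  # degenerate (e.g. all rows identical)
      xy <- cbind(xy, matrix(0, nrow = nrow(m),
                             ncol = 2 - ncol(xy)))
    if (nrow(xy) == 0L) xy <- matrix(0, nrow = nrow(m), ncol = 2)
  } else {
    dm <- as.matrix(d)
    k <- min(n_neighbors, nrow(m) - 1L)
    edges <- do.call(rbind, lapply(seq_len(nrow(dm)), function(i) {
      nb <- order(dm[i, -i])[seq_len(k)]
      nb <- setdiff(seq_len(nrow(dm))[-i][nb], i)
      cbind(i, nb, w = 1 - dm[i, nb])
    }))
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE,
      vertices = data.frame(name = seq_len(nrow(dm))))
    g <- igraph::simplify(g)
    xy <- igraph::layout_with_fr(g, weights = rep(1, igraph::ecount(g)))
  }
  rownames(xy) <- rownames(m)
  de <- stats::dist(xy)
  if (is.null(eps)) eps <- eps_heuristic(de, min_cluster_size)
  labels <- dbscan_labels(de, eps, min_cluster_size)
  out <- data.frame(strain = rownames(m), x = xy[, 1], y = xy[, 2],
                    cluster = labels, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "eps") <- eps
  attr(out, "min_cluster_size") <- min_cluster_size
  attr(out, "seed") <- seed
  class(out) <- c("strain_embedding", "data.frame")
  out
}

#' Cluster size summary of a strain embedding
#'
#' @param emb a `strain_embedding`.
#' @return data frame `cluster`, `n_strains` (noise = -1), largest first.
#' @export
cluster_sizes <- function(emb) {
  t0 <- table(emb$cluster)
  out <- data.frame(cluster = as.integer(names(t0)),
                    n_strains = as.integer(t0))
  out[order(-out$n_strains), , drop = FALSE]
}
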