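# Independent oracles, deliberately naive: a full-matrix affine-gap
# Smith-Waterman with traceback, a stack-based DFS for connected components,
# and an exhaustive accumulation-curve enumerator. These are written against
# the textbook definitions, not against the package internals.

blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Affine gaps: a gap of length g costs open + g * ext (NCBI convention).
# Returns NULL when no positive-scoring local alignment exists.
sw_oracle <- function(a, b, mat = blosum62_matrix, open = 11, ext = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (consumes B)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in B (consumes A)
  best <- 0; bi <- 0; bj <- 0
  for (i in 2:(n + 1)) {
    si <- mat[A[i - 1], ]
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + si[B[j - 1]], E[i, j], F[i, j])
      if (H[i, j] > best) { best <- H[i, j]; bi <- i; bj <- j }
    }
  }
  if (best <= 0) return(NULL)
  # traceback (diagonal preferred on ties, then E, then F)
  i <- bi; j <- bj; state <- "H"
  matches <- 0L; alen <- 0L
  qend <- bi - 1L; send <- bj - 1L
  repeat {
    if (state == "H") {
      if (H[i, j] == 0) break
      diag <- H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]]
      if (i > 1 && j > 1 && H[i, j] == diag) {
        matches <- matches + (A[i - 1] == B[j - 1])
        alen <- alen + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      alen <- alen + 1L
      from_h <- E[i, j] == H[i, j - 1] - open - ext
      j <- j - 1L
      if (from_h) state <- "H"
    } else {
      alen <- alen + 1L
      from_h <- F[i, j] == H[i - 1, j] - open - ext
      i <- i - 1L
      if (from_h) state <- "H"
    }
  }
  qstart <- i; sstart <- j
  list(score = best,
       percent_identity = 100 * matches / alen,
       alignment_length = alen,
       query_coverage = (qend - qstart + 1) / n,
       subject_coverage = (send - sstart + 1) / m,
       query_range = c(qstart, qend),
       subject_range = c(sstart, send))
}

# qualifying unordered pairs of a protein set under the orthologue criteria,
# by exhaustive oracle alignment (E-value ignored: the oracle checks the
# identity/coverage criteria, which dominate at these thresholds; callers
# pass max_evalue = Inf to the package for a like-for-like comparison)
oracle_qualifying_pairs <- function(proteins, min_identity = 80,
                                    min_cov = 0.70) {
  ids <- sort(proteins$protein_id)
  seqs <- proteins$sequence[match(ids, proteins$protein_id)]
  out <- character(0)
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (i + 1):length(ids)) {
      al <- sw_oracle(seqs[i], seqs[j])
      if (is.null(al)) next
      if (al$percent_identity >= min_identity &&
          min(al$query_coverage, al$subject_coverage) >= min_cov) {
        out <- c(out, paste(ids[i], ids[j]))
      }
    }
  }
  sort(out)
}

# stack-based depth-first search over an adjacency list
dfs_components <- function(n_nodes, edges) {
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, n_nodes)
  cur <- 0L
  for (s in seq_len(n_nodes)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      stack <- c(stack, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  comp
}

# exhaustive accumulation curves: every ordering of the genomes, counted
# directly from per-genome group sets
exhaustive_curves <- function(group_sets, soft = 0.95) {
  genomes <- names(group_sets)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  out <- list()
  for (ord in perms(genomes)) {
    for (k in seq_along(ord)) {
      sets <- group_sets[ord[1:k]]
      all_g <- unique(unlist(sets))
      cnt <- vapply(all_g, function(g)
        sum(vapply(sets, function(s) g %in% s, logical(1))), numeric(1))
      out[[length(out) + 1]] <- data.frame(
        ordering = paste(ord, collapse = ""), k = k,
        pangenome = length(all_g),
        strict_core = sum(cnt == k),
        soft_core = sum(cnt >= ceiling(soft * k)))
    }
  }
  do.call(rbind, out)
}

# bin index of a prevalence fraction under 20 left-open right-closed 5% bins,
# computed by direct interval membership
conservation_bin_oracle <- function(frac) {
  lows <- seq(0, 0.95, by = 0.05)
  highs <- seq(0.05, 1, by = 0.05)
  which(frac - lows > 1e-12 & frac - highs <= 1e-12)[1]
}
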