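#' Orthologue qualification criteria
#'
#' Thresholds a directed similarity hit must meet to count as orthologue
#' evidence. Defaults follow the stringent criteria used for *Streptomyces*
#' pangenome construction: alignment identity of at least 80% covering at
#' least 70% of *both* protein sequences, at an E-value below 1e-5. Identity
#' and coverage thresholds are inclusive (`>=`); the E-value threshold is
#' strict (`<`).
#'
#' @param min_identity minimum percent identity (0-100), inclusive.
#' @param min_coverage_both minimum alignment coverage, as a fraction, that
#'   must be reached on both the query and the subject, inclusive.
#' @param max_evalue E-value bound, strict.
#' @return object of class `orthologue_criteria`.
#' @export
orthologue_criteria <- function(min_identity = 80, min_coverage_both = 0.70,
                                max_evalue = 1e-5) {
  if (min_identity < 0 || min_identity > 100)
    stop_config("min_identity must be in [0, 100]")
  if (min_coverage_both <= 0 || min_coverage_both > 1)
    stop_config("min_coverage_both must be in (0, 1]")
  if (max_evalue < 0) stop_config("max_evalue must be >= 0")
  structure(list(min_identity = min_identity,
                 min_coverage_both = min_coverage_both,
                 max_evalue = max_evalue),
            class = "orthologue_criteria")
}

#' Alignment scoring parameters
#'
#' BLOSUM62 with affine gaps costing `gap_open + g * gap_extend` for a gap of
#' length `g` (NCBI convention; the defaults 11/1 are the BLASTP defaults).
#' `karlin_k` and `karlin_lambda` are the Karlin-Altschul parameters used to
#' approximate E-values for the built-in aligner (values for gapped BLOSUM62
#' 11/1); E-values from ingested BLAST tables are taken as authoritative
#' instead.
#'
#' @param matrix substitution matrix name (a matrix shipped with Biostrings)
#'   or a numeric matrix.
#' @param gap_open gap existence cost (positive).
#' @param gap_extend per-residue gap extension cost (positive).
#' @param karlin_k,karlin_lambda Karlin-Altschul K and lambda.
#' @return object of class `align_scoring`.
#' @export
align_scoring <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                          karlin_k = 0.041, karlin_lambda = 0.267) {
  if (is.character(matrix)) {
    env <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = env)
    matrix <- get(matrix, envir = env)
  }
  stopifnot(is.matrix(matrix), gap_open > 0, gap_extend > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_k = karlin_k,
                 karlin_lambda = karlin_lambda),
            class = "align_scoring")
}

check_residues <- function(seq, alphabet, what) {
  res <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(res %in% alphabet))
  if (length(bad) > 0L)
    stop("invalid residue '", res[bad[1L]], "' at position ", bad[1L],
         " of ", what)
  invisible(TRUE)
}

# E-value and bit score from a raw Smith-Waterman score
karlin_evalue <- function(score, m, n, scoring) {
  scoring$karlin_k * m * n * exp(-scoring$karlin_lambda * score)
}
karlin_bits <- function(score, scoring) {
  (scoring$karlin_lambda * score - log(scoring$karlin_k)) / log(2)
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under [align_scoring()]. Percent identity is the
#' number of identical aligned columns divided by the full alignment length
#' (gap columns included in the denominator — the BLAST `pident` convention).
#' Coverage is the aligned span on each sequence divided by its full length.
#'
#' @param query,subject amino-acid strings (non-empty, residues must be in
#'   the scoring matrix alphabet).
#' @param scoring an [align_scoring()].
#' @return `NULL` if no positive-scoring local alignment exists; otherwise a
#'   list with `score`, `bitscore`, `evalue`, `percent_identity`,
#'   `alignment_length`, `query_coverage`, `subject_coverage`,
#'   `query_range`, `subject_range`.
#' @examples
#' local_align("PELICAN", "PELICAN")$percent_identity  # 100
#' @export
local_align <- function(query, subject, scoring = align_scoring()) {
  if (!nzchar(query) || !nzchar(subject)) stop("sequences must be non-empty")
  alphabet <- rownames(scoring$matrix)
  check_residues(query, alphabet, "query")
  check_residues(subject, alphabet, "subject")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  s <- Biostrings::score(aln)
  if (s <= 0) return(NULL)
  alen <- Biostrings::nchar(aln)
  qr <- c(IRanges::start(Biostrings::pattern(aln)),
          IRanges::end(Biostrings::pattern(aln)))
  sr <- c(IRanges::start(Biostrings::subject(aln)),
          IRanges::end(Biostrings::subject(aln)))
  list(score = s,
       bitscore = karlin_bits(s, scoring),
       evalue = karlin_evalue(s, nchar(query), nchar(subject), scoring),
       percent_identity = 100 * Biostrings::nmatch(aln) / alen,
       alignment_length = alen,
       query_coverage = (qr[2] - qr[1] + 1) / nchar(query),
       subject_coverage = (sr[2] - sr[1] + 1) / nchar(subject),
       query_range = qr, subject_range = sr)
}

# unique k-mers of each sequence as a list of character vectors
seq_kmers <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  })
}

# candidate unordered pairs (i < j) sharing >= min_shared exact k-mers,
# via a sparse sequence-by-kmer incidence matrix
kmer_candidate_pairs <- function(seqs, k, min_shared) {
  km <- seq_kmers(seqs, k)
  all_k <- unique(unlist(km))
  if (length(all_k) == 0L) return(cbind(i = integer(0), j = integer(0)))
  j <- match(unlist(km), all_k)
  i <- rep(seq_along(km), lengths(km))
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(seqs), length(all_k)))
  S <- Matrix::tcrossprod(M)
  tr <- Matrix::summary(S)
  keep <- tr$i < tr$j & tr$x >= min_shared
  cbind(i = tr$i[keep], j = tr$j[keep])
}

#' All-vs-all protein similarity search
#'
#' Computes directed pairwise similarity hits for every pair of proteins,
#' optionally prefiltered to pairs sharing at least `min_shared_kmers` exact
#' k-mers (alignment is symmetric here, so each unordered pair is aligned
#' once and reported in both directions with coverages swapped). Self pairs
#' are never reported. Output rows are ordered lexicographically by
#' `(query_id, subject_id)`.
#'
#' @param proteins data frame with columns `protein_id`, `genome_id`,
#'   `sequence` (a `synthetic_pangenome` is also accepted).
#' @param scoring an [align_scoring()].
#' @param prefilter use the k-mer prefilter (`TRUE`) or align every pair.
#' @param k k-mer length for the prefilter.
#' @param min_shared_kmers minimum shared distinct k-mers for a candidate pair.
#' @return data frame of hits: `query_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `query_coverage`, `subject_coverage`, `evalue`,
#'   `bitscore`.
#' @export
all_vs_all <- function(proteins, scoring = align_scoring(), prefilter = TRUE,
                       k = 5, min_shared_kmers = 2) {
  if (inherits(proteins, "synthetic_pangenome")) proteins <- proteins$proteins
  stopifnot(all(c("protein_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein_id in input")
  ord <- order(proteins$protein_id)
  ids <- proteins$protein_id[ord]
  seqs <- proteins$sequence[ord]
  n <- length(seqs)
  pairs <- if (prefilter) {
    kmer_candidate_pairs(seqs, k, min_shared_kmers)
  } else {
    idx <- which(upper.tri(matrix(NA_integer_, n, n)), arr.ind = TRUE)
    cbind(i = idx[, "row"], j = idx[, "col"])
  }
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0),
                      alignment_length = integer(0),
                      query_coverage = numeric(0),
                      subject_coverage = numeric(0),
                      evalue = numeric(0), bitscore = numeric(0))
  if (nrow(pairs) == 0L) return(empty)

  lens <- nchar(seqs)
  aaset <- Biostrings::AAStringSet(seqs)
  out <- vector("list", 0L)
  # element-wise batches: chunked to bound peak memory of the alignment set
  chunk <- 20000L
  starts <- seq(1L, nrow(pairs), by = chunk)
  for (st in starts) {
    sel <- st:min(st + chunk - 1L, nrow(pairs))
    ii <- pairs[sel, "i"]; jj <- pairs[sel, "j"]
    aln <- Biostrings::pairwiseAlignment(
      aaset[ii], aaset[jj], type = "local",
      substitutionMatrix = scoring$matrix,
      gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
    sc <- Biostrings::score(aln)
    keep <- sc > 0
    if (!any(keep)) next
    aln <- aln[keep]; ii <- ii[keep]; jj <- jj[keep]; sc <- sc[keep]
    alen <- Biostrings::nchar(aln)
    qs <- IRanges::start(Biostrings::pattern(aln))
    qe <- IRanges::end(Biostrings::pattern(aln))
    ss <- IRanges::start(Biostrings::subject(aln))
    se <- IRanges::end(Biostrings::subject(aln))
    pid <- 100 * Biostrings::nmatch(aln) / alen
    covq <- (qe - qs + 1) / lens[ii]
    covs <- (se - ss + 1) / lens[jj]
    ev <- karlin_evalue(sc, lens[ii], lens[jj], scoring)
    bits <- karlin_bits(sc, scoring)
    out[[length(out) + 1L]] <- data.frame(
      query_id = c(ids[ii], ids[jj]),
      subject_id = c(ids[jj], ids[ii]),
      percent_identity = c(pid, pid),
      alignment_length = c(alen, alen),
      query_coverage = c(covq, covs),
      subject_coverage = c(covs, covq),
      evalue = c(ev, ev), bitscore = c(bits, bits),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$query_id, hits$subject_id), ]
  rownames(hits) <- NULL
  hits
}

#' Read a tabular BLAST hit file
#'
#' Parses tab-separated BLAST output (`-outfmt 6` dialects). Coverage of each
#' side is `(end - start + 1) / length`, so the query/subject length columns
#' are mandatory: a 12-column file without `qlen`/`slen` cannot express the
#' dual-coverage orthologue criterion and is rejected. Self hits
#' (`query == subject`) are skipped and counted in the `skipped_self`
#' attribute. File E-values are authoritative.
#'
#' @param path file path.
#' @param dialect `"qlen_slen"` (the standard 12 columns plus `qlen` and
#'   `slen`) or `"std12"` (rejected with a configuration error).
#' @return hit data frame as in [all_vs_all()], with attribute
#'   `skipped_self`.
#' @export
read_blast_tab <- function(path, dialect = c("qlen_slen", "std12")) {
  dialect <- match.arg(dialect)
  if (dialect == "std12")
    stop_config("dialect 'std12' lacks qlen/slen columns; coverage cannot ",
                "be computed. Re-run BLAST with ",
                "-outfmt '6 std qlen slen'.")
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore",
            "qlen", "slen")
  num <- setdiff(cols, c("qseqid", "sseqid"))
  df <- read_tsv_strict(path, cols, numeric_cols = num, header = FALSE)
  self <- df$qseqid == df$sseqid
  df <- df[!self, , drop = FALSE]
  hits <- data.frame(
    query_id = df$qseqid, subject_id = df$sseqid,
    percent_identity = df$pident,
    alignment_length = as.integer(df$length),
    query_coverage = (df$qend - df$qstart + 1) / df$qlen,
    subject_coverage = (abs(df$send - df$sstart) + 1) / df$slen,
    evalue = df$evalue, bitscore = df$bitscore,
    stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  attr(hits, "skipped_self") <- sum(self)
  hits
}

#' Does a similarity hit qualify as orthologue evidence?
#'
#' Vectorised over the rows of a hit table: `TRUE` iff
#' `evalue < max_evalue`, `percent_identity >= min_identity` and
#' `min(query_coverage, subject_coverage) >= min_coverage_both`.
#'
#' @param hits hit data frame (columns as produced by [all_vs_all()]).
#' @param criteria an [orthologue_criteria()].
#' @return logical vector, one element per hit row.
#' @export
hit_passes <- function(hits, criteria = orthologue_criteria()) {
  stopifnot(inherits(criteria, "orthologue_criteria"))
  hits$evalue < criteria$max_evalue &
    hits$percent_identity >= criteria$min_identity &
    pmin(hits$query_coverage, hits$subject_coverage) >= criteria$min_coverage_both
}
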