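#' Round half away from zero
#'
#' Fixed-point rounding in which ties go up (`0.45 -> 0.5` at one decimal),
#' matching how percentages are conventionally printed in comparative-genomics
#' reports. Base [round()] uses banker's rounding and would print e.g. 0.4 for
#' 0.45.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards values like 51.2 stored as 51.19999...
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' The 20 standard amino acids
#' @return character vector of one-letter residue codes.
#' @export
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# stop() with a class so callers/tests can distinguish configuration errors
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("streptopan_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Strict TSV reader: every row must have exactly length(col_names) fields;
# numeric columns must parse. Errors carry 1-based line numbers (header = line 1
# when header = TRUE).
read_tsv_strict <- function(path, col_names, numeric_cols = character(),
                            header = TRUE) {
  lines <- readLines(path)
  offset <- 0L
  if (header) {
    if (length(lines) == 0L) stop("empty file: ", path)
    hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (!identical(hdr, col_names)) {
      stop_config(path, ": header mismatch; expected '",
                  paste(col_names, collapse = "\t"), "'")
    }
    lines <- lines[-1L]
    offset <- 1L
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(col_names)),
                                  col_names))
    for (nc in numeric_cols) out[[nc]] <- numeric(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(col_names))
  if (length(bad) > 0L) {
    stop(path, ": line ", bad[[1L]] + offset, ": expected ",
         length(col_names), " fields, found ", nf[[bad[[1L]]]])
  }
  m <- matrix(unlist(parts), ncol = length(col_names), byrow = TRUE)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- col_names
  for (nc in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[nc]]))
    badv <- which(is.na(v) & !is.na(out[[nc]]))
    if (length(badv) > 0L) {
      stop(path, ": line ", badv[[1L]] + offset, ": field '", nc,
           "' is not numeric ('", out[[nc]][badv[[1L]]], "')")
    }
    out[[nc]] <- v
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
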