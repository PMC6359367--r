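#' Levenshtein distance between nucleotide sequences
#'
#' The minimum number of single-character edits (insertions, deletions,
#' substitutions) transforming one sequence into the other, computed with a
#' banded dynamic program. `a` and `b` are compared element-wise.
#'
#' @param a,b character vectors of equal length.
#' @param cutoff optional non-negative integer; when given, any distance
#'   greater than `cutoff` is reported as `cutoff + 1` (the band plus early
#'   exit makes bounded queries much cheaper on long sequences).
#' @return integer vector of distances.
#' @examples
#' levenshtein("GCTAGC", "GATTAC")
#' @export
levenshtein <- function(a, b, cutoff = NULL) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  cut <- if (is.null(cutoff)) -1L else as.integer(cutoff)
  if (!is.null(cutoff) && cut < 0) stop("'cutoff' must be >= 0")
  .lev_dist_cpp(a, b, cut)
}

#' Enumerate all sequence pairs within an edit-distance threshold
#'
#' Returns exactly the pairs with `1 <= LD <= t`, equivalent to brute-force
#' all-vs-all comparison, but computed with length bucketing (pairs whose
#' length difference exceeds `t` are skipped) and banded early-exit distance
#' computation so the full distance matrix is never materialized.
#'
#' @param sequences character vector (or a `repertoire`, whose sequences are
#'   used); vertex ids in the output are positions in this vector.
#' @param t inclusive distance threshold, `>= 1`.
#' @return data.frame with columns `a`, `b` (vertex ids, `a < b`) and `ld`.
#' @export
ld_pairs <- function(sequences, t) {
  if (inherits(sequences, "repertoire")) sequences <- sequences$sequences
  t <- as.integer(t)
  if (t < 1) stop("'t' must be >= 1")
  .lev_pairs_cpp(as.character(sequences), t)
}

#' Write an edge list TSV
#'
#' @param pairs data.frame from [ld_pairs()] (columns `a`, `b`, `ld`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(pairs, path) {
  df <- pairs[order(pairs$a, pairs$b), c("a", "b", "ld")]
  names(df) <- c("vertex_id_a", "vertex_id_b", "ld")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
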