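#' Construct a repertoire collection
#'
#' A `repertoire` is the pooled, deduplicated set of unique VH nucleotide
#' sequences ("vertices") observed across an ordered series of time points,
#' with a per-vertex read count at every time point (zero-filled) and the
#' per-time-point read totals used to normalize clonal frequencies.
#'
#' @param sequences character vector of unique VH nucleotide sequences.
#' @param counts integer matrix, `length(sequences)` rows by one column per
#'   time point, of read counts. Column names, when present, must equal
#'   `timepoints`.
#' @param timepoints ordered character vector of time-point labels.
#' @return An object of class `repertoire`: a list with elements `timepoints`,
#'   `sequences`, `counts` (vertices x timepoints matrix), `totals`
#'   (per-time-point column sums) and optionally `hcdr3` (see
#'   [annotate_repertoire()]). Vertex ids are row indices (1-based).
#' @seealso [validate_repertoire()]
#' @export
new_repertoire <- function(sequences, counts, timepoints = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(timepoints)) stop("'timepoints' must be given when 'counts' has no column names")
  colnames(counts) <- timepoints
  storage.mode(counts) <- "integer"
  rep <- structure(
    list(timepoints = as.character(timepoints),
         sequences = as.character(sequences),
         counts = counts,
         totals = setNames(as.integer(colSums(counts)), timepoints)),
    class = "repertoire")
  validate_repertoire(rep)
  rep
}

#' Validate repertoire invariants
#'
#' Checks that sequences are unique, non-empty and over the `ACGT` alphabet,
#' that counts are non-negative with every vertex observed at least once, and
#' that `totals` equals the column sums of `counts`.
#'
#' @param rep a [new_repertoire()] object.
#' @return `rep`, invisibly; errors otherwise.
#' @export
validate_repertoire <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  n <- length(rep$sequences)
  if (nrow(rep$counts) != n) stop("counts must have one row per sequence")
  if (!identical(colnames(rep$counts), rep$timepoints))
    stop("counts columns must match timepoints")
  if (anyDuplicated(rep$sequences)) stop("sequences must be pairwise distinct")
  if (n > 0) {
    if (any(!nzchar(rep$sequences))) stop("empty sequence")
    if (any(grepl("[^ACGT]", rep$sequences))) stop("sequences must be over {A,C,G,T}")
    if (any(rep$counts < 0)) stop("negative read count")
    if (any(rowSums(rep$counts) == 0)) stop("every vertex needs at least one read")
  }
  if (!isTRUE(all.equal(as.numeric(unname(rep$totals)), unname(colSums(rep$counts)))))
    stop("totals do not match column sums")
  invisible(rep)
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("VH repertoire: %d unique sequences over %d time points (%s)\n",
              length(x$sequences), length(x$timepoints),
              paste(x$timepoints, collapse = ", ")))
  cat("reads per time point:",
      paste(sprintf("%s=%d", x$timepoints, x$totals), collapse = ", "), "\n")
  if (!is.null(x$hcdr3))
    cat(sprintf("HCDR3 annotated: %d/%d found\n",
                sum(x$hcdr3$status == "found"), length(x$sequences)))
  invisible(x)
}

#' @export
summary.repertoire <- function(object, ...) {
  print(object)
  lens <- nchar(object$sequences)
  cat(sprintf("sequence length: %d-%d (median %d)\n",
              min(lens), max(lens), as.integer(stats::median(lens))))
  shared <- rowSums(object$counts > 0)
  cat(sprintf("vertices seen at >1 time point: %d\n", sum(shared > 1)))
  invisible(object)
}

#' @export
as.data.frame.repertoire <- function(x, ...) {
  df <- data.frame(vertex_id = seq_along(x$sequences),
                   sequence = x$sequences,
                   stringsAsFactors = FALSE)
  cnt <- as.data.frame(x$counts)
  names(cnt) <- paste0("duplicate_count_", x$timepoints)
  cbind(df, cnt)
}

#' Read a preprocessed sequence table
#'
#' Bypasses FASTQ preprocessing: reads a TSV with columns `sequence`,
#' `timepoint` and optionally `count` (default 1 per row) and aggregates it
#' into a [new_repertoire()].
#'
#' @param path TSV path.
#' @param timepoints ordered time-point labels; defaults to order of first
#'   appearance in the file.
#' @return a `repertoire`.
#' @export
read_sequence_table <- function(path, timepoints = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "timepoint") %in% names(df)))
    stop("sequence table needs 'sequence' and 'timepoint' columns")
  if (is.null(df$count)) df$count <- 1L
  if (is.null(timepoints)) timepoints <- unique(df$timepoint)
  collect_repertoire(df, timepoints)
}

# Aggregate a long (sequence, timepoint, count) data.frame into a repertoire.
# Vertices ordered by descending total count, ties by sequence.
collect_repertoire <- function(df, timepoints) {
  if (nrow(df) == 0) {
    warning("empty input: returning empty repertoire")
    m <- matrix(integer(0), nrow = 0, ncol = length(timepoints),
                dimnames = list(NULL, timepoints))
    return(new_repertoire(character(0), m, timepoints))
  }
  if (!all(df$timepoint %in% timepoints))
    stop("timepoint label not in declared set: ",
         paste(setdiff(unique(df$timepoint), timepoints), collapse = ", "))
  seqs <- sort(unique(df$sequence))
  m <- matrix(0L, nrow = length(seqs), ncol = length(timepoints),
              dimnames = list(NULL, timepoints))
  i <- match(df$sequence, seqs)
  j <- match(df$timepoint, timepoints)
  for (k in seq_len(nrow(df))) m[i[k], j[k]] <- m[i[k], j[k]] + as.integer(df$count[k])
  ord <- order(-rowSums(m), seqs)
  new_repertoire(seqs[ord], m[ord, , drop = FALSE], timepoints)
}

#' Write a repertoire as an AIRR-flavoured wide TSV
#'
#' Columns: `sequence_id`, `sequence`, and `duplicate_count_<timepoint>` for
#' every declared time point.
#'
#' @param rep a `repertoire`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(rep, path) {
  df <- as.data.frame(rep)
  names(df)[1] <- "sequence_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
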