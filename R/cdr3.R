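#' Extract the HCDR3 peptide from VH nucleotide sequences
#'
#' Translates each sequence in a fixed reading frame and takes the residues
#' strictly between the conserved second cysteine (the last `C` preceding the
#' J anchor) and the J-anchor tryptophan of a `W-G-x-G` motif — the standard
#' junction anchors of the heavy-chain CDR3. No germline alignment is
#' attempted; trimmed amplicons are assumed in frame (the forward primer sits
#' in framework 1), with the frame configurable.
#'
#' @param sequences character vector of nucleotide sequences (length >= 9).
#' @param frame reading frame offset: 0, 1 or 2.
#' @return data.frame with one row per sequence: `frame`, `status` (`found`,
#'   `not_found`, or `stop_codon` for an internal stop before/within the
#'   junction), and `hcdr3_aa` (peptide, NA unless found).
#' @export
extract_hcdr3 <- function(sequences, frame = 0L) {
  frame <- as.integer(frame)
  stopifnot(frame %in% 0:2)
  if (length(sequences) && any(nchar(sequences) < 9))
    stop("sequences must be at least 9 nt long")
  sub <- substring(sequences, frame + 1L)
  sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(sub),
                                           if.fuzzy.codon = "X"))
  status <- rep("not_found", length(sequences))
  pep <- rep(NA_character_, length(sequences))
  for (i in seq_along(aa)) {
    w <- regexpr("WG.G", aa[i])[1]
    if (w < 0) next
    head_aa <- substr(aa[i], 1L, w)
    if (grepl("*", head_aa, fixed = TRUE)) {
      status[i] <- "stop_codon"
      next
    }
    cpos <- gregexpr("C", substr(head_aa, 1L, w - 1L), fixed = TRUE)[[1]]
    if (cpos[1] < 0) next
    cpos <- max(cpos)
    if (cpos + 1L > w - 1L) next  # empty junction
    cand <- substr(aa[i], cpos + 1L, w - 1L)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", cand)) next  # fuzzy/ambiguous residue
    status[i] <- "found"
    pep[i] <- cand
  }
  data.frame(frame = frame, status = status, hcdr3_aa = pep,
             stringsAsFactors = FALSE)
}

#' Annotate a repertoire with HCDR3 peptides
#'
#' Adds the [extract_hcdr3()] table (plus `vertex_id`) as element `hcdr3` of
#' the repertoire. Re-annotation is idempotent.
#'
#' @param rep a `repertoire`.
#' @param frame reading frame, see [extract_hcdr3()].
#' @return the annotated `repertoire`.
#' @export
annotate_repertoire <- function(rep, frame = 0L) {
  stopifnot(inherits(rep, "repertoire"))
  ann <- extract_hcdr3(rep$sequences, frame)
  rep$hcdr3 <- cbind(data.frame(vertex_id = seq_along(rep$sequences)), ann)
  rep
}

#' Per-component HCDR3 ratio
#'
#' Number of unique HCDR3 amino-acid sequences in a component divided by its
#' vertex count. A low ratio indicates a coherent clonal lineage (many related
#' transcripts sharing few CDR3 peptides); unrelated sequences lumped together
#' push the ratio toward 1. By default vertices without an extractable HCDR3
#' count in the denominator only.
#'
#' @param cc a [clonal_components()] object.
#' @param annotations HCDR3 annotation table with columns `vertex_id`,
#'   `status`, `hcdr3_aa` (e.g. `rep$hcdr3` after [annotate_repertoire()]).
#' @param include_unannotated if `FALSE`, the denominator is the number of
#'   annotated vertices instead of all vertices (components with none give
#'   `NA`).
#' @return named numeric vector: ratio in `[0, 1]` per `component_id`.
#' @export
hcdr3_ratio <- function(cc, annotations, include_unannotated = TRUE) {
  stopifnot(inherits(cc, "clonal_components"))
  comp_of <- cc$membership[annotations$vertex_id]
  found <- annotations$status == "found" & comp_of %in% cc$summary$component_id
  uniq <- vapply(split(annotations$hcdr3_aa[found], comp_of[found]),
                 function(x) length(unique(x)), integer(1))
  ids <- cc$summary$component_id
  u <- setNames(integer(length(ids)), ids)
  u[names(uniq)] <- uniq
  if (include_unannotated) {
    denom <- setNames(cc$summary$n_vertices, ids)
  } else {
    nf <- table(factor(comp_of[found], levels = ids))
    denom <- as.integer(nf)
    names(denom) <- ids
    denom[denom == 0] <- NA_integer_
  }
  u / denom
}

#' Write the HCDR3 annotation TSV
#'
#' @param rep an annotated `repertoire` (see [annotate_repertoire()]).
#' @param path output path (columns `vertex_id`, `frame`, `status`,
#'   `hcdr3_aa`).
#' @return `path`, invisibly.
#' @export
write_hcdr3 <- function(rep, path) {
  if (is.null(rep$hcdr3)) stop("repertoire is not HCDR3-annotated")
  utils::write.table(rep$hcdr3, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
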