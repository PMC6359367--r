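#' Primer pair for VH amplicon trimming
#'
#' Defaults are the VH amplification primers used for the chicken
#' immunization time course this package was designed around.
#'
#' @param forward forward primer (5'->3', matched at the read 5' end).
#' @param reverse reverse primer (5'->3'; matched as its reverse complement at
#'   the read 3' end).
#' @param max_mismatches maximum Hamming mismatches tolerated per primer.
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(forward = "ACTCAGCCGTCCTCGGTGTC",
                        reverse = "ACTGACCTAGGACGGTCAGG",
                        max_mismatches = 2L) {
  stopifnot(nzchar(forward), nzchar(reverse), max_mismatches >= 0)
  structure(list(forward = toupper(forward), reverse = toupper(reverse),
                 max_mismatches = as.integer(max_mismatches)),
            class = "primer_pair")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

str_rev <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Locate and trim primers from merged amplicon reads
#'
#' Each read is oriented forward-primer-first: the forward primer is searched
#' by sliding Hamming match within a window at the 5' end and the reverse
#' primer (as reverse complement) within a window at the 3' end. Reads where
#' either primer is absent at `<= max_mismatches` in both orientations are
#' rejected (counted, not an error).
#'
#' @param sequences character vector of read sequences over `{A,C,G,T,N}`.
#' @param qualities optional character vector of Phred+33 quality strings,
#'   same lengths as `sequences`.
#' @param primers a [primer_pair()].
#' @param window number of start offsets examined at each read end.
#' @return a data.frame with one row per input read: `sequence` and
#'   `qualities` of the trimmed insert (NA when rejected), `orientation`
#'   (`"+"`, `"-"`, or NA) and logical `kept`.
#' @export
annotate_primers <- function(sequences, qualities = NULL,
                             primers = primer_pair(), window = 10L) {
  stopifnot(inherits(primers, "primer_pair"))
  sequences <- toupper(sequences)
  if (any(grepl("[^ACGTN]", sequences)))
    stop("malformed nucleotide alphabet: reads must be over {A,C,G,T,N}")
  if (!is.null(qualities) && any(nchar(qualities) != nchar(sequences)))
    stop("quality strings must match sequence lengths")
  fwd <- primers$forward
  rrc <- revcomp(primers$reverse)
  hit <- .primer_hits_cpp(sequences, fwd, rrc, primers$max_mismatches, as.integer(window))
  orientation <- ifelse(hit[, 1] >= 0 & hit[, 2] >= 0, "+", NA_character_)

  miss <- which(is.na(orientation))
  if (length(miss)) {
    rc <- revcomp(sequences[miss])
    hit2 <- .primer_hits_cpp(rc, fwd, rrc, primers$max_mismatches, as.integer(window))
    ok <- hit2[, 1] >= 0 & hit2[, 2] >= 0
    flip <- miss[ok]
    sequences[flip] <- rc[ok]
    if (!is.null(qualities)) qualities[flip] <- str_rev(qualities[flip])
    hit[flip, ] <- hit2[ok, , drop = FALSE]
    orientation[flip] <- "-"
  }

  kept <- !is.na(orientation)
  from <- hit[, 1] + nchar(fwd) + 1L
  to <- hit[, 2]  # 0-based start of rev-primer match == last insert base (1-based)
  bad <- kept & (to < from)  # primers overlap: no insert
  kept[bad] <- FALSE
  orientation[bad] <- NA_character_
  out_seq <- rep(NA_character_, length(sequences))
  out_seq[kept] <- substr(sequences[kept], from[kept], to[kept])
  out_q <- rep(NA_character_, length(sequences))
  if (!is.null(qualities)) out_q[kept] <- substr(qualities[kept], from[kept], to[kept])
  data.frame(sequence = out_seq, qualities = out_q,
             orientation = orientation, kept = kept, stringsAsFactors = FALSE)
}

#' Quality filter ("qXpY") for merged reads
#'
#' A read passes when at least a fraction `p` of its bases have Phred quality
#' `>= q`. The defaults (`q = 20`, `p = 1`) express the "q20p100" rule: every
#' base at Q20 or better. Ambiguous bases (`N`) are treated as quality 0, so
#' any `N` fails a read under the default.
#'
#' @param qualities character vector of Phred+33 quality strings.
#' @param sequences optional read sequences, used to zero out `N` bases.
#' @param q minimum per-base Phred score.
#' @param p minimum fraction of bases meeting `q`.
#' @return logical vector: pass/fail per read.
#' @export
quality_filter <- function(qualities, sequences = NULL, q = 20L, p = 1.0) {
  stopifnot(q >= 0, p >= 0, p <= 1)
  n <- length(qualities)
  pass <- logical(n)
  for (i in seq_len(n)) {
    ph <- utf8ToInt(qualities[i]) - 33L
    if (!is.null(sequences)) {
      ch <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
      ph[ch == "N"] <- 0L
    }
    pass[i] <- mean(ph >= q) >= p
  }
  pass
}

#' Greedy abundance-ranked error correction
#'
#' Within each time point, reads are deduplicated to (sequence, count) and
#' visited in descending count (ties broken lexicographically by sequence). A
#' sequence is absorbed into a previously retained sequence when their
#' Levenshtein distance is `<= ld_merge` and its count divided by the parent's
#' current (accumulated) count is `<= ratio`; absorbed counts are added to the
#' parent, so read mass is conserved. Survivors are merged across time points
#' by exact sequence identity into one vertex with per-time-point counts.
#'
#' This is a deliberately simple, documented stand-in for hierarchical-
#' clustering error correctors; externally corrected tables can be supplied
#' instead via [read_sequence_table()].
#'
#' @param reads data.frame with columns `sequence`, `timepoint` and optionally
#'   `count` (default 1 per row).
#' @param timepoints ordered time-point labels.
#' @param ld_merge maximum edit distance for absorption.
#' @param ratio maximum child/parent count ratio for absorption.
#' @return a [new_repertoire()].
#' @export
error_correct <- function(reads, timepoints, ld_merge = 1L, ratio = 0.1) {
  stopifnot(ld_merge >= 0, ratio >= 0)
  if (nrow(reads) == 0)
    return(collect_repertoire(reads[, c("sequence", "timepoint"), drop = FALSE], timepoints))
  if (is.null(reads$count)) reads$count <- 1L
  out <- vector("list", length(timepoints))
  for (ti in seq_along(timepoints)) {
    tp <- timepoints[ti]
    sub <- reads[reads$timepoint == tp, , drop = FALSE]
    if (nrow(sub) == 0) next
    cnt <- tapply(as.integer(sub$count), sub$sequence, sum)
    seqs <- names(cnt)
    cnt <- as.integer(cnt)
    ord <- order(-cnt, seqs)
    seqs <- seqs[ord]; cnt <- cnt[ord]
    k <- length(seqs)
    retained <- logical(k)
    if (ld_merge >= 1 && k > 1) {
      prs <- .lev_pairs_cpp(seqs, as.integer(ld_merge))
      # adjacency by visiting order; a < b in visiting order after remap
      adj <- vector("list", k)
      if (nrow(prs)) {
        lo <- pmin(prs$a, prs$b); hi <- pmax(prs$a, prs$b)
        for (e in seq_along(lo)) adj[[hi[e]]] <- c(adj[[hi[e]]], lo[e])
      }
      for (i in seq_len(k)) {
        parents <- adj[[i]]
        parents <- parents[retained[parents]]
        absorbed <- FALSE
        if (length(parents)) {
          parents <- sort(parents)  # earliest visit = highest count, tie lex
          for (pp in parents) {
            if (cnt[i] / cnt[pp] <= ratio) {
              cnt[pp] <- cnt[pp] + cnt[i]
              absorbed <- TRUE
              break
            }
          }
        }
        if (!absorbed) retained[i] <- TRUE
      }
    } else {
      retained[] <- TRUE
    }
    out[[ti]] <- data.frame(sequence = seqs[retained], timepoint = tp,
                            count = cnt[retained], stringsAsFactors = FALSE)
  }
  collect_repertoire(do.call(rbind, out), timepoints)
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(read_id = names(x),
             sequence = as.character(x),
             qualities = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' Preprocess FASTQ reads into a deduplicated repertoire
#'
#' Runs primer annotation/trimming, quality filtering and greedy error
#' correction over one FASTQ file (gzip-transparent, pre-merged reads) per
#' time point.
#'
#' @param files named character vector: time-point label -> FASTQ path. The
#'   order of names defines the time-point order.
#' @param primers a [primer_pair()].
#' @param q,p quality-filter parameters, see [quality_filter()].
#' @param ld_merge,ratio error-correction parameters, see [error_correct()].
#' @param window primer search window, see [annotate_primers()].
#' @return list with `repertoire` (a [new_repertoire()]) and `report`: per
#'   time point, reads in, primer-rejected, quality-failed, passed, unique
#'   after dedup and unique after correction.
#' @export
preprocess_reads <- function(files, primers = primer_pair(), q = 20L, p = 1.0,
                             ld_merge = 1L, ratio = 0.1, window = 10L) {
  if (is.null(names(files)) || any(!nzchar(names(files))))
    stop("'files' must be named by time-point label")
  timepoints <- names(files)
  rows <- vector("list", length(files))
  report <- list()
  for (ti in seq_along(files)) {
    tp <- timepoints[ti]
    fq <- read_fastq(files[[ti]])
    ann <- annotate_primers(fq$sequence, fq$qualities, primers, window)
    n_rej <- sum(!ann$kept)
    keep <- ann$kept
    qpass <- rep(FALSE, nrow(ann))
    if (any(keep))
      qpass[keep] <- quality_filter(ann$qualities[keep], ann$sequence[keep], q, p)
    passed <- keep & qpass
    rows[[ti]] <- data.frame(sequence = ann$sequence[passed],
                             timepoint = rep(tp, sum(passed)),
                             count = rep(1L, sum(passed)),
                             stringsAsFactors = FALSE)
    report[[tp]] <- list(reads_in = nrow(fq),
                         primer_rejected = n_rej,
                         quality_failed = sum(keep) - sum(passed),
                         passed = sum(passed),
                         unique_raw = length(unique(ann$sequence[passed])))
  }
  reads <- do.call(rbind, rows)
  rep <- error_correct(reads, timepoints, ld_merge = ld_merge, ratio = ratio)
  for (tp in timepoints)
    report[[tp]]$unique_corrected <- sum(rep$counts[, tp] > 0)
  list(repertoire = rep, report = report)
}
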