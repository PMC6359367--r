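NT <- c("A", "C", "G", "T")

# Codons over which random CDR3 positions are drawn: no stop (TAA/TAG/TGA),
# no Cys (TGT/TGC) and no Trp (TGG), so simulated junctions never break the
# anchor rule used for extraction.
codon_table <- function() {
  all <- as.vector(outer(outer(NT, NT, paste0), NT, paste0))
  setdiff(all, c("TAA", "TAG", "TGA", "TGT", "TGC", "TGG"))
}

# Deterministic germline backbone (chicken-like single functional V): cycled
# framework codons without Cys/Trp/stop, the conserved YYC, a CDR3 window of
# cdr3_len codons, the WGQG J anchor, and a short tail.
sim_germline <- function(founder_length = 350L, cdr3_len = 12L) {
  n_codons <- founder_length %/% 3L
  rem <- founder_length - 3L * n_codons
  fw_pool <- c("GCT", "GAA", "TCT", "GGT", "AAA", "CTG", "GTT", "ACC", "GAC",
               "TTC", "CCT", "ATG", "CAT", "AGA", "AAC", "ATC", "TAC", "CAG")
  n_fr1 <- n_codons - (3L + cdr3_len + 4L + 2L)
  if (n_fr1 < 4) stop("founder_length too short for the germline layout")
  fr1 <- fw_pool[(seq_len(n_fr1) - 1L) %% length(fw_pool) + 1L]
  cdr3 <- rep("GCT", cdr3_len)  # germline junction; founders randomize it
  codons <- c(fr1, c("TAT", "TAT", "TGC"), cdr3,
              c("TGG", "GGC", "CAA", "GGC"), c("ACC", "CTG"))
  seq <- paste(codons, collapse = "")
  tail_nt <- c("", "G", "GA")[rem + 1L]
  list(sequence = paste0(seq, tail_nt),
       cdr3_nt = 3L * n_fr1 + 9L + seq_len(3L * cdr3_len),  # nt positions of the window
       anchor_nt = c(3L * n_fr1 + seq_len(9L),              # YYC codons
                     3L * (n_fr1 + 3L + cdr3_len) + seq_len(12L)))  # WGQG codons
}

substitute_at <- function(seq, pos, new) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ch[pos] <- new
  paste(ch, collapse = "")
}

mutate_positions <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(NT, ch[p]), 1L)
  paste(ch, collapse = "")
}

# Point substitutions that never create an in-frame stop codon (frame 0):
# simulated transcripts are functional antibodies, so biological mutations
# (founder divergence, SHM/gene-conversion daughters) are stop-free;
# sequencing errors, applied separately, have no such constraint.
mutate_positions_coding <- function(seq, pos) {
  stops <- c("TAA", "TAG", "TGA")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_codon <- length(ch) %/% 3L
  for (p in pos) {
    alt <- sample(setdiff(NT, ch[p]))
    ci <- (p - 1L) %/% 3L
    for (a in alt) {
      old <- ch[p]
      ch[p] <- a
      if (ci >= n_codon ||
          !(paste(ch[(3L * ci + 1L):(3L * ci + 3L)], collapse = "") %in% stops))
        break
      ch[p] <- old
    }
  }
  paste(ch, collapse = "")
}

#' Simulation configuration
#'
#' Defines an immunization time-course repertoire: `n_lineages` founder
#' lineages descended from one germline backbone, of which `n_expanded` are
#' antigen-reactive and expand `expansion_factor`-fold in read share (and gain
#' `n_novel_daughters` new variants) by the last time point. Founders diverge
#' mainly in a designated CDR3 window plus scattered framework substitutions,
#' with pairwise distance at least `inter_lineage_floor`; daughters carry
#' 1..`intra_lineage_mutations` point mutations, biased away from the CDR3
#' window (`cdr3_mutation_prob` per mutation), mirroring the low replacement
#' rate of HCDR3 under somatic hypermutation / gene conversion.
#'
#' Default read depths total 20,000 split across four time points in the
#' proportions of the study's sequencing runs.
#'
#' @param n_lineages number of founder lineages.
#' @param n_expanded number of expanded (antigen-reactive) lineages.
#' @param founder_length founder/germline length in nt.
#' @param intra_lineage_mutations maximal point edits per daughter (`d`).
#' @param inter_lineage_floor minimal Levenshtein distance between founders;
#'   must exceed `2 * intra_lineage_mutations` for separability.
#' @param expansion_factor read-share multiplier of expanded lineages at the
#'   last time point (geometric ramp over intermediate time points).
#' @param timepoints ordered labels.
#' @param reads_per_timepoint named integer vector of read depths.
#' @param error_rate per-base substitution error probability.
#' @param n_daughters daughters per lineage present from the first time point.
#' @param n_novel_daughters extra daughters gained by expanded lineages at
#'   later time points.
#' @param cdr3_mutation_prob probability that a daughter point mutation falls
#'   in the CDR3 window.
#' @param low_quality_fraction fraction of reads given one sub-threshold
#'   quality base (exercises the quality filter).
#' @param primers a [primer_pair()]; reads are emitted with primers attached.
#' @param seed RNG seed; all sampling is drawn from one global stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_lineages = 20L, n_expanded = 3L, founder_length = 350L,
                       intra_lineage_mutations = 4L, inter_lineage_floor = 40L,
                       expansion_factor = 10,
                       timepoints = c("wk0", "wk2", "wk4", "wk5"),
                       reads_per_timepoint = c(wk0 = 9246L, wk2 = 5686L,
                                               wk4 = 2528L, wk5 = 2540L),
                       error_rate = 0.001, n_daughters = 12L,
                       n_novel_daughters = 30L, cdr3_mutation_prob = 0.1,
                       low_quality_fraction = 0.005, primers = primer_pair(),
                       seed = 1L) {
  stopifnot(n_expanded <= n_lineages,
            inter_lineage_floor > 2 * intra_lineage_mutations,
            error_rate >= 0, error_rate <= 1,
            low_quality_fraction >= 0, low_quality_fraction <= 1,
            cdr3_mutation_prob >= 0, cdr3_mutation_prob <= 1,
            length(reads_per_timepoint) == length(timepoints))
  names(reads_per_timepoint) <- timepoints
  structure(list(n_lineages = as.integer(n_lineages),
                 n_expanded = as.integer(n_expanded),
                 founder_length = as.integer(founder_length),
                 intra_lineage_mutations = as.integer(intra_lineage_mutations),
                 inter_lineage_floor = as.integer(inter_lineage_floor),
                 expansion_factor = expansion_factor,
                 timepoints = as.character(timepoints),
                 reads_per_timepoint = setNames(as.integer(reads_per_timepoint),
                                                timepoints),
                 error_rate = error_rate,
                 n_daughters = as.integer(n_daughters),
                 n_novel_daughters = as.integer(n_novel_daughters),
                 cdr3_mutation_prob = cdr3_mutation_prob,
                 low_quality_fraction = low_quality_fraction,
                 primers = primers,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_founders <- function(config, germ) {
  n <- config$n_lineages
  codons <- codon_table()
  cdr3_starts <- germ$cdr3_nt[seq(1, length(germ$cdr3_nt), by = 3)]
  fw_pos <- setdiff(seq_len(nchar(germ$sequence)), c(germ$cdr3_nt, germ$anchor_nt))
  n_fw_mut <- max(0L, ceiling(config$inter_lineage_floor * 0.6))
  for (attempt in seq_len(20L)) {
    founders <- character(n)
    for (i in seq_len(n)) {
      s <- germ$sequence
      for (st in cdr3_starts)
        s <- substitute_at(s, st:(st + 2L), strsplit(sample(codons, 1L), "")[[1]])
      s <- mutate_positions_coding(s, sample(fw_pos, min(n_fw_mut, length(fw_pos))))
      founders[i] <- s
    }
    if (n < 2) return(founders)
    d <- .lev_pairs_cpp(founders, config$inter_lineage_floor - 1L)
    if (nrow(d) == 0) return(founders)  # no pair below the floor
  }
  stop("could not draw founders with the requested inter-lineage separation")
}

sim_daughter <- function(founder, germ, config) {
  m <- sample.int(config$intra_lineage_mutations, 1L)
  in_cdr3 <- stats::runif(m) < config$cdr3_mutation_prob
  fw_pos <- setdiff(seq_len(nchar(founder)), c(germ$cdr3_nt, germ$anchor_nt))
  pos <- integer(m)
  if (any(in_cdr3)) pos[in_cdr3] <- sample(germ$cdr3_nt, sum(in_cdr3))
  if (any(!in_cdr3)) pos[!in_cdr3] <- sample(fw_pos, sum(!in_cdr3))
  mutate_positions_coding(founder, pos)
}

#' Simulate an immunization time-course repertoire
#'
#' Generates FASTQ files (one per time point, reads with primers attached and
#' per-base qualities), a per-read ground-truth table and a lineage table, all
#' reproducible from the seed. See [sim_config()] for the generative model.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `fastq` (named paths), `truth` (data.frame: `read_id`,
#'   `timepoint`, `lineage`, `variant_id`, `expanded`, `sequence` — the
#'   observed, error-bearing insert), `lineages` (data.frame: `lineage`,
#'   `expanded`, `founder_sequence`), `germline`, `config`, and `dir`. The
#'   truth and lineage tables and the config JSON are also written to `dir`.
#' @export
simulate_repertoire <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  germ <- sim_germline(config$founder_length)
  founders <- sim_founders(config, germ)
  n_tp <- length(config$timepoints)
  expanded <- seq_len(config$n_lineages) <= config$n_expanded

  # variant pool: founder + daughters, each with a birth time point
  variants <- list()
  vid <- 0L
  for (l in seq_len(config$n_lineages)) {
    vid <- vid + 1L
    variants[[length(variants) + 1L]] <-
      data.frame(variant_id = vid, lineage = l, sequence = founders[l],
                 birth = 1L, weight = 3, stringsAsFactors = FALSE)
    n_extra <- if (expanded[l]) config$n_novel_daughters else 0L
    n_d <- config$n_daughters + n_extra
    births <- c(rep(1L, config$n_daughters),
                if (n_extra > 0 && n_tp > 1)
                  sort(sample(2:n_tp, n_extra, replace = TRUE)))
    if (n_d == 0L) next
    seqs <- character(n_d)
    for (k in seq_len(n_d)) {
      for (try in 1:10) {
        s <- sim_daughter(founders[l], germ, config)
        if (!(s %in% seqs) && s != founders[l]) break
      }
      seqs[k] <- s
    }
    variants[[length(variants) + 1L]] <-
      data.frame(variant_id = vid + seq_len(n_d), lineage = l, sequence = seqs,
                 birth = births, weight = 1, stringsAsFactors = FALSE)
    vid <- vid + n_d
  }
  variants <- do.call(rbind, variants)

  fwd <- config$primers$forward
  rev_attach <- revcomp(config$primers$reverse)
  fastq <- setNames(file.path(dir, paste0(config$timepoints, ".fastq")),
                    config$timepoints)
  truth <- vector("list", n_tp)
  width <- nchar(founders[1]) # substitutions only: all inserts equal length

  for (ti in seq_len(n_tp)) {
    n_reads <- config$reads_per_timepoint[ti]
    ramp <- if (n_tp > 1) (ti - 1) / (n_tp - 1) else 1
    lw <- ifelse(expanded, config$expansion_factor^ramp, 1)
    reads_l <- as.integer(stats::rmultinom(1, n_reads, lw))
    rows <- vector("list", config$n_lineages)
    for (l in seq_len(config$n_lineages)) {
      if (reads_l[l] == 0) next
      pool <- variants[variants$lineage == l & variants$birth <= ti, , drop = FALSE]
      cnt <- as.integer(stats::rmultinom(1, reads_l[l], pool$weight))
      idx <- base::rep(seq_len(nrow(pool)), cnt)
      rows[[l]] <- data.frame(lineage = l, variant_id = pool$variant_id[idx],
                              sequence = pool$sequence[idx],
                              stringsAsFactors = FALSE)
    }
    reads <- do.call(rbind, rows)
    n <- nrow(reads)
    # per-base sequencing errors (substitutions) on the insert
    n_err <- stats::rbinom(n, width, config$error_rate)
    for (i in which(n_err > 0))
      reads$sequence[i] <- mutate_positions(reads$sequence[i],
                                            sample.int(width, n_err[i]))
    reads$read_id <- sprintf("%s_read%06d", config$timepoints[ti], seq_len(n))
    reads$timepoint <- config$timepoints[ti]
    reads$expanded <- expanded[reads$lineage]

    amplicon <- paste0(fwd, reads$sequence, rev_attach)
    qual <- strrep("I", nchar(amplicon))  # Q40
    n_lq <- stats::rbinom(1, n, config$low_quality_fraction)
    if (n_lq > 0) {
      which_lq <- sample.int(n, n_lq)
      for (i in which_lq) {
        p <- sample.int(nchar(qual[i]), 1L)
        substr(qual[i], p, p) <- "+"  # Q10
      }
    }
    writeLines(paste0("@", reads$read_id, "\n", amplicon, "\n+\n", qual),
               fastq[ti])
    truth[[ti]] <- reads[, c("read_id", "timepoint", "lineage", "variant_id",
                             "expanded", "sequence")]
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  lineages <- data.frame(lineage = seq_len(config$n_lineages),
                         expanded = expanded,
                         founder_sequence = founders,
                         stringsAsFactors = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(lineages, file.path(dir, "lineages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$primers <- unclass(cfg$primers)
  jsonlite::write_json(unclass(cfg), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fastq = fastq, truth = truth, lineages = lineages,
       germline = germ$sequence, config = config, dir = dir)
}

#' Lineage recovery of a clustering against simulation truth
#'
#' Maps every repertoire vertex to a true lineage by majority vote over the
#' simulated reads carrying exactly its sequence, then scores the component
#' partition against the lineage labels with the adjusted Rand index.
#'
#' @param cc a [clonal_components()] object.
#' @param rep the matching `repertoire`.
#' @param truth the per-read truth table from [simulate_repertoire()].
#' @return list with `ari`, `n_matched` (vertices with a truth label),
#'   `vertex_lineage` (per-vertex label, NA when unmatched) and
#'   `lineage_component` (data.frame mapping each true lineage to the
#'   component holding most of its vertices).
#' @export
lineage_recovery <- function(cc, rep, truth) {
  stopifnot(inherits(cc, "clonal_components"), inherits(rep, "repertoire"))
  tab <- table(truth$sequence, truth$lineage)
  lab <- as.integer(colnames(tab))[max.col(tab, ties.method = "first")]
  vertex_lineage <- lab[match(rep$sequences, rownames(tab))]
  ok <- !is.na(vertex_lineage)
  ari <- mclust::adjustedRandIndex(cc$membership[ok], vertex_lineage[ok])
  lc <- vapply(split(cc$membership[ok], vertex_lineage[ok]), function(m) {
    tt <- table(m)
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
  list(ari = ari, n_matched = sum(ok), vertex_lineage = vertex_lineage,
       lineage_component = data.frame(lineage = as.integer(names(lc)),
                                      component_id = as.integer(lc)))
}
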