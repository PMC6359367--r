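# Shared fixtures, all built in code.

rand_dna <- function(n, len_min = 1, len_max = 50) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(len_min:len_max, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

# tiny two-timepoint repertoire with hand-chosen counts
toy_repertoire <- function() {
  new_repertoire(
    sequences = c("AAAAAA", "AAAAAT", "CCCCCC", "GGGGGG"),
    counts = matrix(c(5L, 3L, 2L, 0L,
                      0L, 2L, 4L, 4L), ncol = 2,
                    dimnames = list(NULL, c("wk0", "wk5"))),
    timepoints = c("wk0", "wk5"))
}

# nucleotide sequence encoding a given peptide (simple reverse translation)
nt_for <- function(peptide) {
  map <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC", G = "GGT",
           H = "CAT", I = "ATC", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
           P = "CCT", Q = "CAG", R = "AGA", S = "TCT", T = "ACC", V = "GTT",
           W = "TGG", Y = "TAT", "*" = "TAA")
  paste(map[strsplit(peptide, "")[[1]]], collapse = "")
}

# reference quality string from integer Phred scores
qual_str <- function(phred) intToUtf8(phred + 33L)

# preprocessed repertoire of the small simulation (computed once)
small_sim_rep <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- preprocess_reads(small_sim()$sim$fastq)$repertoire
    cache
  }
})

# small simulated study reused across tests (cheap: ~1.5k reads)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_lineages = 6, n_expanded = 2,
                        reads_per_timepoint = c(wk0 = 600, wk2 = 400,
                                                wk4 = 250, wk5 = 250),
                        n_daughters = 8, n_novel_daughters = 15, seed = 11)
      cache <<- list(config = cfg,
                     sim = simulate_repertoire(cfg, file.path(tempdir(), "vhnet_small_sim")))
    }
    cache
  }
})
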