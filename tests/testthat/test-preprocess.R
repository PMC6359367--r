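test_that("primer annotation trims, rejects and re-orients", {
  pr <- primer_pair("ACTCAGCCGTCC", "ACTGACCTAGGA", max_mismatches = 0L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  insert <- "ACGTACGT"
  read <- paste0(pr$forward, insert, rc(pr$reverse))
  ann <- annotate_primers(read, primers = pr)
  expect_true(ann$kept)
  expect_identical(ann$sequence, insert)

  # no primer occurrence within tolerance -> rejected, not an error
  ann2 <- annotate_primers(strrep("T", 60), primers = pr)
  expect_false(ann2$kept)
  expect_true(is.na(ann2$sequence))

  # reverse complement of the read re-orients to the same insert
  ann3 <- annotate_primers(rc(read), primers = pr)
  expect_true(ann3$kept)
  expect_identical(ann3$sequence, insert)
  expect_identical(ann3$orientation, "-")

  # qualities are trimmed (and reversed) alongside the bases
  qual <- qual_str(c(rep(30L, nchar(pr$forward)), 2:9 + 30L,
                     rep(30L, nchar(pr$reverse))))
  a4 <- annotate_primers(read, qual, primers = pr)
  expect_identical(a4$qualities, qual_str(2:9 + 30L))
  a5 <- annotate_primers(rc(read), intToUtf8(rev(utf8ToInt(qual))), primers = pr)
  expect_identical(a5$qualities, qual_str(2:9 + 30L))

  expect_error(annotate_primers("ACGTX", primers = pr), "alphabet")
})

test_that("primer matching tolerates mismatches up to the declared maximum", {
  pr <- primer_pair("ACTCAGCCGTCC", "ACTGACCTAGGA", max_mismatches = 2L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  fwd_mut <- paste0("TT", substring(pr$forward, 3))  # 2 mismatches
  read <- paste0(fwd_mut, "ACGTACGT", rc(pr$reverse))
  expect_true(annotate_primers(read, primers = pr)$kept)
  fwd_mut3 <- paste0("GGG", substring(pr$forward, 4))  # 3 mismatches
  read3 <- paste0(fwd_mut3, "ACGTACGT", rc(pr$reverse))
  expect_false(annotate_primers(read3, primers = pr)$kept)
})

test_that("quality filter implements the qXpY rule", {
  expect_true(quality_filter(qual_str(rep(30L, 10))))
  q19 <- qual_str(c(rep(30L, 9), 19L))
  expect_false(quality_filter(q19))
  q1of100 <- qual_str(c(rep(30L, 99), 19L))
  expect_false(quality_filter(q1of100, q = 20, p = 1.0))
  expect_true(quality_filter(q1of100, q = 20, p = 0.99))
  # degenerate parameters pass everything
  expect_true(quality_filter(q19, q = 0))
  expect_true(quality_filter(q19, p = 0))
  # N bases count as quality 0
  expect_false(quality_filter(qual_str(rep(40L, 4)), "ACGN"))
  expect_true(quality_filter(qual_str(rep(40L, 4)), "ACGT"))
})

test_that("error correction absorbs low-abundance neighbors", {
  tp <- "wk0"
  df <- data.frame(sequence = c("AAAA", "AAAT"), timepoint = tp,
                   count = c(100L, 2L))
  rep1 <- error_correct(df, tp, ld_merge = 1, ratio = 0.1)
  expect_identical(rep1$sequences, "AAAA")
  expect_identical(unname(rep1$counts[1, 1]), 102L)

  # ratio guard: 50/100 > 0.1 keeps both
  df2 <- data.frame(sequence = c("AAAA", "AAAT"), timepoint = tp,
                    count = c(100L, 50L))
  rep2 <- error_correct(df2, tp, ld_merge = 1, ratio = 0.1)
  expect_identical(sort(rep2$sequences), c("AAAA", "AAAT"))

  # identical sequences across time points collapse to one vertex
  df3 <- data.frame(sequence = "AAAA", timepoint = c("wk0", "wk5"),
                    count = c(10L, 7L))
  rep3 <- error_correct(df3, c("wk0", "wk5"))
  expect_identical(rep3$sequences, "AAAA")
  expect_identical(unname(rep3$counts[1, ]), c(10L, 7L))
  expect_identical(unname(rep3$totals), c(10L, 7L))
})

test_that("error correction conserves read mass within each time point", {
  set.seed(33)
  tps <- c("wk0", "wk5")
  base <- rand_dna(40, 12, 14)
  df <- data.frame(
    sequence = c(base, vapply(base, function(s) {
      p <- sample(nchar(s), 1)
      substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      s
    }, character(1))),
    timepoint = sample(tps, 80, replace = TRUE),
    count = sample(1:50, 80, replace = TRUE))
  rep <- error_correct(df, tps, ld_merge = 1, ratio = 0.5)
  for (tp in tps)
    expect_identical(unname(rep$totals[tp]),
                     sum(df$count[df$timepoint == tp]))
  expect_silent(validate_repertoire(rep))
})

test_that("preprocess_reads runs FASTQ to repertoire with a stage report", {
  ss <- small_sim()
  pre <- preprocess_reads(ss$sim$fastq)
  expect_s3_class(pre$repertoire, "repertoire")
  expect_silent(validate_repertoire(pre$repertoire))
  r0 <- pre$report[["wk0"]]
  expect_identical(r0$reads_in,
                   unname(ss$config$reads_per_timepoint["wk0"]))
  expect_identical(r0$reads_in - r0$primer_rejected - r0$quality_failed,
                   r0$passed)
  # every retained sequence was actually observed in a simulated read
  expect_true(all(pre$repertoire$sequences %in% ss$sim$truth$sequence))
})

test_that("sequence-table input bypasses preprocessing", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(sequence = c("AAAA", "CCCC", "AAAA"),
                   timepoint = c("wk0", "wk0", "wk5"),
                   count = c(3L, 2L, 4L))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- read_sequence_table(path)
  expect_identical(sort(rep$sequences), c("AAAA", "CCCC"))
  expect_identical(unname(rep$totals), c(5L, 4L))
})

test_that("empty input yields an empty repertoire with a warning", {
  df <- data.frame(sequence = character(0), timepoint = character(0),
                   count = integer(0))
  expect_warning(rep <- error_correct(df, c("wk0", "wk5")), "empty")
  expect_identical(length(rep$sequences), 0L)
})
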