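#' Pipeline run configuration
#'
#' Collects every stage parameter of the end-to-end workflow. Input is either
#' `fastq` (named time-point -> path vector of pre-merged FASTQ files) or
#' `sequence_table` (a TSV of sequence/timepoint/count that bypasses
#' preprocessing, e.g. output of an external error-correction tool).
#'
#' @param fastq named character vector of FASTQ paths, or `NULL`.
#' @param sequence_table path to a sequence TSV, or `NULL`.
#' @param timepoints ordered labels; default from `names(fastq)` or file order.
#' @param primers a [primer_pair()].
#' @param q,p quality-filter parameters ([quality_filter()]).
#' @param ld_merge,ratio error-correction parameters ([error_correct()]).
#' @param t_range thresholds swept ([sweep_thresholds()]).
#' @param min_component_size,ratio_cutoff sweep parameters.
#' @param frame HCDR3 reading frame ([extract_hcdr3()]).
#' @param min_delta_vertices,min_fold_freq candidate thresholds
#'   ([rank_candidates()]).
#' @param mode clonal-frequency averaging mode ([avg_clonal_frequency()]).
#' @param outdir output directory, or `NULL` to skip writing stage outputs.
#' @return a `run_config` list.
#' @export
run_config <- function(fastq = NULL, sequence_table = NULL, timepoints = NULL,
                       primers = primer_pair(), q = 20L, p = 1.0,
                       ld_merge = 1L, ratio = 0.1, t_range = 1:20,
                       min_component_size = 3L, ratio_cutoff = 0.3, frame = 0L,
                       min_delta_vertices = 5, min_fold_freq = 2,
                       mode = "all", outdir = NULL) {
  if (is.null(fastq) == is.null(sequence_table))
    stop("give exactly one of 'fastq' or 'sequence_table'")
  if (!is.null(fastq) && is.null(timepoints)) timepoints <- names(fastq)
  structure(list(fastq = fastq, sequence_table = sequence_table,
                 timepoints = timepoints, primers = primers, q = q, p = p,
                 ld_merge = ld_merge, ratio = ratio,
                 t_range = as.integer(t_range),
                 min_component_size = as.integer(min_component_size),
                 ratio_cutoff = ratio_cutoff, frame = as.integer(frame),
                 min_delta_vertices = min_delta_vertices,
                 min_fold_freq = min_fold_freq, mode = mode, outdir = outdir),
            class = "run_config")
}

#' Read a pipeline config from JSON or YAML
#'
#' The file mirrors [run_config()] fields; `fastq` is a mapping of time-point
#' label to path.
#'
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(lst$fastq)) lst$fastq <- unlist(lst$fastq)
  if (!is.null(lst$primers)) lst$primers <- do.call(primer_pair, as.list(lst$primers))
  do.call(run_config, lst)
}

pipeline_log <- function(msg, logfile = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> distance -> threshold sweep/selection -> component
#' extraction and naming -> HCDR3 annotation -> dynamics -> candidate ranking,
#' writes all stage outputs under `config$outdir` (when set) and returns a
#' `vh_run` object whose `report` holds the census: unique sequences, edges,
#' components, singletons, retained components, the selected threshold, and
#' the ranked candidates. The report contains no wall-clock information, so
#' identical inputs and config give byte-identical reports.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `vh_run`: list with `repertoire`, `pairs`,
#'   `sweep`, `threshold`, `components`, `dynamics`, `candidates`, `report`
#'   and `config`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  logfile <- NULL
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(config$outdir, "pipeline.log")
    if (file.exists(logfile)) file.remove(logfile)
  }
  say <- function(msg) if (!quiet) pipeline_log(msg, logfile)

  say("stage preprocess")
  if (!is.null(config$fastq)) {
    pre <- preprocess_reads(config$fastq, config$primers, config$q, config$p,
                            config$ld_merge, config$ratio)
    rep <- pre$repertoire
    pre_report <- pre$report
  } else {
    rep <- read_sequence_table(config$sequence_table, config$timepoints)
    pre_report <- list(skipped = "preprocessed sequence table supplied")
  }
  if (length(rep$sequences) == 0) stop("stage preprocess: no sequences retained")

  say(sprintf("stage distance (%d unique sequences)", length(rep$sequences)))
  t_max <- max(config$t_range)
  pairs <- ld_pairs(rep, t_max)

  say("stage cdr3")
  rep <- annotate_repertoire(rep, config$frame)

  say("stage sweep")
  sweep_rec <- sweep_thresholds(rep, pairs, config$t_range,
                                config$min_component_size, config$ratio_cutoff)
  t_sel <- select_threshold(sweep_rec)
  say(sprintf("selected LD threshold %d", t_sel))

  say("stage cluster")
  graph <- build_graph(rep, pairs, t_sel)
  cc <- filter_singletons(clonal_components(graph, rep))

  say("stage dynamics")
  dyn <- component_dynamics(cc, rep, mode = config$mode)
  dyn_retained <- dyn[dyn$component_id %in% cc$summary$component_id, , drop = FALSE]
  cand <- rank_candidates(dyn_retained, config$min_delta_vertices,
                          config$min_fold_freq)

  report <- list(
    parameters = list(q = config$q, p = config$p, ld_merge = config$ld_merge,
                      ratio = config$ratio, t_range = range(config$t_range),
                      min_component_size = config$min_component_size,
                      ratio_cutoff = config$ratio_cutoff, frame = config$frame,
                      min_delta_vertices = config$min_delta_vertices,
                      min_fold_freq = config$min_fold_freq, mode = config$mode),
    package_version = as.character(utils::packageVersion("vhnet")),
    preprocess = pre_report,
    census = list(unique_sequences = length(rep$sequences),
                  selected_threshold = t_sel,
                  edges = sum(pairs$ld <= t_sel),
                  components = cc$census$total,
                  singletons = cc$census$singletons,
                  retained = cc$census$retained),
    candidates = cand$component_id)

  run <- structure(list(repertoire = rep, pairs = pairs, sweep = sweep_rec,
                        threshold = t_sel, components = cc,
                        dynamics = dyn_retained, candidates = cand,
                        report = report, config = config),
                   class = "vh_run")
  if (!is.null(config$outdir)) {
    say("stage report (writing outputs)")
    out <- config$outdir
    write_airr(rep, file.path(out, "repertoire.tsv"))
    write_hcdr3(rep, file.path(out, "hcdr3.tsv"))
    write_edges(pairs[pairs$ld <= t_sel, ], file.path(out, "edges.tsv"))
    write_membership(cc, file.path(out, "membership.tsv"))
    write_sweep(sweep_rec, file.path(out, "sweep.tsv"))
    write_dynamics(dyn_retained, file.path(out, "dynamics.tsv"))
    write_dynamics(cand, file.path(out, "candidates.tsv"))
    write_graphml(graph, rep, file.path(out, "graph.graphml"))
    write_report(run, file.path(out, "report.json"))
  }
  run
}

#' Write the run report JSON
#'
#' @param run a `vh_run`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(run, path) {
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.vh_run <- function(x, ...) {
  cen <- x$report$census
  cat("VH repertoire pipeline run\n")
  cat(sprintf("  unique sequences: %d\n", cen$unique_sequences))
  cat(sprintf("  selected LD threshold: %d (%d edges)\n", cen$selected_threshold,
              cen$edges))
  cat(sprintf("  components: %d (%d singletons excluded, %d retained)\n",
              cen$components, cen$singletons, cen$retained))
  if (length(x$report$candidates))
    cat("  candidate components:", paste(x$report$candidates, collapse = ", "), "\n")
  else cat("  no candidate components passed the thresholds\n")
  invisible(x)
}

#' @export
summary.vh_run <- function(object, ...) {
  print(object)
  cat("\nTop of dynamics table:\n")
  print(utils::head(as.data.frame(object$dynamics)[
    , c("component_id", "n_vertices", "delta_vertices", "fold_freq",
        "candidate_score")], 10))
  invisible(object)
}
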