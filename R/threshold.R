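#' Sweep Levenshtein thresholds and bin components by HCDR3 ratio
#'
#' For each threshold `t` the pooled graph is built, components are extracted,
#' components below `min_component_size` vertices are set aside, the
#' per-component HCDR3 ratio is computed, and vertex counts are binned by
#' ratio into the ten left-closed, right-open intervals
#' `[0,0.1), ..., [0.9,1]` (the last interval is closed). `vertices_low_ratio`
#' records the vertices in components whose ratio is strictly below
#' `ratio_cutoff`.
#'
#' @param rep a `repertoire` (annotated or not; HCDR3 annotations are computed
#'   once if missing).
#' @param pairs neighbor pairs from [ld_pairs()] at threshold
#'   `>= max(t_range)`.
#' @param t_range integer thresholds to sweep (default `1:20`).
#' @param min_component_size components with fewer vertices are excluded from
#'   the binning (default 3).
#' @param ratio_cutoff strict upper bound defining "low-ratio" components
#'   (default 0.3).
#' @param frame reading frame for HCDR3 extraction when `rep` is unannotated.
#' @return an object of classes `ld_sweep` and `data.frame`: one row per `t`
#'   with `n_components`, `n_excluded_small`, `vertices_low_ratio`, and bin
#'   columns `bin_0.0_0.1`, ..., `bin_0.9_1.0`.
#' @export
sweep_thresholds <- function(rep, pairs, t_range = 1:20, min_component_size = 3L,
                             ratio_cutoff = 0.3, frame = 0L) {
  stopifnot(inherits(rep, "repertoire"), length(t_range) >= 1)
  t_range <- sort(unique(as.integer(t_range)))
  if (is.null(rep$hcdr3)) rep <- annotate_repertoire(rep, frame)
  edges <- seq(0, 1, by = 0.1)
  bin_names <- sprintf("bin_%.1f_%.1f", edges[-11], edges[-1])
  rows <- vector("list", length(t_range))
  for (k in seq_along(t_range)) {
    t <- t_range[k]
    cc <- clonal_components(build_graph(rep, pairs, t), rep)
    keep <- cc$summary$n_vertices >= min_component_size
    ratios <- hcdr3_ratio(cc, rep$hcdr3)
    r <- ratios[keep]
    nv <- cc$summary$n_vertices[keep]
    bin <- pmin(floor(r * 10) + 1L, 10L)  # left-closed; 1.0 -> last bin
    counts <- vapply(seq_len(10L), function(bi) sum(nv[bin == bi]), numeric(1))
    rows[[k]] <- c(t = t,
                   n_components = nrow(cc$summary),
                   n_excluded_small = sum(!keep),
                   vertices_low_ratio = sum(nv[r < ratio_cutoff]),
                   setNames(counts, bin_names))
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "min_component_size") <- min_component_size
  attr(out, "ratio_cutoff") <- ratio_cutoff
  class(out) <- c("ld_sweep", "data.frame")
  out
}

#' Select the distance threshold
#'
#' The threshold maximizing the number of vertices in components with an
#' HCDR3 ratio below the cutoff; ties go to the smaller threshold, which
#' minimizes inclusion of unrelated transcripts.
#'
#' @param records an `ld_sweep` (or any data.frame with columns `t` and
#'   `vertices_low_ratio`).
#' @return the selected integer threshold.
#' @export
select_threshold <- function(records) {
  stopifnot(nrow(records) >= 1)
  records <- records[order(records$t), , drop = FALSE]
  as.integer(records$t[which.max(records$vertices_low_ratio)])
}

#' Write the sweep table as TSV
#'
#' @param sweep an `ld_sweep`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a threshold sweep
#'
#' `which = "heatmap"` draws threshold x ratio-bin vertex counts;
#' `which = "histogram"` draws the total vertices in low-ratio components per
#' threshold, marking the selected threshold.
#'
#' @param x an `ld_sweep`.
#' @param which `"heatmap"` or `"histogram"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.ld_sweep <- function(x, which = c("heatmap", "histogram"), ...) {
  which <- match.arg(which)
  bins <- as.matrix(x[, grep("^bin_", names(x)), drop = FALSE])
  if (which == "heatmap") {
    image(x = x$t, y = seq(0.05, 0.95, by = 0.1), z = log10(bins + 1),
          col = hcl.colors(64, "YlOrRd", rev = TRUE),
          xlab = "LD threshold", ylab = "HCDR3 ratio",
          main = "vertices per HCDR3-ratio bin (log10)")
    abline(h = attr(x, "ratio_cutoff"), lty = 2)
  } else {
    barplot(x$vertices_low_ratio, names.arg = x$t,
            xlab = "LD threshold",
            ylab = sprintf("vertices in components with ratio < %.1f",
                           attr(x, "ratio_cutoff")),
            main = sprintf("selected threshold: %d", select_threshold(x)))
  }
  invisible(x)
}
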