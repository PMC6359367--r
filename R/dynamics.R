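#' Clonal frequency matrix
#'
#' The clonal frequency of a vertex at a time point is its read count divided
#' by the total read count of that time point's transcript set, so frequencies
#' over all vertices sum to 1 at every time point with reads. Time points with
#' a zero total are reported as `NA`.
#'
#' @param rep a `repertoire`.
#' @return numeric matrix, vertices x time points.
#' @export
clonal_frequency <- function(rep) {
  stopifnot(inherits(rep, "repertoire"))
  tot <- rep$totals
  f <- sweep(rep$counts, 2, pmax(tot, 1), "/")
  f[, tot == 0] <- NA_real_
  f
}

#' Average clonal frequency per component
#'
#' Mean clonal frequency of a component's member vertices at each time point.
#' `mode = "all"` (default) averages over all members, including those with a
#' zero count at that time point; `mode = "active"` averages over members with
#' a positive count only (0 when none are active).
#'
#' @param cc a [clonal_components()] object.
#' @param rep the matching `repertoire`.
#' @param mode `"all"` or `"active"`.
#' @param smoothed if `TRUE`, per-vertex frequencies use additive smoothing
#'   `(count + 1) / total` so fold changes are defined at zero baselines.
#' @return numeric matrix, components (rows, in `summary` order) x time
#'   points.
#' @export
avg_clonal_frequency <- function(cc, rep, mode = c("all", "active"),
                                 smoothed = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(cc, "clonal_components"), inherits(rep, "repertoire"))
  keep_v <- cc$membership %in% cc$summary$component_id  # summary may be filtered
  cnt <- rep$counts[keep_v, , drop = FALSE]
  raw <- cnt
  if (smoothed) cnt <- cnt + 1L
  f <- sweep(cnt, 2, pmax(rep$totals, 1), "/")
  f[, rep$totals == 0] <- NA_real_
  memb <- factor(cc$membership[keep_v], levels = cc$summary$component_id)
  sums <- rowsum(f, memb)
  if (mode == "all") {
    out <- sums / as.integer(table(memb))
  } else {
    active <- rowsum((raw > 0) * f, memb)
    n_act <- rowsum((raw > 0) * 1, memb)
    out <- active / pmax(n_act, 1)  # 0 by convention when no active member
  }
  rownames(out) <- cc$summary$component_id
  out
}

#' Per-component time-course dynamics
#'
#' For every component: the number of active vertices (count > 0; or
#' cumulative distinct vertices seen up to each time point) and the average
#' clonal frequency at each time point; the first-to-last changes
#' `delta_vertices` and `delta_avg_freq`; the smoothed average-frequency fold
#' change `fold_freq`; and `candidate_score`, the rank-sum of the two deltas
#' (rank 1 = largest increase; smaller scores are stronger candidates).
#'
#' @param cc a [clonal_components()] object.
#' @param rep the matching `repertoire` (needs >= 2 time points).
#' @param mode averaging mode, see [avg_clonal_frequency()].
#' @param count_mode `"active"` (vertices with reads at the time point) or
#'   `"cumulative"` (vertices seen at any time point up to it).
#' @return an object of classes `component_dynamics` and `data.frame`, one
#'   row per component.
#' @export
component_dynamics <- function(cc, rep, mode = c("all", "active"),
                               count_mode = c("active", "cumulative")) {
  mode <- match.arg(mode)
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(cc, "clonal_components"), inherits(rep, "repertoire"))
  if (length(rep$timepoints) < 2) stop("dynamics need at least 2 time points")
  keep_v <- cc$membership %in% cc$summary$component_id
  memb <- factor(cc$membership[keep_v], levels = cc$summary$component_id)
  present <- rep$counts[keep_v, , drop = FALSE] > 0
  if (count_mode == "cumulative")
    present <- t(apply(present, 1, cumsum)) > 0
  n_act <- rowsum(present * 1L, memb)
  avg <- avg_clonal_frequency(cc, rep, mode)
  sm <- avg_clonal_frequency(cc, rep, mode, smoothed = TRUE)
  first <- 1L
  last <- length(rep$timepoints)
  delta_v <- n_act[, last] - n_act[, first]
  delta_f <- avg[, last] - avg[, first]
  fold <- sm[, last] / sm[, first]
  score <- rank(-delta_v, ties.method = "min") + rank(-delta_f, ties.method = "min")
  out <- data.frame(component_id = cc$summary$component_id,
                    n_vertices = cc$summary$n_vertices)
  nn <- n_act; colnames(nn) <- paste0("n_active_", rep$timepoints)
  aa <- avg; colnames(aa) <- paste0("avg_freq_", rep$timepoints)
  out <- cbind(out, as.data.frame(nn), as.data.frame(aa))
  out$delta_vertices <- as.integer(delta_v)
  out$delta_avg_freq <- as.numeric(delta_f)
  out$fold_freq <- as.numeric(fold)
  out$candidate_score <- as.numeric(score)
  rownames(out) <- NULL
  attr(out, "timepoints") <- rep$timepoints
  class(out) <- c("component_dynamics", "data.frame")
  out
}

#' Rank candidate antigen-reactive components
#'
#' Components passing both expansion thresholds — growth in active vertex
#' count of at least `min_delta_vertices` and a smoothed average-frequency
#' fold change of at least `min_fold_freq` from the first to the last time
#' point — are ranked by `candidate_score` (ascending; ties by larger
#' `delta_vertices`, then smaller `component_id`).
#'
#' @param dynamics a [component_dynamics()] table.
#' @param min_delta_vertices minimum vertex-count increase (default 5).
#' @param min_fold_freq minimum average-frequency fold change (default 2).
#' @return the passing rows, ranked; a `rank` column is prepended.
#' @export
rank_candidates <- function(dynamics, min_delta_vertices = 5, min_fold_freq = 2) {
  keep <- dynamics$delta_vertices >= min_delta_vertices &
    !is.na(dynamics$fold_freq) & dynamics$fold_freq >= min_fold_freq
  out <- as.data.frame(dynamics)[keep, , drop = FALSE]
  out <- out[order(out$candidate_score, -out$delta_vertices, out$component_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out <- cbind(rank = seq_len(nrow(out)), out)
  out
}

#' Write the dynamics table as TSV
#'
#' @param dynamics a `component_dynamics` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dynamics <- function(dynamics, path) {
  utils::write.table(as.data.frame(dynamics), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scatter plot of component dynamics
#'
#' Change in active vertex count versus change in average clonal frequency
#' (first to last time point), with candidate components highlighted.
#'
#' @param x a `component_dynamics` table.
#' @param min_delta_vertices,min_fold_freq candidate thresholds, see
#'   [rank_candidates()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.component_dynamics <- function(x, min_delta_vertices = 5, min_fold_freq = 2,
                                    ...) {
  cand <- rank_candidates(x, min_delta_vertices, min_fold_freq)
  plot(x$delta_vertices, x$delta_avg_freq, pch = 16, col = "grey40",
       xlab = "change in active vertices (last - first)",
       ylab = "change in average clonal frequency", ...)
  if (nrow(cand)) {
    sel <- x$component_id %in% cand$component_id
    points(x$delta_vertices[sel], x$delta_avg_freq[sel], pch = 16, col = "firebrick")
    legend("topleft", legend = c("candidate", "other"), pch = 16,
           col = c("firebrick", "grey40"), bty = "n")
  }
  invisible(x)
}
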