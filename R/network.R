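#' Build the thresholded sequence graph
#'
#' Undirected graph over all vertices of the pooled repertoire (all time
#' points), with an edge for every sequence pair at Levenshtein distance
#' `<= t`.
#'
#' @param rep a `repertoire`.
#' @param pairs neighbor pairs from [ld_pairs()], computed at a threshold
#'   `>= t`.
#' @param t inclusive distance threshold (`t = 0` yields an edgeless graph).
#' @return an object of class `vh_graph`: list with `graph` (igraph),
#'   `threshold` and `edges` (the retained pair table).
#' @export
build_graph <- function(rep, pairs, t) {
  stopifnot(inherits(rep, "repertoire"), t >= 0)
  if (!is.null(attr(pairs, "threshold")) && attr(pairs, "threshold") < t)
    stop("pairs were enumerated at a smaller threshold than 't'")
  edges <- pairs[pairs$ld <= t, , drop = FALSE]
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  n <- length(rep$sequences)
  if (length(edges$a) && (max(edges$a, edges$b) > n))
    stop("pair vertex id exceeds repertoire size")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$a, edges$b), ld = edges$ld)
  structure(list(graph = g, threshold = t, edges = edges), class = "vh_graph")
}

#' @export
print.vh_graph <- function(x, ...) {
  cat(sprintf("VH sequence graph: %d vertices, %d edges at LD threshold %d\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Extract and name connected components
#'
#' Connected components of the thresholded graph are the putative clonal
#' lineages. Components are named by sorting on vertex count in descending
#' order and assigning identification numbers ascending from 1; ties are
#' broken by larger pooled read count, then by the lexicographically smallest
#' member sequence.
#'
#' @param graph a [build_graph()] object.
#' @param rep the `repertoire` the graph was built on.
#' @return an object of class `clonal_components`: list with `membership`
#'   (integer component id per vertex), `summary` (data.frame `component_id`,
#'   `n_vertices`, `edge_count`, `total_reads`), `threshold`, and `graph`.
#' @export
clonal_components <- function(graph, rep) {
  stopifnot(inherits(graph, "vh_graph"), inherits(rep, "repertoire"))
  comp <- igraph::components(graph$graph)
  memb <- comp$membership
  n_comp <- comp$no
  sizes <- as.integer(comp$csize)
  total_reads <- as.numeric(rowsum(rowSums(rep$counts), memb)[, 1])
  min_seq <- vapply(split(rep$sequences, memb), min, character(1))
  ecnt <- integer(n_comp)
  if (nrow(graph$edges)) {
    tab <- table(memb[graph$edges$a])
    ecnt[as.integer(names(tab))] <- as.integer(tab)
  }
  ord <- order(-sizes, -total_reads, min_seq)
  new_id <- integer(n_comp)
  new_id[ord] <- seq_len(n_comp)
  structure(list(
    membership = new_id[memb],
    summary = data.frame(component_id = seq_len(n_comp),
                         n_vertices = sizes[ord],
                         edge_count = ecnt[ord],
                         total_reads = total_reads[ord]),
    threshold = graph$threshold,
    graph = graph), class = "clonal_components")
}

#' @export
print.clonal_components <- function(x, ...) {
  cat(sprintf("%d components over %d vertices (LD threshold %d); %d singletons\n",
              nrow(x$summary), length(x$membership), x$threshold,
              sum(x$summary$n_vertices == 1)))
  invisible(x)
}

#' Census of component sizes
#'
#' @param sizes integer vector of component vertex counts.
#' @return list with `total`, `singletons` and `retained`
#'   (`total - singletons`), satisfying the identity exactly.
#' @export
component_census <- function(sizes) {
  total <- length(sizes)
  singletons <- sum(sizes == 1L)
  list(total = total, singletons = singletons, retained = total - singletons)
}

#' Drop single-vertex components
#'
#' Components composed of a single vertex carry no homology signal and are
#' excluded from downstream analysis; the census (total, singletons,
#' retained) is reported alongside.
#'
#' @param x a `clonal_components` object, or an integer vector of component
#'   sizes (to replay a published census without the underlying graph).
#' @param ... unused.
#' @return For `clonal_components`: the same object with `summary` restricted
#'   to components of `>= 2` vertices and a `census` element added. For a
#'   size vector: list with `sizes` (retained sizes) and `census`.
#' @export
filter_singletons <- function(x, ...) UseMethod("filter_singletons")

#' @rdname filter_singletons
#' @export
filter_singletons.clonal_components <- function(x, ...) {
  census <- component_census(x$summary$n_vertices)
  x$summary <- x$summary[x$summary$n_vertices >= 2L, , drop = FALSE]
  x$census <- census
  x
}

#' @rdname filter_singletons
#' @export
filter_singletons.numeric <- function(x, ...) {
  list(sizes = x[x >= 2], census = component_census(x))
}

#' @rdname filter_singletons
#' @export
filter_singletons.integer <- filter_singletons.numeric

#' Minimum spanning tree of one component
#'
#' Kruskal-style minimum spanning tree over a component's internal edges with
#' Levenshtein-distance weights; ties are broken by canonical edge order
#' (`ld`, then vertex ids), so the tree is deterministic. Used to reduce dense
#' components for visualization.
#'
#' @param cc a [clonal_components()] object.
#' @param component_id which component.
#' @return data.frame of tree edges (`a`, `b`, `ld`) with attribute `weight`
#'   (total LD); `n_vertices - 1` rows.
#' @export
component_mst <- function(cc, component_id) {
  stopifnot(inherits(cc, "clonal_components"))
  members <- which(cc$membership == component_id)
  if (length(members) < 2) stop("MST needs a component with >= 2 vertices")
  e <- cc$graph$edges
  e <- e[e$a %in% members & e$b %in% members, , drop = FALSE]
  e <- e[order(e$ld, e$a, e$b), , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(match(e$a, members), match(e$b, members)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(members) - igraph::vcount(g)))
  if (igraph::components(g)$no != 1) stop("component subgraph is disconnected")
  # strictly monotone perturbation by canonical rank: unique MST, same total LD
  igraph::E(g)$idx <- seq_len(nrow(e))
  w <- e$ld + seq_len(nrow(e)) * 1e-9
  tree <- igraph::mst(g, weights = w)
  out <- e[sort(igraph::E(tree)$idx), c("a", "b", "ld")]
  out <- out[order(out$ld, out$a, out$b), ]
  rownames(out) <- NULL
  attr(out, "weight") <- sum(out$ld)
  out
}

#' Export the thresholded graph as GraphML
#'
#' @param graph a `vh_graph`.
#' @param rep the matching `repertoire` (vertex attributes: sequence, counts).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, rep, path) {
  g <- graph$graph
  igraph::V(g)$name <- as.character(seq_along(rep$sequences))
  igraph::V(g)$sequence <- rep$sequences
  freq <- clonal_frequency(rep)
  igraph::V(g)$max_clonal_frequency <- apply(freq, 1, max, na.rm = TRUE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write component membership TSV
#'
#' @param cc a `clonal_components` object.
#' @param path output path (columns `vertex_id`, `component_id`).
#' @return `path`, invisibly.
#' @export
write_membership <- function(cc, path) {
  utils::write.table(
    data.frame(vertex_id = seq_along(cc$membership), component_id = cc$membership),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a component's minimum spanning tree
#'
#' Minimal layout plot: vertex diameter scales with the vertex's highest
#' clonal frequency across time points.
#'
#' @param cc a `clonal_components` object.
#' @param rep the matching `repertoire`.
#' @param component_id which component to draw.
#' @param ... passed to `plot.igraph`.
#' @return invisibly, the MST edge table.
#' @export
plot_component_mst <- function(cc, rep, component_id, ...) {
  tree <- component_mst(cc, component_id)
  members <- sort(unique(c(tree$a, tree$b)))
  g <- igraph::graph_from_edgelist(cbind(match(tree$a, members), match(tree$b, members)),
                                   directed = FALSE)
  freq <- clonal_frequency(rep)
  sz <- apply(freq[members, , drop = FALSE], 1, max, na.rm = TRUE)
  sz <- 3 + 12 * sz / max(sz)
  plot(g, vertex.size = sz, vertex.label = NA,
       main = sprintf("component %d (MST)", component_id), ...)
  invisible(tree)
}
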