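make_rep <- function(seqs, tp = "wk0") {
  new_repertoire(seqs, matrix(1L, length(seqs), 1, dimnames = list(NULL, tp)), tp)
}

test_that("build_graph keeps exactly the pairs within the threshold", {
  # pairwise LDs {1, 2, 5}
  seqs <- c("AAAAAA", "AAAAAT", "AAAATT", "CCCCGG")
  rep <- make_rep(c(seqs[1], seqs[2], "GGGGGG"))
  pairs <- ld_pairs(rep, 6)
  rep3 <- make_rep(c("AAAAAA", "AAAAAT", "AAATTT"))  # LDs 1, 3, 2
  p3 <- ld_pairs(rep3, 10)
  g2 <- build_graph(rep3, p3, 2)
  expect_identical(nrow(g2$edges), 2L)
  g0 <- build_graph(rep3, p3, 0)
  expect_identical(nrow(g0$edges), 0L)
  gall <- build_graph(rep3, p3, 3)
  expect_identical(nrow(gall$edges), 3L)  # complete graph on 3 vertices
})

test_that("components partition the vertex set", {
  rep <- make_rep(c("AAAAAA", "AAAAAT", "CCCCCC", "CCCCCT", "GGGGGG"))
  pairs <- ld_pairs(rep, 6)
  cc <- clonal_components(build_graph(rep, pairs, 1), rep)
  expect_identical(sum(cc$summary$n_vertices), 5L)
  expect_setequal(unique(cc$membership), cc$summary$component_id)
  # two doubletons and one singleton
  expect_identical(sort(cc$summary$n_vertices), c(1L, 2L, 2L))

  # edgeless graph: every vertex its own component
  cc0 <- clonal_components(build_graph(rep, pairs, 0), rep)
  expect_identical(nrow(cc0$summary), 5L)
  # path graph A-B, B-C (LDs 1,1): one component with 2 edges... build a path
  path_rep <- make_rep(c("AAAA", "AAAT", "AATT"))
  pp <- ld_pairs(path_rep, 4)
  ccp <- clonal_components(build_graph(path_rep, pp, 1), path_rep)
  expect_identical(nrow(ccp$summary), 1L)
  expect_identical(ccp$summary$edge_count, 2L)
})

test_that("components agree with brute-force transitive closure", {
  set.seed(77)
  seqs <- unique(rand_dna(60, 6, 12))
  rep <- make_rep(seqs)
  pairs <- ld_pairs(rep, 3)
  cc <- clonal_components(build_graph(rep, pairs, 3), rep)
  # oracle: boolean reachability closure over the adjacency matrix
  n <- length(seqs)
  adj <- diag(n) > 0
  d <- adist(seqs)
  adj <- adj | (d >= 1 & d <= 3)
  for (k in seq_len(n)) adj <- adj | (adj[, k] %o% adj[k, ] > 0)
  oracle_lab <- apply(adj, 1, function(r) min(which(r)))
  # same partition (labels may differ)
  expect_identical(length(unique(oracle_lab)), nrow(cc$summary))
  split_ours <- split(seq_len(n), cc$membership)
  split_oracle <- split(seq_len(n), oracle_lab)
  norm <- function(s) unname(lapply(s[order(vapply(s, min, 1))], identity))
  expect_identical(norm(split_ours), norm(split_oracle))
})

test_that("component naming sorts by size with deterministic tie-breaks", {
  # sizes 3 ("AAAA" cluster), 2 x 2, 1; the two doubletons tie on size and
  # total reads, and are ordered by smallest member sequence
  seqs <- c("AAAA", "AAAT", "AATT",          # size 3
            "CCCC", "CCCG",                  # doubleton, min seq CCCC
            "GGGG", "GGGT",                  # doubleton, min seq GGGG
            "TCGATCGA")                      # singleton
  rep <- make_rep(seqs)
  pairs <- ld_pairs(rep, 8)
  cc <- clonal_components(build_graph(rep, pairs, 1), rep)
  expect_identical(cc$summary$n_vertices, c(3L, 2L, 2L, 1L))
  expect_identical(cc$membership, c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L))
  # larger pooled read count wins the tie
  cnt <- matrix(c(1L, 1L, 1L, 1L, 1L, 5L, 5L, 1L), ncol = 1,
                dimnames = list(NULL, "wk0"))
  rep2 <- new_repertoire(seqs, cnt, "wk0")
  cc2 <- clonal_components(build_graph(rep2, pairs, 1), rep2)
  expect_identical(cc2$membership, c(1L, 1L, 1L, 3L, 3L, 2L, 2L, 4L))
})

test_that("singleton filtering reports an exact census", {
  sizes <- c(5L, 3L, 1L, 1L, 2L, 1L)
  fs <- filter_singletons(sizes)
  expect_identical(fs$census, list(total = 6L, singletons = 3L, retained = 3L))
  expect_identical(fs$sizes, c(5L, 3L, 2L))
  # all singletons -> empty retained set
  expect_identical(filter_singletons(rep(1L, 4))$census$retained, 0L)
  # no singletons -> identity
  expect_identical(filter_singletons(c(2L, 4L))$sizes, c(2L, 4L))

  rep <- make_rep(c("AAAA", "AAAT", "GGGG"))
  cc <- filter_singletons(
    clonal_components(build_graph(rep, ld_pairs(rep, 4), 1), rep))
  expect_identical(cc$census, list(total = 2L, singletons = 1L, retained = 1L))
  expect_identical(cc$census$total - cc$census$singletons, cc$census$retained)
  expect_true(all(cc$summary$n_vertices >= 2))
})

test_that("MST has n - 1 edges, minimal weight and deterministic ties", {
  # triangle with weights {1, 2, 2}: tree weight 3 (oracle: enumerate all 3
  # spanning trees -> weights 3, 3, 4; canonical tie rule keeps edges (1,2),(1,3))
  seqs <- c("AAAA", "AAAT", "AATC")  # LDs: 1 (1-2), 2 (1-3), 2 (2-3)
  rep <- make_rep(seqs)
  pairs <- ld_pairs(rep, 4)
  cc <- clonal_components(build_graph(rep, pairs, 2), rep)
  tree <- component_mst(cc, 1)
  expect_identical(nrow(tree), 2L)
  expect_identical(attr(tree, "weight"), 3L)
  expect_identical(tree$a, c(1L, 1L))
  expect_identical(tree$b, c(2L, 3L))

  # 2-vertex component: its single edge
  rep2 <- make_rep(c("AAAA", "AAAT"))
  cc2 <- clonal_components(build_graph(rep2, ld_pairs(rep2, 4), 1), rep2)
  expect_identical(nrow(component_mst(cc2, 1)), 1L)

  # path graph: the unique spanning tree is the path itself
  rep3 <- make_rep(c("AAAA", "AAAT", "AATT", "ATTT"))
  p3 <- ld_pairs(rep3, 4)
  cc3 <- clonal_components(build_graph(rep3, p3, 1), rep3)
  tr3 <- component_mst(cc3, 1)
  expect_equal(tr3[, c("a", "b")],
               data.frame(a = 1:3, b = 2:4), ignore_attr = TRUE)

  expect_error(component_mst(cc, 99))
})

test_that("MST edge count is n - 1 for every component of a random graph", {
  set.seed(12)
  seqs <- unique(rand_dna(50, 6, 10))
  rep <- make_rep(seqs)
  pairs <- ld_pairs(rep, 2)
  cc <- clonal_components(build_graph(rep, pairs, 2), rep)
  for (cid in cc$summary$component_id[cc$summary$n_vertices >= 2]) {
    tree <- component_mst(cc, cid)
    expect_identical(nrow(tree),
                     cc$summary$n_vertices[cc$summary$component_id == cid] - 1L)
  }
})

test_that("component count shrinks and edge count grows as t increases", {
  set.seed(13)
  seqs <- unique(rand_dna(80, 8, 14))
  rep <- make_rep(seqs)
  pairs <- ld_pairs(rep, 10)
  prev_comp <- Inf
  prev_edge <- -1
  for (t in 1:10) {
    g <- build_graph(rep, pairs, t)
    cc <- clonal_components(g, rep)
    expect_lte(nrow(cc$summary), prev_comp)
    expect_gte(nrow(g$edges), prev_edge)
    prev_comp <- nrow(cc$summary)
    prev_edge <- nrow(g$edges)
  }
})

test_that("graph and membership exports round-trip through files", {
  rep <- make_rep(c("AAAA", "AAAT", "GGGG"))
  pairs <- ld_pairs(rep, 4)
  g <- build_graph(rep, pairs, 1)
  cc <- clonal_components(g, rep)
  gm <- tempfile(fileext = ".graphml")
  write_graphml(g, rep, gm)
  g2 <- igraph::read_graph(gm, format = "graphml")
  expect_identical(igraph::vcount(g2), 3)
  expect_identical(igraph::ecount(g2), 1)
  mem <- tempfile(fileext = ".tsv")
  write_membership(cc, mem)
  df <- read.delim(mem)
  expect_identical(df$component_id, cc$membership)
  ed <- tempfile(fileext = ".tsv")
  write_edges(pairs, ed)
  expect_identical(read.delim(ed)$ld, pairs$ld)
})
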