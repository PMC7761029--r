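test_that("Pearson correlations match hand-derived values", {
  x <- c(1, 2, 3, 4)
  m <- rbind(a = x, b = 3 + 2 * x, c = 10 - x, d = c(1, 2, 3, 10))
  colnames(m) <- paste0("s", 1:4)
  corr <- pcc_matrix(m)
  expect_equal(corr["a", "a"], 1)
  expect_equal(corr["a", "b"], 1)
  expect_equal(corr["a", "c"], -1)
  expect_equal(corr["a", "d"], 14 / sqrt(5 * 50), tolerance = 1e-12)
  expect_equal(corr, t(corr))

  flat <- rbind(m, e = rep(2, 4))
  corr2 <- pcc_matrix(flat)
  expect_false("e" %in% rownames(corr2))
  expect_equal(attr(corr2, "dropped"), "e")
  expect_error(pcc_matrix(m[, 1:2]), "samples")
})

test_that("neighbor ranks follow decreasing PCC with id tie-breaks", {
  m <- rbind(A = c(1, 2, 3, 4), B = c(2, 4, 6, 8), C = c(4, 3, 2, 1))
  colnames(m) <- paste0("s", 1:4)
  rk <- rank_neighbors(pcc_matrix(m))
  expect_equal(rk["A", "B"], 1L)
  expect_equal(rk["A", "C"], 2L)
  # row C: A and B tie at PCC -1; ascending id puts A first
  expect_equal(rk["C", "A"], 1L)
  expect_equal(rk["C", "B"], 2L)

  h <- hrr_matrix(rk)
  expect_equal(h["A", "C"], 2L)
  expect_equal(h, t(h))

  # two genes rank each other first
  m2 <- m[1:2, ]
  rk2 <- rank_neighbors(pcc_matrix(m2))
  expect_equal(unname(rk2[cbind(c(1, 2), c(2, 1))]), c(1L, 1L))
  expect_equal(hrr_matrix(rk2)["A", "B"], 1L)
})

test_that("ranks are invariant to gene input order", {
  set.seed(61)
  m <- matrix(rnorm(80), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  rk <- rank_neighbors(pcc_matrix(m))
  perm <- sample(10)
  rk_p <- rank_neighbors(pcc_matrix(m[perm, ]))
  expect_identical(rk_p[rownames(rk), colnames(rk)], rk)
})

test_that("HRR equals the naive per-pair recomputation on a seeded matrix", {
  set.seed(62)
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:8)))
  h <- hrr_matrix(rank_neighbors(pcc_matrix(m)))
  expect_identical(h, naive_hrr(m))
  expect_true(all(h[upper.tri(h)] >= 1))
})

test_that("network capture applies the strict HRR threshold", {
  ids <- c("bait", "near", "far")
  h <- matrix(c(0L, 99L, 100L,
                99L, 0L, 120L,
                100L, 120L, 0L), 3, 3, dimnames = list(ids, ids))
  g <- build_network(h, "bait", tau = 100)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("bait", "near"))
  expect_equal(igraph::E(g)$hrr, 99)
  expect_true(igraph::V(g)$is_bait[igraph::V(g)$name == "bait"])

  expect_warning(g0 <- build_network(h, "bait", tau = 50), "isolated")
  expect_equal(igraph::ecount(g0), 0)
  expect_error(build_network(h, "zz", tau = 100), "no baits")
})

test_that("lowering the capture threshold never adds edges", {
  set.seed(63)
  m <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(sprintf("g%02d", 1:60), paste0("s", 1:8)))
  h <- hrr_matrix(rank_neighbors(pcc_matrix(m)))
  baits <- c("g01", "g02", "g03")
  edge_key <- function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) character(0) else paste(el[, 1], el[, 2])
  }
  for (capture in c("bait", "all")) {
    prev <- NULL
    for (tau in c(40, 20, 10, 2)) {
      e <- suppressWarnings(
        edge_key(build_network(h, baits, tau = tau, capture = capture)))
      if (!is.null(prev)) expect_true(all(e %in% prev))
      prev <- e
    }
  }
})

test_that("modularity matches its definition and the exhaustive optimum", {
  tri2 <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  memb_all <- setNames(rep(1, 6), igraph::V(tri2)$name)
  expect_equal(modularity_q(tri2, memb_all), 0)

  memb_comp <- setNames(c(1, 1, 1, 2, 2, 2), igraph::V(tri2)$name)
  expect_equal(modularity_q(tri2, memb_comp), 0.5)

  memb_single <- setNames(1:6, igraph::V(tri2)$name)
  expect_lt(modularity_q(tri2, memb_single), 0)

  # exhaustive search over all 203 partitions of 6 nodes
  parts <- all_partitions(6)
  expect_length(parts, 203)
  qs <- vapply(parts, function(p)
    modularity_q(tri2, setNames(p, igraph::V(tri2)$name)), numeric(1))
  expect_equal(max(qs), 0.5)
  expect_equal(sort(unique(parts[[which.max(qs)]])), 1:2)

  expect_error(modularity_q(igraph::make_empty_graph(3), c(1, 1, 1)),
               "edgeless")
})

test_that("modularity agrees with igraph's implementation", {
  skip_if_not_installed("igraph")
  set.seed(64)
  for (i in 1:10) {
    g <- igraph::sample_gnp(8, 0.4)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("n", 1:8)
    memb <- sample(1:3, 8, replace = TRUE)
    expect_equal(modularity_q(g, setNames(memb, igraph::V(g)$name)),
                 igraph::modularity(g, memb), tolerance = 1e-12)
  }
})

test_that("fast-greedy agglomeration finds the known optima", {
  tri2 <- igraph::make_graph(~ a - b, b - c, c - a, d - e, e - f, f - d)
  fg <- fast_greedy_communities(tri2)
  expect_equal(fg$q, 0.5)
  expect_equal(length(unique(fg$membership)), 2)
  expect_equal(length(unique(fg$membership[c("a", "b", "c")])), 1)
  expect_equal(length(unique(fg$membership[c("d", "e", "f")])), 1)

  single <- igraph::make_graph(~ x - y)
  fs <- fast_greedy_communities(single)
  expect_equal(fs$q, 0)
  expect_equal(length(unique(fs$membership)), 1)

  expect_error(fast_greedy_communities(igraph::make_empty_graph(2)),
               "edgeless")
})

test_that("greedy modularity never beats the exhaustive optimum and is exact on cliques", {
  set.seed(65)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    g <- igraph::sample_gnp(n, 0.5)
    if (igraph::ecount(g) == 0) next
    igraph::V(g)$name <- paste0("n", seq_len(n))
    fg <- fast_greedy_communities(g)
    parts <- all_partitions(n)
    q_best <- max(vapply(parts, function(p)
      modularity_q(g, setNames(p, igraph::V(g)$name)), numeric(1)))
    expect_lte(fg$q, q_best + 1e-12)
    expect_equal(fg$q, modularity_q(g, fg$membership), tolerance = 1e-12)
  }

  # two disconnected cliques: greedy attains the exhaustive optimum
  for (sizes in list(c(3, 3), c(3, 4), c(4, 4))) {
    g <- igraph::disjoint_union(igraph::make_full_graph(sizes[1]),
                                igraph::make_full_graph(sizes[2]))
    igraph::V(g)$name <- paste0("n", seq_len(sum(sizes)))
    fg <- fast_greedy_communities(g)
    parts <- all_partitions(sum(sizes))
    q_best <- max(vapply(parts, function(p)
      modularity_q(g, setNames(p, igraph::V(g)$name)), numeric(1)))
    expect_equal(fg$q, q_best, tolerance = 1e-12)
    expect_equal(length(unique(fg$membership)), 2)
  }
})

test_that("candidate reports sort by HRR, then PCC, then id", {
  g <- igraph::graph_from_data_frame(
    data.frame(u = c("B", "B", "B"), v = c("x", "y", "z")),
    directed = FALSE,
    vertices = data.frame(name = c("B", "x", "y", "z"),
                          is_bait = c(TRUE, FALSE, FALSE, FALSE)))
  igraph::E(g)$hrr <- c(3, 3, 7)
  igraph::E(g)$pcc <- c(0.8, 0.9, 0.99)
  part <- structure(list(membership = setNames(c(1L, 1L, 1L, 2L),
                                               c("B", "x", "y", "z")),
                         q = 0), class = "community_partition")
  rep <- candidate_report(g, part)
  expect_equal(rep$candidates$gene, c("y", "x", "z"))
  expect_equal(rep$candidates$same_community, c(TRUE, TRUE, FALSE))
  expect_equal(rep$communities$n_baits, c(1, 0))

  g1 <- igraph::graph_from_data_frame(
    data.frame(u = "B", v = "c1"), directed = FALSE,
    vertices = data.frame(name = c("B", "c1"),
                          is_bait = c(TRUE, FALSE)))
  igraph::E(g1)$hrr <- 1
  p1 <- structure(list(membership = c(B = 1L, c1 = 1L), q = 0),
                  class = "community_partition")
  r1 <- candidate_report(g1, p1)
  expect_equal(nrow(r1$candidates), 1)
  expect_equal(r1$candidates$gene, "c1")
  expect_equal(r1$candidates$hrr, 1)
})

test_that("the profile filter keeps young-aerial-maximal candidates", {
  tpm <- rbind(
    young = c(1300, 1300, 1310, 1310, 90, 90, 40, 40),
    rooty = c(10, 10, 20, 20, 30, 30, 900, 900),
    both  = c(5, 5, 5, 5, 5, 5, 5, 5))
  colnames(tpm) <- c("YL1", "YL2", "YS1", "YS2", "OL1", "OL2", "AR1", "AR2")
  meta <- data.frame(sample_id = colnames(tpm),
                     tissue = rep(c("YL", "YS", "OL", "AR"), each = 2))
  kept <- profile_filter(c("young", "rooty", "both"), tpm, meta)
  expect_setequal(kept, c("young", "both"))  # flat profile ties everywhere

  all_t <- profile_filter(c("young", "rooty"), tpm, meta,
                          tissues = c("YL", "YS", "OL", "AR"))
  expect_setequal(all_t, c("young", "rooty"))
  expect_error(profile_filter("young", tpm, meta, tissues = "XX"),
               "unknown tissue")
})

test_that("network export writes a stable edge list and GraphML", {
  set.seed(66)
  m <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  corr <- pcc_matrix(m)
  h <- hrr_matrix(rank_neighbors(corr))
  g <- build_network(h, c("g01", "g02"), tau = 10, pcc = corr)
  part <- fast_greedy_communities(g)
  d <- withr::local_tempdir()
  write_network(g, file.path(d, "e.tsv"), file.path(d, "g.graphml"), part)
  e <- read.delim(file.path(d, "e.tsv"))
  expect_equal(nrow(e), igraph::ecount(g))
  expect_true(all(c("u", "v", "hrr", "pcc") %in% names(e)))
  g2 <- igraph::read_graph(file.path(d, "g.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(sort(igraph::V(g2)$community), sort(part$membership),
               ignore_attr = TRUE)
})
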