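#' Pairwise Pearson correlation matrix of expression profiles
#'
#' Computes the gene-by-gene Pearson correlation over samples on the supplied
#' (log-transformed) expression matrix. Zero-variance genes make the
#' coefficient undefined and are removed first; their ids are attached as the
#' `dropped` attribute.
#'
#' @param log_expr matrix, genes x samples (>= 3 samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pcc_matrix <- function(log_expr) {
  if (ncol(log_expr) < 3) stop("need >= 3 samples for correlation")
  v <- apply(log_expr, 1, var)
  dropped <- rownames(log_expr)[v == 0]
  if (length(dropped))
    log_expr <- log_expr[v > 0, , drop = FALSE]
  corr <- cor(t(log_expr))
  attr(corr, "dropped") <- dropped
  corr
}

#' Ordinal neighbor ranks from a correlation matrix
#'
#' For every gene i, the other genes are sorted by decreasing correlation
#' with i and assigned ordinal ranks 1..(n-1); ties are broken by ascending
#' gene id (deterministic and invariant to input order). The diagonal is 0.
#'
#' @param corr correlation matrix from [pcc_matrix()].
#' @return integer matrix of directed ranks.
#' @export
rank_neighbors <- function(corr) {
  n <- nrow(corr)
  ids <- rownames(corr)
  rk <- matrix(0L, n, n, dimnames = dimnames(corr))
  for (i in seq_len(n)) {
    o <- order(-corr[i, -i], ids[-i], method = "radix")
    r <- integer(n - 1)
    r[o] <- seq_len(n - 1)
    rk[i, -i] <- r
  }
  rk
}

#' Highest reciprocal rank matrix
#'
#' HRR(i, j) = max(rank_i(j), rank_j(i)): the worse of the two directed
#' neighbor ranks. Symmetric, integer, >= 1 off the diagonal; HRR = 1 iff
#' the two genes are mutually top-ranked.
#'
#' @param ranks directed rank matrix from [rank_neighbors()].
#' @return symmetric integer HRR matrix (diagonal 0).
#' @export
hrr_matrix <- function(ranks) {
  pmax(ranks, t(ranks))
}

#' Bait-anchored co-expression network at an HRR threshold
#'
#' Captures, for every bait gene, the co-expressed partners whose HRR to the
#' bait is strictly below `tau` (default 100). The default `"bait"` capture
#' mode keeps only bait-incident edges (bait-bait edges under the same rule);
#' `"all"` additionally connects captured non-bait genes to each other when
#' their mutual HRR passes the threshold.
#'
#' @param hrr HRR matrix from [hrr_matrix()].
#' @param baits character vector of bait gene ids (must be in the matrix).
#' @param tau capture threshold; edges require HRR < tau (strict).
#' @param capture `"bait"` (default) or `"all"`.
#' @param pcc optional correlation matrix to attach as an edge attribute.
#' @return an `igraph` graph; vertices carry `is_bait`, edges carry `hrr`
#'   and (optionally) `pcc`.
#' @export
build_network <- function(hrr, baits, tau = 100,
                          capture = c("bait", "all"), pcc = NULL) {
  capture <- match.arg(capture)
  ids <- rownames(hrr)
  baits <- sort(unique(baits), method = "radix")
  if (!any(baits %in% ids)) stop("no baits present in the HRR matrix")
  if (!all(baits %in% ids)) {
    warning("baits missing from the HRR matrix: ",
            paste(setdiff(baits, ids), collapse = ", "))
    baits <- intersect(baits, ids)
  }

  bait_rows <- hrr[baits, , drop = FALSE]
  hit <- which(bait_rows < tau & bait_rows > 0, arr.ind = TRUE)
  edges <- data.frame(u = baits[hit[, 1]], v = ids[hit[, 2]],
                      stringsAsFactors = FALSE)
  swap <- edges$u > edges$v
  tmp <- edges$u[swap]; edges$u[swap] <- edges$v[swap]; edges$v[swap] <- tmp
  edges <- unique(edges)

  nodes <- sort(unique(c(baits, edges$u, edges$v)), method = "radix")
  if (capture == "all" && length(nodes) > 1) {
    sub <- hrr[nodes, nodes, drop = FALSE]
    hit <- which(sub < tau & sub > 0 & upper.tri(sub), arr.ind = TRUE)
    edges <- unique(data.frame(u = nodes[pmin(hit[, 1], hit[, 2])],
                               v = nodes[pmax(hit[, 1], hit[, 2])],
                               stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$u, edges$v, method = "radix"), , drop = FALSE]
  if (nrow(edges) == 0)
    warning("no pair passes HRR < ", tau, "; network has isolated baits only")

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, is_bait = nodes %in% baits,
                          stringsAsFactors = FALSE))
  if (nrow(edges) > 0) {
    igraph::E(g)$hrr <- hrr[cbind(edges$u, edges$v)]
    if (!is.null(pcc)) igraph::E(g)$pcc <- pcc[cbind(edges$u, edges$v)]
  }
  g
}

#' Newman modularity of a partition
#'
#' Q = sum_c (e_c - a_c^2), where e_c is the fraction of edges inside
#' community c and a_c the fraction of edge endpoints in c. Edges are
#' unweighted.
#'
#' @param graph an `igraph` graph with >= 1 edge.
#' @param membership community id per vertex (named or in vertex order).
#' @return Q in [-0.5, 1].
#' @export
modularity_q <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("modularity undefined for an edgeless graph")
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(graph)$name]
  el <- igraph::as_edgelist(graph, names = FALSE)
  cu <- membership[el[, 1]]; cv <- membership[el[, 2]]
  e_c <- tapply(as.numeric(cu == cv), cu, sum)
  e_in <- sum(e_c, na.rm = TRUE) / m
  ends <- c(cu, cv)
  a <- table(ends) / (2 * m)
  e_in - sum(a^2)
}

#' Fast-greedy modularity communities (agglomerative)
#'
#' Greedy modularity agglomeration: starting from singleton communities, the
#' pair of connected communities with the largest modularity gain is merged
#' repeatedly (ties broken by the lexicographically smallest community-id
#' pair) until no connected pair remains; the partition attaining the maximum
#' modularity along the merge path is returned. Deterministic.
#'
#' @param graph an `igraph` graph with >= 1 edge.
#' @return list of class `community_partition`: `membership` (named integer,
#'   communities numbered 1..k in order of first member) and `q`.
#' @export
fast_greedy_communities <- function(graph) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("community detection undefined for an edgeless graph")
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  el <- igraph::as_edgelist(graph, names = FALSE)

  # B[c, d]: number of edges between communities c and d (diag: within)
  B <- matrix(0, n, n)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1]; j <- el[k, 2]
    if (i == j) B[i, i] <- B[i, i] + 1
    else { B[i, j] <- B[i, j] + 1; B[j, i] <- B[j, i] + 1 }
  }
  a <- (2 * diag(B) + rowSums(B) - diag(B)) / (2 * m)
  active <- rep(TRUE, n)
  comm <- seq_len(n)

  q <- sum(diag(B)) / m - sum(a^2)
  best_q <- q
  best_comm <- comm

  repeat {
    # merging c,d changes Q by 2(e_cd - a_c a_d) with e_cd = B_cd / (2m)
    dq <- B / m - 2 * outer(a, a)
    dq[B == 0] <- -Inf
    dq[!active, ] <- -Inf; dq[, !active] <- -Inf
    dq[lower.tri(dq, diag = TRUE)] <- -Inf
    mx <- max(dq)
    if (!is.finite(mx)) break
    hits <- which(dq == mx, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    c1 <- hits[1, 1]; c2 <- hits[1, 2]

    # merge c2 into c1
    old11 <- B[c1, c1]; old22 <- B[c2, c2]; old12 <- B[c1, c2]
    B[c1, ] <- B[c1, ] + B[c2, ]
    B[, c1] <- B[, c1] + B[, c2]
    B[c1, c1] <- old11 + old22 + old12
    B[c2, ] <- 0; B[, c2] <- 0
    a[c1] <- a[c1] + a[c2]; a[c2] <- 0
    active[c2] <- FALSE
    comm[comm == c2] <- c1
    q <- q + mx
    if (q > best_q + 1e-12) { best_q <- q; best_comm <- comm }
  }

  membership <- match(best_comm, unique(best_comm))
  names(membership) <- nodes
  structure(list(membership = membership, q = best_q),
            class = "community_partition")
}

#' Bait-centred candidate report
#'
#' For every bait, lists its non-bait network neighbors sorted by ascending
#' HRR, then descending PCC, then id, with community membership and any
#' annotation keywords; also summarizes communities (size, member baits,
#' candidate counts), largest first.
#'
#' @param network graph from [build_network()].
#' @param partition `community_partition` from [fast_greedy_communities()].
#' @param annotations optional keyword data.frame (`transcript_id`,
#'   `keyword`).
#' @return list with `candidates` and `communities` data.frames.
#' @export
candidate_report <- function(network, partition, annotations = NULL) {
  memb <- partition$membership
  if (!all(igraph::V(network)$name %in% names(memb)))
    stop("partition does not cover the network")
  vnames <- igraph::V(network)$name
  is_bait <- setNames(igraph::V(network)$is_bait, vnames)

  el <- igraph::as_edgelist(network)
  if (nrow(el) > 0) {
    edf <- data.frame(u = el[, 1], v = el[, 2],
                      hrr = igraph::E(network)$hrr,
                      pcc = if (!is.null(igraph::E(network)$pcc))
                        igraph::E(network)$pcc else NA_real_,
                      stringsAsFactors = FALSE)
    both <- rbind(edf, setNames(edf[, c(2, 1, 3, 4)], names(edf)))
    cand <- both[is_bait[both$u] & !is_bait[both$v], , drop = FALSE]
  } else {
    cand <- data.frame(u = character(), v = character(), hrr = numeric(),
                       pcc = numeric(), stringsAsFactors = FALSE)
  }
  names(cand) <- c("bait", "gene", "hrr", "pcc")
  cand$community <- unname(memb[cand$gene])
  cand$same_community <- unname(memb[cand$gene] == memb[cand$bait])
  if (!is.null(annotations)) {
    kw <- vapply(split(annotations$keyword, annotations$transcript_id),
                 paste, character(1), collapse = ";")
    cand$keywords <- unname(kw[cand$gene])
    cand$keywords[is.na(cand$keywords)] <- ""
  }
  cand <- cand[order(cand$bait, cand$hrr, -cand$pcc, cand$gene,
                     method = "radix"), , drop = FALSE]
  rownames(cand) <- NULL

  comm_rows <- lapply(split(names(memb)[names(memb) %in% vnames],
                            memb[names(memb) %in% vnames]), function(members) {
    b <- members[is_bait[members]]
    data.frame(community = memb[members[1]], size = length(members),
               n_baits = length(b),
               baits = paste(sort(b, method = "radix"), collapse = ";"),
               n_candidates = length(members) - length(b),
               stringsAsFactors = FALSE)
  })
  communities <- do.call(rbind, comm_rows)
  communities <- communities[order(-communities$size, communities$community), ,
                             drop = FALSE]
  rownames(communities) <- NULL
  list(candidates = cand, communities = communities)
}

#' Filter candidates by tissue expression profile
#'
#' Retains candidates whose per-tissue mean TPM attains its maximum in the
#' given tissue set (default: the young aerial tissues YL and YS, the
#' expression pattern expected of alkaloid-pathway genes).
#'
#' @param candidates data.frame with a `gene` column (or character vector).
#' @param tpm TPM matrix.
#' @param meta sample metadata (`sample_id`, `tissue`).
#' @param tissues tissue labels where the maximum must lie.
#' @return the filtered candidates.
#' @export
profile_filter <- function(candidates, tpm, meta, tissues = c("YL", "YS")) {
  genes <- if (is.data.frame(candidates)) candidates$gene else candidates
  if (!all(tissues %in% meta$tissue))
    stop("unknown tissue in pattern: ",
         paste(setdiff(tissues, meta$tissue), collapse = ", "))
  if (!all(genes %in% rownames(tpm)))
    stop("candidates missing from the TPM matrix")
  tiss_means <- sapply(unique(meta$tissue), function(t) {
    rowMeans(tpm[genes, meta$sample_id[meta$tissue == t], drop = FALSE])
  })
  if (length(genes) == 1)
    tiss_means <- matrix(tiss_means, nrow = 1,
                         dimnames = list(genes, unique(meta$tissue)))
  mx <- apply(tiss_means, 1, max)
  in_set <- apply(tiss_means[, tissues, drop = FALSE], 1, max)
  keep <- in_set >= mx
  if (is.data.frame(candidates)) candidates[keep, , drop = FALSE]
  else candidates[keep]
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param network graph from [build_network()].
#' @param edge_tsv path for the edge list (u, v, hrr, pcc).
#' @param graphml optional path for a GraphML export with node attributes.
#' @param partition optional `community_partition`; adds a `community` node
#'   attribute.
#' @return invisibly, the paths written.
#' @export
write_network <- function(network, edge_tsv, graphml = NULL,
                          partition = NULL) {
  el <- igraph::as_edgelist(network)
  edf <- data.frame(u = el[, 1], v = el[, 2], stringsAsFactors = FALSE)
  if (nrow(edf) > 0) {
    edf$hrr <- igraph::E(network)$hrr
    if (!is.null(igraph::E(network)$pcc)) edf$pcc <- igraph::E(network)$pcc
  }
  write.table(edf, edge_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml)) {
    if (!is.null(partition))
      igraph::V(network)$community <-
        unname(partition$membership[igraph::V(network)$name])
    igraph::write_graph(network, graphml, format = "graphml")
  }
  invisible(c(edge_tsv, graphml))
}
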