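# The default synthetic study: 2000 genes, 5 modules of 50, eight-fold
# module activity, common dispersion 0.168531, 4 tissues x 2 replicates,
# seed 42. Built once and shared across test files.
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42)
      ds <- generate_expression_dataset(cfg)
      ds$annotations <- generate_annotations(ds$truth, cfg)
      ds$config <- cfg
      ds$baits <- names(ds$truth$module_of)[which(ds$truth$module_of == 1)][1:10]
      cache <<- ds
    }
    cache
  }
})

# Edge-level recovery of the planted pathway module from a bait-anchored
# network: precision = fraction of bait-incident edges joining two module
# members; recall = fraction of (bait, module member) pairs captured.
module_recovery <- function(network, baits, module_genes) {
  el <- igraph::as_edgelist(network)
  within <- (el[, 1] %in% module_genes) & (el[, 2] %in% module_genes)
  precision <- if (nrow(el)) mean(within) else NA_real_
  vs <- igraph::V(network)$name
  pairs <- 0; captured <- 0
  for (b in baits) for (m in setdiff(module_genes, b)) {
    if (m %in% baits && m < b) next  # unordered bait-bait pairs once
    pairs <- pairs + 1
    if (b %in% vs && m %in% vs &&
        igraph::are_adjacent(network, b, m)) captured <- captured + 1
  }
  list(precision = precision, recall = captured / pairs,
       n_edges = nrow(el))
}
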