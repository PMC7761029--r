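#' Run the full guilt-by-association analysis chain
#'
#' Convenience driver over the package's stages: TPM normalization,
#' low-expression filtering, replicate QC, per-tissue-pair differential
#' expression with the exact conditional test, the HRR co-expression network
#' anchored on the supplied baits, fast-greedy communities, keyword
#' enrichment of the captured candidate set, and the bait-centred candidate
#' report. Optionally writes every table (and a GraphML export) under
#' `out_dir`; outputs are byte-stable given identical inputs.
#'
#' @param counts a [count_matrix()].
#' @param meta sample metadata (`sample_id`, `tissue`).
#' @param baits character vector of bait gene ids.
#' @param annotations optional keyword table (`transcript_id`, `keyword`).
#' @param tpm_threshold low-expression cutoff (strict, default 5).
#' @param tau HRR capture threshold (strict, default 100).
#' @param phi common dispersion for the exact test; `NULL` estimates it.
#' @param p_thresh,lfc_thresh DEG decision thresholds (strict).
#' @param capture network capture mode, see [build_network()].
#' @param out_dir optional output directory for TSV/GraphML files.
#' @return list with `tpm`, `qc`, `dispersion`, `dge` (all comparisons,
#'   direction-called), `overlaps`, `network`, `partition`, `report`,
#'   `enrichment`.
#' @export
run_gba_pipeline <- function(counts, meta, baits, annotations = NULL,
                             tpm_threshold = 5, tau = 100, phi = NULL,
                             p_thresh = 0.01, lfc_thresh = 2,
                             capture = "bait", out_dir = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  tpm <- compute_tpm(counts)
  tpm_f <- filter_low_expression(tpm, threshold = tpm_threshold)
  qc <- replicate_qc(tpm_f, meta)

  groups <- meta$tissue[match(colnames(counts$counts), meta$sample_id)]
  if (is.null(phi))
    phi <- estimate_common_dispersion(counts$counts, groups)$phi

  tiss <- unique(meta$tissue)
  dge <- list()
  for (i in seq_along(tiss)) for (j in seq_along(tiss)) {
    if (i >= j) next
    res <- run_dge(counts$counts[rownames(tpm_f), , drop = FALSE], groups,
                   tiss[i], tiss[j], phi = phi)
    dge[[length(dge) + 1]] <- call_degs(res, p_thresh, lfc_thresh)
  }
  dge <- do.call(rbind, dge)
  up_sets <- lapply(split(dge, dge$comparison),
                    function(d) d$gene[d$direction == "up"])
  overlaps <- if (length(up_sets) >= 2) deg_set_overlaps(up_sets) else NULL

  log_expr <- log_transform(tpm_f)
  corr <- pcc_matrix(log_expr)
  ranks <- rank_neighbors(corr)
  hrr <- hrr_matrix(ranks)
  network <- build_network(hrr, baits, tau = tau, capture = capture,
                           pcc = corr)
  partition <- fast_greedy_communities(network)
  report <- candidate_report(network, partition, annotations)

  enrichment <- NULL
  if (!is.null(annotations)) {
    captured <- setdiff(igraph::V(network)$name, baits)
    if (length(captured))
      enrichment <- keyword_enrichment(captured, rownames(tpm_f), annotations)
  }

  out <- list(tpm = tpm_f, qc = qc, dispersion = phi, dge = dge,
              overlaps = overlaps, network = network, partition = partition,
              report = report, enrichment = enrichment)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(qc, "qc.tsv")
    wt(dge, "dge.tsv")
    if (!is.null(overlaps)) wt(overlaps, "deg_overlaps.tsv")
    wt(report$candidates, "candidates.tsv")
    wt(report$communities, "communities.tsv")
    if (!is.null(enrichment)) wt(enrichment, "enrichment.tsv")
    write_network(network, file.path(out_dir, "network_edges.tsv"),
                  file.path(out_dir, "network.graphml"), partition)
  }
  out
}
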