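#!/usr/bin/env Rscript
# Differential expression between every tissue pair with the exact
# conditional negative-binomial test (p < 0.01, |log2 FC| > 2, both strict),
# UpSet-style exclusive overlaps of the up-regulated sets, and hypergeometric
# keyword enrichment of the young-aerial DEGs.

suppressMessages(library(gbanet))
if (!dir.exists("results/fixture")) stop("run analysis/01_simulate.R first")
fx <- read_fixture("results/fixture")

groups <- fx$meta$tissue[match(colnames(fx$counts$counts),
                               fx$meta$sample_id)]
phi_hat <- estimate_common_dispersion(fx$counts$counts, groups)$phi
message("estimated common dispersion: ", round(phi_hat, 4),
        " (BCV ", round(sqrt(phi_hat), 3), ")")

tiss <- unique(fx$meta$tissue)
dge <- do.call(rbind, lapply(which(upper.tri(diag(length(tiss)))), function(k) {
  ij <- arrayInd(k, rep(length(tiss), 2))
  call_degs(run_dge(fx$counts, groups, tiss[ij[1]], tiss[ij[2]],
                    phi = phi_hat))
}))
write.table(dge, "results/dge.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

counts_by_cmp <- table(dge$comparison[dge$direction != "ns"])
message("DEGs per comparison:")
for (cmp in names(counts_by_cmp))
  message("  ", cmp, ": ", counts_by_cmp[[cmp]])

pd <- fx$truth$planted_degs
hit <- paste(dge$comparison, dge$gene)[dge$direction != "ns"]
message("planted DEG recovery: ",
        round(mean(paste(pd$comparison, pd$gene) %in% hit), 3))

up_sets <- lapply(split(dge, dge$comparison),
                  function(d) d$gene[d$direction == "up"])
ov <- deg_set_overlaps(up_sets)
write.table(ov, "results/deg_overlaps.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# keyword enrichment of genes higher in young leaves than in roots
# (logFC in "YL vs AR" is AR relative to YL, so YL-high genes are "down")
yl <- dge$gene[dge$comparison == "YL vs AR" & dge$direction == "down"]
enr <- keyword_enrichment(yl, rownames(fx$counts$counts), fx$keywords)
write.table(enr, "results/enrichment_dge.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top enrichment for the YL-high set (n = ", length(yl), "): ",
        enr$keyword[1], " (p = ", signif(enr$pvalue[1], 3), ")")
message("wrote results/dge.tsv, results/deg_overlaps.tsv, results/enrichment_dge.tsv")
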