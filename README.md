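# gbanet

Guilt-by-association candidate gene discovery from multi-tissue RNA-seq.

`gbanet` re-implements, as a tested R package, the computational chain used
to nominate monoterpene indole alkaloid (MIA) biosynthesis candidates from a
four-tissue *Vinca minor* transcriptome: expression normalization and
filtering, redundancy compaction of a merged de novo assembly, exact
negative-binomial differential expression, homology-based conservation
tiering against known pathway ("bait") genes, and — at its core — a
**highest-reciprocal-rank (HRR) co-expression network** with fast-greedy
modularity communities and bait-anchored candidate reports. It is aimed at
plant specialized-metabolism groups (and anyone doing guilt-by-association
on non-model transcriptomes) who want each stage of that chain as an
auditable, unit-tested function rather than a one-off script.

Because the original sequencing data are not required, the package ships a
seeded synthetic-data generator that reproduces the statistical structure
the analysis assumes — negative-binomial counts at common dispersion
φ = 0.168531 (BCV ≈ 0.4), four tissues × two replicates, planted
co-expression modules with tissue-specific activity, planted differential
expression, redundant transcript variants, and bait homologs at controlled
percent identity — so every stage is testable against known ground truth.

## The statistics at the core

**HRR.** For genes *i*, *j*, Pearson correlations r(i,·) over all samples of
log2(TPM+1) are ranked per gene (rank 1 = best, self excluded);

HRR(i, j) = max( rank_i(j), rank_j(i) ).

A bait-anchored network keeps every pair (bait, gene) with HRR < τ
(default τ = 100, strict). Communities are found by greedy modularity
agglomeration (Clauset–Newman–Moore): merge the connected community pair
with the largest ΔQ until none remains, and report the partition at the
maximum Q = Σ_c (e_c − a_c²) reached along the merge path.

**Exact test.** For a two-group comparison with equalized library sizes and
common dispersion φ, the group-A sum given the total T is enumerated from
the convolution NB(n_A μ, φ/n_A) ⊗ NB(n_B μ, φ/n_B) over 0..T; the
two-sided p sums all outcomes with probability ≤ that of the observed one
(at φ = 0 this is the exact binomial test). Genes with p < 0.01 and
|log2 FC| > 2 (both strict) are called differentially expressed.

## Worked example

```r
library(gbanet)

cfg <- sim_config(seed = 42)                     # the default study design
ds  <- generate_expression_dataset(cfg)          # counts + metadata + truth
ann <- generate_annotations(ds$truth, cfg)       # keyword table
baits <- names(ds$truth$module_of)[which(ds$truth$module_of == 1)][1:10]

res <- run_gba_pipeline(ds$counts, ds$meta, baits,
                        annotations = ann, phi = 0.168531)

res$qc                       # within-tissue replicate correlations
head(res$report$candidates)  # per-bait candidates by ascending HRR
head(res$enrichment, 2)      # keyword enrichment of captured genes
```

Replicate QC — every within-tissue pair exceeds the 0.9 Spearman threshold:

```
  tissue sample_a sample_b       rho pass
1     AR      AR1      AR2 0.9194818 TRUE
2     OL      OL1      OL2 0.9216447 TRUE
3     YL      YL1      YL2 0.9294674 TRUE
4     YS      YS1      YS2 0.9181640 TRUE
```

The first candidates of bait `g0001` (a planted young-aerial module member):
`g0036` is mutually top-ranked with the bait (HRR = 1, PCC 0.99) and sits in
the bait's community — exactly the guilt-by-association signal the network
is built to surface:

```
   bait  gene hrr       pcc community same_community
1 g0001 g0036   1 0.9904476         1           TRUE
2 g0001 g0040   3 0.9674322         3          FALSE
3 g0001 g0030   7 0.9773850         4          FALSE
```

The planted keyword dominates the enrichment of the captured candidate set
(40 of the 145 keyword-bearing genes among 182 captured, universe 1980):

```
                keyword  k   K   n    N       pvalue
1 alkaloid biosynthesis 40 145 182 1980 1.559247e-11
2            keyword_03 12 103 182 1980 2.316829e-01
```

The network itself has 192 nodes and 914 edges at HRR < 100 and resolves
into four communities (Q = 0.142), each anchored by two or three baits.

The numbered scripts under `analysis/` run the same chain step by step
(simulation, QC, compaction, differential expression, homology tiering,
network) and write their tables under `results/`.

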