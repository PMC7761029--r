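test_that("generators are deterministic given the same config and seed", {
  cfg <- sim_config(n_genes = 120, n_modules = 2, module_size = 15, seed = 3)
  d1 <- generate_expression_dataset(cfg)
  d2 <- generate_expression_dataset(cfg)
  expect_identical(d1$counts$counts, d2$counts$counts)
  expect_identical(d1$counts$lengths, d2$counts$lengths)
  expect_identical(d1$truth$planted_degs, d2$truth$planted_degs)

  s1 <- generate_sequence_fixtures(cfg)
  s2 <- generate_sequence_fixtures(cfg)
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$baits, s2$baits)

  a1 <- generate_annotations(d1$truth, cfg)
  a2 <- generate_annotations(d2$truth, cfg)
  expect_identical(a1, a2)
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_genes = 10, n_modules = 3, module_size = 5),
               "overcommit")
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(module_fold = 0.5), "module_fold")
  expect_error(sim_config(identity_targets = c(0.9, 1.2)), "identity_targets")
})

test_that("no activity effect means no planted differential expression", {
  cfg <- sim_config(n_genes = 100, n_modules = 2, module_size = 10,
                    module_fold = 1, seed = 4)
  ds <- generate_expression_dataset(cfg)
  expect_equal(nrow(ds$truth$planted_degs), 0)
})

test_that("planted DEGs come from modules whose activity differs (truth consistency)", {
  for (seed in 1:4) {
    cfg <- sim_config(n_genes = 150, n_modules = 4, module_size = 12,
                      seed = seed)
    ds <- generate_expression_dataset(cfg)
    pd <- ds$truth$planted_degs
    expect_gt(nrow(pd), 0)
    expect_true(all(pd$gene %in% names(ds$truth$module_of)))
    for (r in seq_len(nrow(pd))) {
      m <- ds$truth$module_of[pd$gene[r]]
      expect_false(is.na(m))
      ts <- strsplit(pd$comparison[r], " vs ")[[1]]
      expect_true(ds$truth$activity[m, ts[1]] != ds$truth$activity[m, ts[2]])
    }
  }
})

test_that("counts follow the negative-binomial moments", {
  # flat baseline makes every gene's expected count library_size / n_genes
  # exactly, so replicate datasets give iid draws at a known mean
  n_genes <- 100; lib <- 1e5; phi <- 0.168531
  mu <- lib / n_genes
  draws <- vapply(1:200, function(s) {
    cfg <- sim_config(n_genes = n_genes, n_modules = 0, module_size = 0,
                      library_size = lib, dispersion = phi,
                      baseline_log_sd = 0, seed = s)
    generate_expression_dataset(cfg)$counts$counts[1, 1]
  }, numeric(1))
  se <- sqrt((mu + phi * mu^2) / 200)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("zero dispersion gives Poisson-like variance/mean ratios", {
  cfg <- sim_config(n_genes = 500, n_modules = 0, module_size = 0,
                    library_size = 5e5, dispersion = 0,
                    baseline_log_sd = 0, seed = 12)
  cnt <- generate_expression_dataset(cfg)$counts$counts
  # pooled (n_s - 1) * s^2 / mean ~ chi-square with 500 * 7 df under Poisson
  stat <- sum(apply(cnt, 1, function(x) (length(x) - 1) * var(x) / mean(x)))
  df <- 500 * (ncol(cnt) - 1)
  expect_gt(stat, qchisq(5e-4, df))
  expect_lt(stat, qchisq(1 - 5e-4, df))
})

test_that("homolog fixtures hit their identity targets", {
  cfg <- sim_config(identity_targets = c(1.0, 0.85, 0.75), seed = 21)
  sq <- generate_sequence_fixtures(cfg)
  sch <- scoring_scheme(mode = "global")
  it <- sq$truth$identity_targets

  # exact copy at target 1.0
  expect_identical(sq$transcripts[[it$homolog[1]]], sq$baits[[it$bait[1]]])
  al <- align_pair(sq$baits[[it$bait[1]]], sq$transcripts[[it$homolog[1]]], sch)
  expect_equal(al$pct_identity, 100)

  for (r in 2:3) {
    al <- align_pair(sq$baits[[it$bait[r]]], sq$transcripts[[it$homolog[r]]],
                     sch)
    expect_lt(abs(al$identities / al$aln_length - it$identity[r]), 0.03)
  }
  expect_error(generate_sequence_fixtures(
    sim_config(identity_targets = 0)), "identity")
})

test_that("independent random sequences align far below the homolog targets", {
  # random DNA matches ~25% of positions, but optimal gap placement pushes
  # global-alignment identity to just above one half; the empirical bound
  # over these draws is 0.513, well below the weakest homolog target (0.75)
  set.seed(33)
  sch <- scoring_scheme(mode = "global")
  for (i in 1:50) {
    al <- align_pair(rdna(1000), rdna(1000), sch)
    expect_lt(al$identities / al$aln_length, 0.55)
  }
})

test_that("redundancy members derive from their representative", {
  cfg <- sim_config(seed = 8)
  sq <- generate_sequence_fixtures(cfg)
  sch <- scoring_scheme()  # local
  for (rep_id in names(sq$truth$redundancy_groups)) {
    for (mem in setdiff(sq$truth$redundancy_groups[[rep_id]], rep_id)) {
      al <- align_pair(sq$transcripts[[rep_id]], sq$transcripts[[mem]], sch)
      expect_gt(al$identities / al$aln_length, 0.9)
      expect_gt(al$coverage_subject, 0.8)
    }
  }
})

test_that("annotation planting obeys its fractions", {
  genes <- sprintf("g%03d", 1:200)
  truth <- structure(list(
    module_of = setNames(c(rep(1L, 30), rep(NA_integer_, 170)), genes),
    keyword_module = 1L, enriched_keyword = "kw"), class = "sim_truth")

  cfg <- sim_config(n_genes = 200, n_modules = 1, module_size = 30,
                    keyword_module_fraction = 1,
                    keyword_background_rate = 0, seed = 7)
  ann <- generate_annotations(truth, cfg)
  planted <- ann$transcript_id[ann$keyword == "kw"]
  expect_equal(sort(planted), genes[1:30])

  # determinism: the same seed reproduces the same Bernoulli assignments
  cfg2 <- sim_config(n_genes = 200, n_modules = 1, module_size = 30, seed = 7)
  expect_identical(generate_annotations(truth, cfg2),
                   generate_annotations(truth, cfg2))

  expect_error(sim_config(keyword_module_fraction = 1.4), "fractions")
})

test_that("enrichment p of an unplanted keyword is calibrated (null)", {
  genes <- sprintf("g%03d", 1:500)
  truth <- structure(list(
    module_of = setNames(c(rep(1L, 40), rep(NA_integer_, 460)), genes),
    keyword_module = 1L, enriched_keyword = "kw"), class = "sim_truth")
  ps <- vapply(1:200, function(s) {
    cfg <- sim_config(n_genes = 500, n_modules = 1, module_size = 40,
                      keyword_module_fraction = 0.05,
                      keyword_background_rate = 0.05, seed = s)
    ann <- generate_annotations(truth, cfg, n_decoy_keywords = 0)
    enr <- keyword_enrichment(genes[1:40], genes, ann)
    enr$pvalue[enr$keyword == "kw"]
  }, numeric(1))
  # exact-test p-values are discrete and super-uniform; check the
  # anti-conservative direction only
  expect_lte(mean(ps < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  ks <- suppressWarnings(ks.test(ps, "punif", alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})

test_that("fixtures round-trip through write_fixture and read_fixture", {
  cfg <- sim_config(n_genes = 60, n_modules = 2, module_size = 10,
                    n_redundancy_groups = 2, n_background_seqs = 5, seed = 5)
  ds <- generate_expression_dataset(cfg)
  sq <- generate_sequence_fixtures(cfg, ds$truth)
  ds$truth <- sq$truth
  ds$transcripts <- sq$transcripts
  ds$baits <- sq$baits
  ds$keywords <- generate_annotations(ds$truth, cfg)

  dir <- withr::local_tempdir()
  write_fixture(ds, dir)
  expect_error(write_fixture(ds, dir), "overwrite")
  back <- read_fixture(dir)

  expect_identical(back$counts$counts, ds$counts$counts)
  expect_equal(back$counts$lengths, ds$counts$lengths)
  expect_identical(back$transcripts, ds$transcripts)
  expect_identical(back$baits, ds$baits)
  expect_identical(back$keywords, ds$keywords)
  expect_identical(back$truth$module_of, ds$truth$module_of)
  expect_identical(
    lapply(back$truth$redundancy_groups, identity),
    ds$truth$redundancy_groups)
  expect_equal(back$truth$identity_targets$identity,
               ds$truth$identity_targets$identity)

  # FASTA conservation: one record per transcript and per bait
  expect_length(back$transcripts, length(sq$transcripts))
  expect_length(back$baits, length(cfg$identity_targets))

  expect_error(write_fixture(list(counts = NULL), withr::local_tempdir()),
               "empty")
})
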