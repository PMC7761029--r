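#' Simulation configuration for synthetic multi-tissue RNA-seq datasets
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generators. The defaults emulate a four-tissue, two-replicate bulk
#' RNA-seq design: young leaves (YL), young stems (YS), old leaves (OL) and
#' arial roots (AR), with negative-binomial counts at a common dispersion of
#' 0.168531 (biological coefficient of variation ~0.4, typical for plant
#' tissue panels), five planted co-expression modules of 50 genes each, and
#' an eight-fold multiplicative activity effect.
#'
#' Each module is active in exactly two tissues. The default activity
#' patterns -- \{YL,YS\}, \{YL,OL\}, \{YL,AR\}, \{OL,AR\}, \{YS,AR\} -- have
#' pairwise orthogonal or negatively correlated mean profiles, so planted
#' modules do not leak correlation into one another. Module 1 (young aerial
#' tissues) plays the role of the specialized-metabolism pathway module and
#' carries the planted annotation keyword.
#'
#' @param n_genes total number of genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size genes per module; `n_modules * module_size` must not
#'   exceed `n_genes`.
#' @param tissues character vector of tissue labels.
#' @param replicates_per_tissue biological replicates per tissue.
#' @param library_size expected reads per sample.
#' @param dispersion negative-binomial dispersion phi (variance =
#'   mu + phi * mu^2); 0 gives Poisson counts.
#' @param module_fold multiplicative effect (>= 1) applied to a module
#'   gene's expression proportion in tissues where the module is active.
#' @param baseline_log_mean,baseline_log_sd parameters of the log-normal
#'   distribution of baseline expression proportions (natural-log scale).
#' @param activity optional logical matrix (`n_modules` x `length(tissues)`)
#'   of module activity; a default balanced two-tissue design is used when
#'   omitted (requires 4 tissues and <= 5 modules).
#' @param n_redundancy_groups,redundancy_group_size redundancy structure of
#'   the sequence fixture: number of transcript groups and members per group
#'   (representative included).
#' @param n_background_seqs unrelated background transcripts in the
#'   sequence fixture.
#' @param identity_targets fractional identities (0, 1] at which bait
#'   homologs are planted, one homolog per target.
#' @param bait_length length (nt) of simulated bait genes.
#' @param keyword_module_fraction fraction of the designated module's genes
#'   that carry the planted keyword.
#' @param keyword_background_rate rate at which keywords are assigned to
#'   genes outside their target set.
#' @param seed integer seed; all generators are deterministic given the
#'   configuration (seed included).
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_modules = 5,
                       module_size = 50,
                       tissues = c("YL", "YS", "OL", "AR"),
                       replicates_per_tissue = 2,
                       library_size = 1e6,
                       dispersion = 0.168531,
                       module_fold = 8,
                       baseline_log_mean = 0,
                       baseline_log_sd = 1.5,
                       activity = NULL,
                       n_redundancy_groups = 5,
                       redundancy_group_size = 4,
                       n_background_seqs = 80,
                       identity_targets = c(0.95, 0.85, 0.75),
                       bait_length = 1200,
                       keyword_module_fraction = 0.8,
                       keyword_background_rate = 0.05,
                       seed = 1L) {
  stopifnot(length(tissues) >= 1, !anyDuplicated(tissues))
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_modules * module_size > n_genes)
    stop("module overcommit: n_modules * module_size (",
         n_modules * module_size, ") exceeds n_genes (", n_genes, ")")
  if (library_size <= 0) stop("library_size must be positive")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (module_fold < 1) stop("module_fold must be >= 1")
  if (replicates_per_tissue < 1) stop("replicates_per_tissue must be >= 1")
  if (any(identity_targets <= 0) || any(identity_targets > 1))
    stop("identity_targets must lie in (0, 1]")
  if (keyword_module_fraction < 0 || keyword_module_fraction > 1 ||
      keyword_background_rate < 0 || keyword_background_rate > 1)
    stop("keyword fractions must lie in [0, 1]")

  if (is.null(activity)) {
    activity <- default_activity(n_modules, tissues)
  } else {
    activity <- as.matrix(activity)
    if (!is.logical(activity) || nrow(activity) != n_modules ||
        ncol(activity) != length(tissues))
      stop("activity must be a logical n_modules x n_tissues matrix")
    colnames(activity) <- tissues
  }

  cfg <- list(
    n_genes = as.integer(n_genes), n_modules = as.integer(n_modules),
    module_size = as.integer(module_size), tissues = tissues,
    replicates_per_tissue = as.integer(replicates_per_tissue),
    library_size = library_size, dispersion = dispersion,
    module_fold = module_fold,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    activity = activity,
    n_redundancy_groups = as.integer(n_redundancy_groups),
    redundancy_group_size = as.integer(redundancy_group_size),
    n_background_seqs = as.integer(n_background_seqs),
    identity_targets = identity_targets, bait_length = as.integer(bait_length),
    keyword_module_fraction = keyword_module_fraction,
    keyword_background_rate = keyword_background_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Balanced two-tissue activity patterns; pairwise orthogonal or
# anti-correlated mean profiles over 4 tissues for up to 5 modules.
default_activity <- function(n_modules, tissues) {
  if (length(tissues) != 4 && n_modules > 1)
    stop("the default activity design requires 4 tissues; supply `activity`")
  pat <- list(c(1, 2), c(1, 3), c(1, 4), c(3, 4), c(2, 4))
  if (n_modules > length(pat))
    stop("default activity design supports at most 5 modules; supply `activity`")
  act <- matrix(FALSE, n_modules, length(tissues),
                dimnames = list(NULL, tissues))
  for (m in seq_len(n_modules)) act[m, pat[[m]]] <- TRUE
  act
}

#' Generate a synthetic expression dataset with planted modules
#'
#' Draws a gene-by-sample matrix of negative-binomial read counts with
#' log-normal baseline expression proportions. Genes assigned to a planted
#' module have their proportion multiplied by `module_fold` in tissues where
#' the module is active; per-sample expected proportions are renormalized to
#' sum to one before counts are drawn. Transcript lengths are drawn uniformly
#' in 500--2000 nt.
#'
#' @param config a [sim_config()] object.
#' @return a list with components `counts` (a [count_matrix()]), `meta`
#'   (sample metadata data.frame with `sample_id`, `tissue`, `condition`,
#'   `replicate`), and `truth` (ground truth: `module_of`, `activity`,
#'   `planted_degs`, `enriched_keyword`, `keyword_module`).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  genes <- sprintf("g%04d", seq_len(config$n_genes))
  module_of <- rep(NA_integer_, config$n_genes)
  if (config$n_modules > 0)
    module_of[seq_len(config$n_modules * config$module_size)] <-
      rep(seq_len(config$n_modules), each = config$module_size)
  names(module_of) <- genes

  meta <- expand.grid(replicate = seq_len(config$replicates_per_tissue),
                      tissue = config$tissues, stringsAsFactors = FALSE)
  meta <- meta[, c("tissue", "replicate")]
  meta$sample_id <- paste0(meta$tissue, meta$replicate)
  meta$condition <- "standard"
  meta <- meta[, c("sample_id", "tissue", "condition", "replicate")]

  base <- exp(rnorm(config$n_genes, config$baseline_log_mean,
                    config$baseline_log_sd))
  lengths <- sample(500:2000, config$n_genes, replace = TRUE)
  names(lengths) <- genes

  counts <- matrix(0L, config$n_genes, nrow(meta),
                   dimnames = list(genes, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    p <- base
    for (m in seq_len(config$n_modules)) {
      if (config$activity[m, meta$tissue[s]]) {
        idx <- which(module_of == m)
        p[idx] <- p[idx] * config$module_fold
      }
    }
    p <- p / sum(p)
    mu <- config$library_size * p
    counts[, s] <- if (config$dispersion > 0)
      rnbinom(config$n_genes, mu = mu, size = 1 / config$dispersion)
    else
      rpois(config$n_genes, mu)
  }

  truth <- list(
    module_of = module_of,
    activity = config$activity,
    planted_degs = planted_deg_table(config, module_of),
    enriched_keyword = "alkaloid biosynthesis",
    keyword_module = if (config$n_modules >= 1) 1L else NA_integer_
  )
  class(truth) <- "sim_truth"

  list(counts = count_matrix(counts, lengths), meta = meta, truth = truth)
}

# Planted DEGs: for each ordered tissue pair (a, b), module genes whose
# activity differs; direction is relative to b (logFC = log2(b / a)).
planted_deg_table <- function(config, module_of) {
  out <- list()
  if (config$module_fold > 1 && config$n_modules > 0) {
    tiss <- config$tissues
    for (i in seq_along(tiss)) for (j in seq_along(tiss)) {
      if (i >= j) next
      a <- tiss[i]; b <- tiss[j]
      for (m in seq_len(config$n_modules)) {
        aa <- config$activity[m, a]; ab <- config$activity[m, b]
        if (aa == ab) next
        out[[length(out) + 1]] <- data.frame(
          comparison = paste(a, "vs", b),
          gene = names(module_of)[which(module_of == m)],
          direction = if (ab && !aa) "up" else "down",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(comparison = character(), gene = character(),
                      direction = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence at the given per-position rate; substitutions only,
# always to a different base, positions chosen uniformly without replacement.
mutate_seq <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  n_mut <- round(rate * length(chars))
  if (n_mut == 0) return(seq)
  pos <- sample(seq_along(chars), n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate sequence fixtures: bait homologs, redundancy groups, background
#'
#' Emits (a) one homolog transcript per bait and identity target, obtained by
#' substituting bases at rate `1 - target identity` at uniformly placed
#' positions; (b) redundancy groups consisting of a representative plus
#' substrings and near-copies (the material a merged multi-sample assembly
#' would contain twice); and (c) unrelated random background transcripts.
#' Substitution-only mutations are used for identity-target homologs; small
#' indels and truncations are reserved for redundancy-group members.
#'
#' @param config a [sim_config()] object.
#' @param truth optional `sim_truth` to update in place; a fresh truth object
#'   is created when omitted.
#' @return a list with `transcripts` (named character vector of transcript
#'   sequences), `baits` (named character vector), and `truth` (updated with
#'   `redundancy_groups` and `identity_targets`).
#' @export
generate_sequence_fixtures <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$identity_targets <= 0 | config$identity_targets > 1))
    stop("identity targets must lie in (0, 1]")
  set.seed(config$seed + 1L)

  transcripts <- character(0)
  baits <- character(0)

  # bait homologs at controlled identity
  id_rows <- list()
  for (i in seq_along(config$identity_targets)) {
    tgt <- config$identity_targets[i]
    bait_id <- sprintf("bait%02d", i)
    hom_id <- sprintf("hom%02d", i)
    bait_seq <- random_dna(config$bait_length)
    baits[bait_id] <- bait_seq
    transcripts[hom_id] <- mutate_seq(bait_seq, 1 - tgt)
    id_rows[[i]] <- data.frame(bait = bait_id, homolog = hom_id,
                               identity = tgt, stringsAsFactors = FALSE)
  }

  # redundancy groups: representative + substrings / near-copies
  groups <- list()
  for (g in seq_len(config$n_redundancy_groups)) {
    rep_id <- sprintf("red%02d_m1", g)
    rep_len <- sample(1200:1800, 1)
    rep_seq <- random_dna(rep_len)
    transcripts[rep_id] <- rep_seq
    members <- rep_id
    for (k in seq_len(config$redundancy_group_size - 1)) {
      mem_id <- sprintf("red%02d_m%d", g, k + 1)
      kind <- k %% 3
      if (kind == 1) {        # exact 5'/3' truncation covering >= 80%
        start <- sample(1:(rep_len - ceiling(0.85 * rep_len)), 1)
        mem <- substr(rep_seq, start, start + ceiling(0.85 * rep_len) - 1)
      } else if (kind == 2) { # near-copy, ~2% substitutions
        mem <- mutate_seq(rep_seq, 0.02)
        mem <- substr(mem, 1, rep_len - sample(5:30, 1))
      } else {                # truncated copy with a small internal deletion
        mem <- substr(rep_seq, 1, ceiling(0.9 * rep_len))
        cut <- sample(seq(100, nchar(mem) - 100), 1)
        del <- sample(3:12, 1)
        mem <- paste0(substr(mem, 1, cut), substr(mem, cut + del + 1, nchar(mem)))
      }
      transcripts[mem_id] <- mem
      members <- c(members, mem_id)
    }
    groups[[rep_id]] <- members
  }

  # unrelated background sequences
  for (b in seq_len(config$n_background_seqs)) {
    transcripts[sprintf("bg%03d", b)] <- random_dna(sample(500:2000, 1))
  }

  if (is.null(truth)) {
    truth <- structure(list(), class = "sim_truth")
  }
  truth$redundancy_groups <- groups
  truth$identity_targets <- do.call(rbind, id_rows)
  list(transcripts = transcripts, baits = baits, truth = truth)
}

#' Generate a transcript-to-keyword annotation table
#'
#' Plants one enriched keyword on a fraction of the designated module's genes
#' and at a background rate elsewhere; additional decoy keywords are assigned
#' at the background rate throughout. Emulates the keyword annotations a
#' UniProt-based annotation pipeline would attach to transcripts.
#'
#' @param truth a `sim_truth` with `module_of` and `keyword_module`.
#' @param config a [sim_config()] object.
#' @param n_decoy_keywords number of background-only keywords.
#' @return data.frame with columns `transcript_id`, `keyword`.
#' @export
generate_annotations <- function(truth, config, n_decoy_keywords = 5) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$module_of) || is.na(truth$keyword_module))
    stop("truth must designate a keyword module (run generate_expression_dataset)")
  set.seed(config$seed + 2L)

  genes <- names(truth$module_of)
  in_mod <- !is.na(truth$module_of) & truth$module_of == truth$keyword_module
  rows <- list()

  kw <- truth$enriched_keyword
  p <- ifelse(in_mod, config$keyword_module_fraction,
              config$keyword_background_rate)
  hit <- runif(length(genes)) < p
  if (any(hit))
    rows[[1]] <- data.frame(transcript_id = genes[hit], keyword = kw,
                            stringsAsFactors = FALSE)

  for (d in seq_len(n_decoy_keywords)) {
    dk <- sprintf("keyword_%02d", d)
    hit <- runif(length(genes)) < config$keyword_background_rate
    if (any(hit))
      rows[[length(rows) + 1]] <- data.frame(
        transcript_id = genes[hit], keyword = dk, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(transcript_id = character(), keyword = character(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a synthetic dataset to disk as plain-text fixture files
#'
#' Emits `counts.tsv`, `lengths.tsv`, `samples.tsv`, `transcripts.fasta`,
#' `baits.fasta`, `keywords.tsv` and `truth.json` into `out_dir`. The files
#' round-trip losslessly through [read_fixture()].
#'
#' @param dataset a list with `counts` ([count_matrix()]), `meta`,
#'   `truth`, and optionally `transcripts`, `baits` (named character
#'   vectors) and `keywords` (annotation data.frame).
#' @param out_dir output directory (created if needed).
#' @param overwrite overwrite existing files (default FALSE: error).
#' @return invisibly, the vector of files written.
#' @export
write_fixture <- function(dataset, out_dir, overwrite = FALSE) {
  if (is.null(dataset$counts) || nrow(dataset$counts$counts) == 0)
    stop("empty dataset: nothing to write")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  files <- file.path(out_dir, c("counts.tsv", "lengths.tsv", "samples.tsv",
                                "keywords.tsv", "transcripts.fasta",
                                "baits.fasta", "truth.json"))
  names(files) <- basename(files)
  existing <- files[file.exists(files)]
  if (length(existing) && !overwrite)
    stop("files already exist (use overwrite = TRUE): ",
         paste(basename(existing), collapse = ", "))

  cm <- dataset$counts
  counts_df <- data.frame(transcript_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write.table(counts_df, files["counts.tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(transcript_id = names(cm$lengths),
                         length = unname(cm$lengths)),
              files["lengths.tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(dataset$meta, files["samples.tsv"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(dataset$keywords))
    write.table(dataset$keywords, files["keywords.tsv"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$transcripts))
    write_fasta(dataset$transcripts, files["transcripts.fasta"])
  if (!is.null(dataset$baits))
    write_fasta(dataset$baits, files["baits.fasta"])

  truth <- dataset$truth
  tj <- list(
    module_of = as.list(truth$module_of),
    activity = if (!is.null(truth$activity))
      apply(truth$activity, 1, function(r) colnames(truth$activity)[r],
            simplify = FALSE),
    activity_note = "module activity patterns are a design choice of the generator",
    planted_degs = truth$planted_degs,
    redundancy_groups = truth$redundancy_groups,
    identity_targets = truth$identity_targets,
    enriched_keyword = truth$enriched_keyword,
    keyword_module = truth$keyword_module
  )
  jsonlite::write_json(tj, files["truth.json"], auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(files)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir fixture directory.
#' @return a list with the same structure as the input to [write_fixture()].
#' @export
read_fixture <- function(dir) {
  counts_df <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  lengths_df <- read.delim(file.path(dir, "lengths.tsv"),
                           stringsAsFactors = FALSE)
  cnt <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(cnt) <- counts_df[[1]]
  storage.mode(cnt) <- "integer"
  lengths <- setNames(lengths_df$length, lengths_df$transcript_id)
  meta <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)

  out <- list(counts = count_matrix(cnt, lengths), meta = meta)
  kw_path <- file.path(dir, "keywords.tsv")
  if (file.exists(kw_path))
    out$keywords <- read.delim(kw_path, stringsAsFactors = FALSE)
  tr_path <- file.path(dir, "transcripts.fasta")
  if (file.exists(tr_path)) out$transcripts <- read_fasta(tr_path)
  bt_path <- file.path(dir, "baits.fasta")
  if (file.exists(bt_path)) out$baits <- read_fasta(bt_path)

  tj <- jsonlite::read_json(file.path(dir, "truth.json"))
  truth <- list(
    module_of = setNames(
      vapply(tj$module_of, function(x) if (is.null(x)) NA_integer_
             else as.integer(x), integer(1)),
      names(tj$module_of)),
    planted_degs = if (length(tj$planted_degs))
      do.call(rbind, lapply(tj$planted_degs, as.data.frame))
    else data.frame(comparison = character(), gene = character(),
                    direction = character()),
    redundancy_groups = lapply(tj$redundancy_groups,
                               function(g) unlist(g, use.names = FALSE)),
    identity_targets = if (length(tj$identity_targets))
      do.call(rbind, lapply(tj$identity_targets, as.data.frame)),
    enriched_keyword = tj$enriched_keyword,
    keyword_module = if (is.null(tj$keyword_module)) NA_integer_
                     else as.integer(tj$keyword_module)
  )
  class(truth) <- "sim_truth"
  out$truth <- truth
  out
}

#' Write sequences to a FASTA file (60-column wrapped)
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}
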