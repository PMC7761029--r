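#' Equalize library sizes
#'
#' Rescales every sample column to the geometric mean of the observed library
#' sizes and rounds to integers. The exact conditional test downstream
#' assumes equal per-sample library sizes; this is the simplified analogue of
#' the quantile adjustment classic count-based testing performs.
#'
#' @param counts integer matrix (genes x samples).
#' @return integer matrix with (near-)equal column sums.
#' @export
equalize_libraries <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0)) stop("all-zero sample column")
  target <- exp(mean(log(libs)))
  out <- round(sweep(counts, 2, target / libs, "*"))
  storage.mode(out) <- "integer"
  out
}

#' Common negative-binomial dispersion by pooled method of moments
#'
#' For every gene, each group with >= 2 replicates contributes the moment
#' estimate (s^2 - mu) / mu^2 of the dispersion phi (from
#' Var = mu + phi mu^2); these are averaged across groups per gene, floored
#' at zero, and the median over genes is returned. Counts are library-
#' equalized first. The median is robust but conservative: with few
#' replicates it sits somewhat below the true phi.
#'
#' @param counts integer matrix (genes x samples).
#' @param groups group label per column.
#' @return list with `phi`, `bcv` (sqrt(phi)) and `method`.
#' @export
estimate_common_dispersion <- function(counts, groups) {
  if (ncol(counts) != length(groups)) stop("groups must match columns")
  if (!any(table(groups) >= 2))
    stop("cannot estimate dispersion: no group has >= 2 replicates")
  counts <- equalize_libraries(counts)
  per_group <- lapply(unique(groups), function(g) {
    sub <- counts[, groups == g, drop = FALSE]
    if (ncol(sub) < 2) return(rep(NA_real_, nrow(counts)))
    mu <- rowMeans(sub)
    v <- apply(sub, 1, var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  })
  d <- rowMeans(do.call(cbind, per_group), na.rm = TRUE)
  phi <- median(pmax(0, d), na.rm = TRUE)
  list(phi = phi, bcv = sqrt(phi), method = "pooled method of moments")
}

#' Exact conditional test for a two-group count difference
#'
#' Conditional on the total, the group-A sum of negative-binomial counts is
#' compared against its convolution law: A-sum ~ NB(n_A mu, phi / n_A) and
#' B-sum ~ NB(n_B mu, phi / n_B) share the success probability, so the
#' conditional probabilities are enumerated over 0..total and the two-sided
#' p-value sums every outcome whose probability does not exceed that of the
#' observed one. With phi = 0 the conditional law is Binomial(total,
#' n_A / (n_A + n_B)). Computed in log space.
#'
#' @param sum_a,sum_b group total counts (library-equalized upstream).
#' @param n_a,n_b number of replicates per group.
#' @param phi common negative-binomial dispersion (>= 0).
#' @return two-sided p-value in (0, 1]; total = 0 returns 1 by convention.
#' @export
nb_exact_test <- function(sum_a, sum_b, n_a = 1, n_b = 1, phi = 0) {
  if (sum_a < 0 || sum_b < 0) stop("counts must be non-negative")
  if (phi < 0) stop("phi must be >= 0")
  total <- sum_a + sum_b
  if (total == 0) return(1)
  lp <- conditional_log_probs(total, n_a, n_b, phi)
  l_obs <- lp[sum_a + 1]
  # outcomes at least as extreme: probability <= observed (small relative
  # slack absorbs floating-point ties, as exact binomial tests do)
  keep <- lp <= l_obs + log1p(1e-7)
  denom <- logsumexp(lp)
  min(1, exp(logsumexp(lp[keep]) - denom))
}

conditional_log_probs <- function(total, n_a, n_b, phi) {
  a <- 0:total
  if (phi == 0) {
    dbinom(a, total, n_a / (n_a + n_b), log = TRUE)
  } else {
    mu <- total / (n_a + n_b)
    dnbinom(a, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      dnbinom(total - a, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Per-gene log2 fold change with prior count
#'
#' logFC = log2((mean_B + prior) / (mean_A + prior)); the prior keeps the
#' ratio finite for zero means.
#'
#' @param counts integer matrix (library-equalized).
#' @param groups group label per column.
#' @param a,b the two group labels being compared (B relative to A).
#' @param prior prior count (default 0.5).
#' @return named numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(counts, groups, a, b, prior = 0.5) {
  ma <- rowMeans(counts[, groups == a, drop = FALSE])
  mb <- rowMeans(counts[, groups == b, drop = FALSE])
  log2((mb + prior) / (ma + prior))
}

#' Two-group differential expression by the exact conditional test
#'
#' Library-equalizes the counts, sums replicates per group, applies
#' [nb_exact_test()] gene-wise at the supplied (or estimated) common
#' dispersion, and attaches log2 fold changes.
#'
#' @param counts integer matrix (genes x samples) or [count_matrix()].
#' @param groups group label per column.
#' @param a,b labels of the two groups compared; logFC is b relative to a.
#' @param phi common dispersion; `NULL` estimates it with
#'   [estimate_common_dispersion()].
#' @param prior prior count for the fold change.
#' @return data.frame: `gene`, `comparison` ("a vs b"), `logFC`, `pvalue`.
#' @export
run_dge <- function(counts, groups, a, b, phi = NULL, prior = 0.5) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (!all(c(a, b) %in% groups)) stop("groups a and b must appear in `groups`")
  sel <- groups %in% c(a, b)
  counts <- equalize_libraries(counts[, sel, drop = FALSE])
  groups <- groups[sel]
  if (is.null(phi)) phi <- estimate_common_dispersion(counts, groups)$phi
  n_a <- sum(groups == a); n_b <- sum(groups == b)
  sum_a <- rowSums(counts[, groups == a, drop = FALSE])
  sum_b <- rowSums(counts[, groups == b, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)),
              function(i) nb_exact_test(sum_a[i], sum_b[i], n_a, n_b, phi),
              numeric(1))
  data.frame(gene = rownames(counts),
             comparison = paste(a, "vs", b),
             logFC = unname(log_fold_change(counts, groups, a, b, prior)),
             pvalue = p,
             stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Strict thresholds exactly as printed in the decision rule: `up` when
#' p < `p_thresh` and logFC > `lfc_thresh`; `down` when p < `p_thresh` and
#' logFC < -`lfc_thresh`; otherwise `ns`.
#'
#' @param results data.frame from [run_dge()].
#' @param p_thresh p-value cutoff (default 0.01, strict).
#' @param lfc_thresh absolute log2 fold-change cutoff (default 2, strict).
#' @return the input with a `direction` column added.
#' @export
call_degs <- function(results, p_thresh = 0.01, lfc_thresh = 2) {
  results$direction <- ifelse(
    results$pvalue < p_thresh & results$logFC > lfc_thresh, "up",
    ifelse(results$pvalue < p_thresh & results$logFC < -lfc_thresh, "down",
           "ns"))
  results
}

#' Exclusive intersection counts of named gene sets
#'
#' UpSet-style decomposition: for every non-empty combination of set names,
#' the number of genes belonging to exactly those sets. Counts sum to the
#' size of the union.
#'
#' @param sets named list of character vectors (>= 2 sets).
#' @return data.frame: `combination` (names joined by "&"), `degree`,
#'   `count`, sorted by decreasing count then combination.
#' @export
deg_set_overlaps <- function(sets) {
  if (length(sets) < 2 || is.null(names(sets)))
    stop("need >= 2 named sets")
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  sig <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "&"))
  tab <- table(sig)
  out <- data.frame(combination = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$degree <- lengths(strsplit(out$combination, "&", fixed = TRUE))
  out <- out[order(-out$count, out$combination, method = "radix"),
             c("combination", "degree", "count")]
  rownames(out) <- NULL
  out
}

#' Hypergeometric keyword enrichment of a gene set
#'
#' For every keyword, tests whether its frequency inside `gene_set` exceeds
#' expectation under sampling without replacement from the universe:
#' p = P(X >= k), X ~ Hypergeometric(N, K, n), via the stable upper-tail
#' implementation in `phyper`. Keywords absent from the universe are skipped
#' with a warning.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all genes considered.
#' @param keyword_map data.frame with `transcript_id` and `keyword`.
#' @param adjust apply Benjamini-Hochberg correction in an extra column
#'   (default FALSE; the raw p is always reported).
#' @return data.frame per keyword: `keyword`, `k`, `n`, `K`, `N`, `pvalue`
#'   (and `padj` when `adjust`), sorted by increasing p.
#' @export
keyword_enrichment <- function(gene_set, universe, keyword_map,
                               adjust = FALSE) {
  if (!all(gene_set %in% universe)) stop("gene_set must be within universe")
  all_kw <- unique(keyword_map$keyword)
  keyword_map <- keyword_map[keyword_map$transcript_id %in% universe, ,
                             drop = FALSE]
  absent <- setdiff(all_kw, unique(keyword_map$keyword))
  if (length(absent))
    warning("keywords absent from universe skipped: ",
            paste(absent, collapse = ", "))
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(split(keyword_map, keyword_map$keyword), function(km) {
    K <- length(unique(km$transcript_id))
    k <- length(intersect(unique(km$transcript_id), gene_set))
    data.frame(keyword = km$keyword[1], k = k, n = n, K = K, N = N,
               pvalue = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(keyword = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), pvalue = numeric()))
  if (adjust) out$padj <- p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$keyword, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
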