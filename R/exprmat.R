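#' Count matrix with transcript lengths
#'
#' Container for raw integer read counts (transcripts x samples) plus the
#' transcript lengths required for TPM normalization.
#'
#' @param counts integer matrix with unique row (transcript) and column
#'   (sample) names; all entries non-negative integers.
#' @param lengths numeric vector of transcript lengths in nt (> 0), named by
#'   transcript or in row order.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have transcript row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  storage.mode(counts) <- "integer"
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts))
      stop("lengths must match the number of transcripts")
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing))
    stop("transcripts without a length: ", paste(head(missing), collapse = ", "))
  lengths <- lengths[rownames(counts)]
  if (any(lengths <= 0))
    stop("non-positive length for transcript: ",
         names(lengths)[which(lengths <= 0)[1]])
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "transcripts x",
      ncol(x$counts), "samples\n")
  invisible(x)
}

#' Transcripts-per-million normalization
#'
#' TPM_gs = (c_gs / l_g) / sum_j (c_js / l_j) * 1e6. Length units cancel, so
#' lengths may be given in nt or kb as long as they are consistent. Every
#' column of the result sums to 1e6.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of TPM values with the same dimnames.
#' @export
compute_tpm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  cs <- colSums(cm$counts)
  if (any(cs == 0))
    stop("all-zero sample column: ", colnames(cm$counts)[which(cs == 0)[1]])
  rate <- cm$counts / cm$lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Filter weakly expressed transcripts
#'
#' Default rule `max` keeps transcripts whose maximum TPM over samples is
#' strictly greater than `threshold` (the assembly-compaction reading: keep
#' anything well expressed somewhere). `mean` uses the across-sample mean;
#' `all` requires every sample to exceed the threshold.
#'
#' @param tpm TPM matrix (transcripts x samples).
#' @param threshold TPM cutoff (default 5), strict inequality.
#' @param rule one of `"max"`, `"mean"`, `"all"`.
#' @param renormalize if TRUE, rescale the retained columns to sum to 1e6;
#'   by default values keep their pre-filter meaning.
#' @return the filtered TPM matrix (possibly 0 rows, with a warning).
#' @export
filter_low_expression <- function(tpm, threshold = 5,
                                  rule = c("max", "mean", "all"),
                                  renormalize = FALSE) {
  rule <- match.arg(rule)
  if (threshold < 0) stop("threshold must be >= 0")
  stat <- switch(rule,
    max = apply(tpm, 1, max),
    mean = rowMeans(tpm),
    all = apply(tpm, 1, min))
  keep <- stat > threshold
  out <- tpm[keep, , drop = FALSE]
  if (nrow(out) == 0) warning("no transcripts retained at threshold ", threshold)
  if (renormalize && nrow(out) > 0)
    out <- sweep(out, 2, colSums(out), "/") * 1e6
  out
}

#' Log2 transform with pseudocount
#'
#' @param tpm TPM matrix.
#' @param pseudocount added before the log (default 1, so TPM 0 maps to 0).
#' @return matrix of log2(TPM + pseudocount).
#' @export
log_transform <- function(tpm, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be positive")
  log2(tpm + pseudocount)
}

#' Within-tissue replicate quality control
#'
#' Computes the correlation between every pair of replicates of the same
#' tissue and flags pairs whose coefficient exceeds `min_rho`. Constant
#' columns make the coefficient undefined; such pairs are reported as failed
#' with a reason rather than raising an error.
#'
#' @param tpm TPM (or log-TPM) matrix.
#' @param meta sample metadata with `sample_id` and `tissue`.
#' @param method `"spearman"` (default; average ranks on ties) or
#'   `"pearson"`.
#' @param min_rho pass threshold: pass <=> rho > min_rho (default 0.9).
#' @return data.frame with one row per within-tissue pair: `tissue`,
#'   `sample_a`, `sample_b`, `rho`, `pass`, `note`.
#' @export
replicate_qc <- function(tpm, meta, method = c("spearman", "pearson"),
                         min_rho = 0.9) {
  method <- match.arg(method)
  if (!all(meta$sample_id %in% colnames(tpm)))
    stop("meta sample_ids missing from the matrix")
  tissues <- split(meta$sample_id, meta$tissue)
  if (!any(lengths(tissues) >= 2))
    stop("no tissue has >= 2 replicates")
  rows <- list()
  for (t in names(tissues)) {
    ids <- sort(tissues[[t]])
    if (length(ids) < 2) next
    for (i in seq_len(length(ids) - 1)) for (j in (i + 1):length(ids)) {
      x <- tpm[, ids[i]]; y <- tpm[, ids[j]]
      note <- ""
      if (sd(x) == 0 || sd(y) == 0) {
        rho <- NA_real_
        note <- "constant column: correlation undefined"
      } else {
        rho <- cor(x, y, method = method)
      }
      rows[[length(rows) + 1]] <- data.frame(
        tissue = t, sample_a = ids[i], sample_b = ids[j], rho = rho,
        pass = !is.na(rho) && rho > min_rho, note = note,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "min_rho") <- min_rho
  attr(out, "method") <- method
  out
}
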