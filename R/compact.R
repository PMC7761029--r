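#' Parameters for greedy redundancy clustering
#'
#' @param min_identity minimum fractional identity between a member and its
#'   cluster representative (default 0.9).
#' @param min_coverage minimum fraction of the shorter sequence covered by
#'   the alignment (default 0.8).
#' @param kmer_size k for the shared k-mer pre-screen that gates the DP
#'   alignment (default 11; must be >= 4).
#' @return an object of class `cluster_params`.
#' @export
cluster_params <- function(min_identity = 0.9, min_coverage = 0.8,
                           kmer_size = 11) {
  if (min_identity <= 0 || min_identity > 1 ||
      min_coverage <= 0 || min_coverage > 1)
    stop("thresholds must lie in (0, 1]")
  if (kmer_size < 4) stop("kmer_size must be >= 4")
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 kmer_size = as.integer(kmer_size)),
            class = "cluster_params")
}

kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' Greedy incremental clustering of redundant transcripts
#'
#' CD-HIT-style compaction of a merged, redundant transcript set: sequences
#' are visited in order of decreasing length (ties: lexicographically
#' smaller id first); each sequence joins the first existing cluster whose
#' representative it matches at identity >= `min_identity` with alignment
#' coverage >= `min_coverage` of the shorter sequence (local affine-gap
#' alignment, both strands), otherwise it founds a new cluster. A shared
#' k-mer pre-screen skips hopeless alignments. Fully deterministic.
#'
#' @param seqs named character vector of ACGTN sequences (unique ids).
#' @param params a [cluster_params()].
#' @param scheme alignment [scoring_scheme()] (local mode enforced).
#' @return an object of class `cluster_assignment`: list with
#'   `representative_of` (named character: member -> representative),
#'   `clusters` (representative -> ordered member vector), and `params`.
#' @export
cluster_transcripts <- function(seqs, params = cluster_params(),
                                scheme = scoring_scheme()) {
  if (length(seqs) == 0) stop("empty sequence set")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique ids")
  for (id in names(seqs)) {
    if (is.na(seqs[[id]]) || nchar(seqs[[id]]) == 0)
      stop("empty sequence: ", id)
    if (grepl("[^ACGTN]", seqs[[id]]))
      stop("non-ACGTN sequence: ", id)
  }
  scheme$mode <- "local"
  ord <- order(-nchar(seqs), names(seqs), method = "radix")
  seqs <- seqs[ord]

  reps <- character(0)
  rep_kmers <- list()
  representative_of <- character(0)
  clusters <- list()

  for (id in names(seqs)) {
    s <- seqs[[id]]
    km <- kmer_set(s, params$kmer_size)
    assigned <- NA_character_
    for (r in reps) {  # founding order = decreasing length
      if (!any(km %in% rep_kmers[[r]])) next
      al <- align_pair(seqs[[r]], s, scheme, both_strands = TRUE)
      # coverage is measured on the shorter of the two sequences
      coverage <- (if (nchar(s) <= nchar(seqs[[r]])) al$coverage_subject
                   else al$coverage_query)
      identity <- al$identities / al$aln_length
      if (identity >= params$min_identity && coverage >= params$min_coverage) {
        assigned <- r
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, id)
      rep_kmers[[id]] <- km
      clusters[[id]] <- id
      representative_of[id] <- id
    } else {
      clusters[[assigned]] <- c(clusters[[assigned]], id)
      representative_of[id] <- assigned
    }
  }
  structure(list(representative_of = representative_of,
                 clusters = clusters, params = params),
            class = "cluster_assignment")
}

#' Pick one consensus sequence per cluster
#'
#' The longest member wins; length ties are broken by the highest
#' max-over-samples TPM (when a TPM matrix is supplied), then by the
#' lexicographically smaller id. Members missing from the TPM table trigger
#' a warning and fall back to the length/id rule.
#'
#' @param assignment a `cluster_assignment` from [cluster_transcripts()].
#' @param seqs the sequences that were clustered.
#' @param tpm optional TPM matrix (rows = transcripts).
#' @return named character vector of consensus sequences (one per cluster),
#'   ordered by representative id.
#' @export
select_representatives <- function(assignment, seqs, tpm = NULL) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  chosen <- vapply(assignment$clusters, function(members) {
    len <- nchar(seqs[members])
    cand <- members[len == max(len)]
    if (length(cand) > 1 && !is.null(tpm)) {
      if (!all(cand %in% rownames(tpm))) {
        warning("cluster members missing from TPM table; using length/id rule")
      } else {
        mx <- apply(tpm[cand, , drop = FALSE], 1, max)
        cand <- cand[mx == max(mx)]
      }
    }
    sort(cand, method = "radix")[1]
  }, character(1))
  ids <- sort(unname(chosen), method = "radix")
  seqs[ids]
}

#' Expression filtering followed by redundancy clustering
#'
#' The full compaction chain: TPM normalization, removal of weakly expressed
#' transcripts (max TPM strictly > `tpm_threshold`), greedy clustering of the
#' survivors, and consensus selection. Mirrors the reduction of a merged
#' multi-sample de novo assembly to a consensus transcriptome.
#'
#' @param seqs named character vector of transcript sequences.
#' @param counts a [count_matrix()] covering (at least) the same ids.
#' @param tpm_threshold expression cutoff (default 5, strict).
#' @param params a [cluster_params()].
#' @param scheme alignment [scoring_scheme()].
#' @return list with `consensus` (named character vector), `assignment`
#'   (the `cluster_assignment`), and `report` (data.frame of stage counts).
#' @export
compact_pipeline <- function(seqs, counts, tpm_threshold = 5,
                             params = cluster_params(),
                             scheme = scoring_scheme()) {
  stopifnot(inherits(counts, "count_matrix"))
  missing <- setdiff(names(seqs), rownames(counts$counts))
  if (length(missing))
    stop("sequences without counts: ", paste(head(missing), collapse = ", "))
  tpm <- compute_tpm(counts)
  kept <- filter_low_expression(tpm[names(seqs), , drop = FALSE],
                                threshold = tpm_threshold)
  if (nrow(kept) == 0) stop("no transcripts retained at TPM threshold ",
                            tpm_threshold)
  retained <- seqs[rownames(kept)]
  assignment <- cluster_transcripts(retained, params, scheme)
  consensus <- select_representatives(assignment, retained, kept)
  report <- data.frame(
    stage = c("input", "expression_filtered", "clusters", "consensus"),
    n = c(length(seqs), length(retained), length(assignment$clusters),
          length(consensus)))
  list(consensus = consensus, assignment = assignment, report = report)
}
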