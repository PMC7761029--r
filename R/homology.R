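#' Alignment scoring scheme
#'
#' Nucleotide scoring for pairwise alignment: positive match reward, negative
#' mismatch and affine gap penalties. A gap of length L costs
#' `gap_open + L * gap_extend` (both negative). `N` matches nothing,
#' including another `N`. Defaults are blastn-flavoured.
#'
#' @param match match score (> 0), default +2.
#' @param mismatch mismatch score (< 0), default -3.
#' @param gap_open gap opening penalty (<= 0), default -5.
#' @param gap_extend per-position gap extension penalty (<= 0), default -2.
#' @param mode `"local"` (Smith-Waterman style, default) or `"global"`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 2, mismatch = -3, gap_open = -5,
                           gap_extend = -2, mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, mode = mode),
            class = "scoring_scheme")
}

substitution_matrix <- function(scheme) {
  alpha <- c("A", "C", "G", "T", "N")
  m <- matrix(scheme$mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(m) <- scheme$match
  m["N", "N"] <- scheme$mismatch  # N never matches, not even itself
  m
}

check_dna <- function(seq, what = "sequence") {
  if (length(seq) != 1 || is.na(seq) || nchar(seq) == 0)
    stop("empty ", what)
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside ACGTN")
  invisible(seq)
}

#' Optimal pairwise alignment of two nucleotide sequences
#'
#' Affine-gap dynamic-programming alignment (local or global per the scheme).
#' Local mode clips to the best-scoring segment. With `both_strands = TRUE`
#' the subject's reverse complement is also aligned and the better raw score
#' wins (assembled transcripts have arbitrary orientation).
#'
#' @param a query sequence (character, ACGTN).
#' @param b subject sequence.
#' @param scheme a [scoring_scheme()].
#' @param both_strands also try the reverse complement of `b`.
#' @return list with `score`, `aln_length` (alignment columns, gaps
#'   included), `identities`, `pct_identity`, `coverage_query` and
#'   `coverage_subject` (aligned span / sequence length), and `strand`
#'   (`"+"` or `"-"`).
#' @export
align_pair <- function(a, b, scheme = scoring_scheme(),
                       both_strands = FALSE) {
  check_dna(a, "query"); check_dna(b, "subject")
  fw <- align_one(a, b, scheme, "+")
  if (!both_strands) return(fw)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(b)))
  rv <- align_one(a, rc, scheme, "-")
  if (rv$score > fw$score) rv else fw
}

align_one <- function(a, b, scheme, strand) {
  type <- if (scheme$mode == "local") "local" else "global"
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = substitution_matrix(scheme),
    gapOpening = -scheme$gap_open, gapExtension = -scheme$gap_extend)
  aln_len <- Biostrings::nchar(pwa)
  ident <- Biostrings::nmatch(pwa)
  qspan <- if (type == "local")
    IRanges::width(Biostrings::pattern(pwa)@range) else nchar(a)
  sspan <- if (type == "local")
    IRanges::width(Biostrings::subject(pwa)@range) else nchar(b)
  list(score = Biostrings::score(pwa),
       aln_length = aln_len,
       identities = ident,
       pct_identity = if (aln_len > 0) 100 * ident / aln_len else 0,
       coverage_query = qspan / nchar(a),
       coverage_subject = sspan / nchar(b),
       strand = strand)
}

#' Best transcript hit per bait gene
#'
#' Aligns every bait against every transcript (both strands) and keeps, per
#' bait, the transcript with the maximal raw alignment score; ties are broken
#' by higher percent identity, then by lexicographically smaller subject id.
#' Baits whose best score falls below `min_score` (or whose alignment is
#' shorter than `min_aln_len`) are reported as "no hit" (`NA` subject).
#'
#' @param baits named character vector of bait sequences.
#' @param transcripts named character vector of transcript sequences.
#' @param scheme a [scoring_scheme()]; local mode is the intended use.
#' @param min_score minimum raw score for a reportable hit (default 50).
#' @param min_aln_len optional minimum alignment length (default 0: keep
#'   all); short best-scoring alignments can otherwise be spurious.
#' @return data.frame with one row per bait: `bait`, `subject`, `score`,
#'   `aln_len`, `identities`, `pct_identity`, `coverage`, `tier`.
#' @export
best_hits <- function(baits, transcripts, scheme = scoring_scheme(),
                      min_score = 50, min_aln_len = 0) {
  if (length(baits) < 1 || length(transcripts) < 1)
    stop("need at least one bait and one transcript")
  tx_ids <- sort(names(transcripts), method = "radix")
  rows <- lapply(names(baits), function(bid) {
    best <- NULL; best_id <- NA_character_
    for (tid in tx_ids) {
      al <- align_pair(baits[[bid]], transcripts[[tid]], scheme,
                       both_strands = TRUE)
      if (al$aln_length < min_aln_len) next
      if (is.null(best) ||
          al$score > best$score ||
          (al$score == best$score && al$pct_identity > best$pct_identity)) {
        best <- al; best_id <- tid
      }
    }
    if (is.null(best) || best$score < min_score) {
      data.frame(bait = bid, subject = NA_character_, score = NA_real_,
                 aln_len = NA_integer_, identities = NA_integer_,
                 pct_identity = NA_real_, coverage = NA_real_,
                 tier = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(bait = bid, subject = best_id, score = best$score,
                 aln_len = best$aln_length, identities = best$identities,
                 pct_identity = best$pct_identity,
                 coverage = best$coverage_subject,
                 tier = assign_conservation_tier(best$pct_identity),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Conservation tier from percent identity
#'
#' Four qualitative conservation bands used to group pathway genes by
#' sequence conservation against the reference species: tier 1 at >= 85%
#' identity (early pathway branches), tier 2 at 78--85% (central steps),
#' tier 3 at 70--78% (around 75%), tier 4 below 70%. Boundaries are
#' half-open: [85, 100] / [78, 85) / [70, 78) / [0, 70). The interior
#' boundary at 78 is a documented design choice between the published
#' anchors.
#'
#' @param pct_identity numeric vector in [0, 100].
#' @return integer tiers in 1..4.
#' @export
assign_conservation_tier <- function(pct_identity) {
  if (any(is.na(pct_identity)) || any(pct_identity < 0 | pct_identity > 100))
    stop("percent identity must lie in [0, 100]")
  ifelse(pct_identity >= 85, 1L,
  ifelse(pct_identity >= 78, 2L,
  ifelse(pct_identity >= 70, 3L, 4L)))
}

#' Mean best-hit identity per pathway branch
#'
#' @param hits data.frame from [best_hits()].
#' @param group_map named character vector: bait id -> pathway branch label.
#' @return data.frame per branch: `branch`, `n_hits`, `n_no_hit`,
#'   `mean_pct_identity` (NA if a branch has no hits).
#' @export
conservation_summary <- function(hits, group_map) {
  missing <- setdiff(hits$bait, names(group_map))
  if (length(missing))
    stop("baits without a branch: ", paste(missing, collapse = ", "))
  hits$branch <- unname(group_map[hits$bait])
  rows <- lapply(split(hits, hits$branch), function(h) {
    ok <- !is.na(h$subject)
    data.frame(branch = h$branch[1], n_hits = sum(ok), n_no_hit = sum(!ok),
               mean_pct_identity = if (any(ok)) mean(h$pct_identity[ok])
                                   else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$branch, method = "radix"), , drop = FALSE]
}
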