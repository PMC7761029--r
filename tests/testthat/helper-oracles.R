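# Independent oracles used to validate the package's computations.
# All are plain-R reimplementations structured differently from the
# implementation paths they check.

oracle_sub <- function(x, y, scheme) {
  if (x == y && x != "N") scheme$match else scheme$mismatch
}

# Needleman-Wunsch with affine gaps (gap of length L costs open + L*extend),
# end gaps penalized. Returns the optimal score.
oracle_global_affine <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)  # last pair aligned
  X <- matrix(NEG, n + 1, m + 1)  # last move: gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # last move: gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- go + ge * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- go + ge * (j - 1)
  if (n >= 1 && m >= 1) {
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
      s <- oracle_sub(A[i - 1], B[j - 1], scheme)
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge,
                     Y[i - 1, j] + go + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge,
                     X[i, j - 1] + go + ge)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Smith-Waterman with affine gaps; zero floor, best cell wins.
oracle_local_affine <- function(a, b, scheme) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gap_open; ge <- scheme$gap_extend
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] + go + ge, E[i, j - 1] + ge)
    F[i, j] <- max(H[i - 1, j] + go + ge, F[i - 1, j] + ge)
    H[i, j] <- max(0, H[i - 1, j - 1] + oracle_sub(A[i - 1], B[j - 1], scheme),
                   E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Exhaustive enumeration of every global alignment path under LINEAR gap
# costs (no dynamic programming; exponential, for tiny sequences only).
enum_global_linear <- function(a, b, match, mismatch, gap) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(A)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(B)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Naive HRR: per-pair rank lookups straight from the definition.
naive_hrr <- function(expr) {
  corr <- cor(t(expr))
  ids <- rownames(expr)
  n <- nrow(corr)
  rank_of <- function(i, j) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-corr[i, others], ids[others], method = "radix")]
    which(ord == j)
  }
  H <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) {
      H[i, j] <- max(rank_of(i, j), rank_of(j, i))
      H[j, i] <- H[i, j]
    }
  }
  H
}

# All set partitions of n elements as membership vectors (restricted growth).
all_partitions <- function(n) {
  out <- list()
  rec <- function(memb, k) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return(invisible(NULL))
    }
    for (c in seq_len(k + 1L)) rec(c(memb, c), max(k, c))
  }
  rec(integer(0), 0L)
  out
}

# Upper-tail hypergeometric probability by term-by-term enumeration.
hyper_enum <- function(k, K, N, n) {
  if (k <= 0) return(1)
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random ACGT string.
rdna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
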