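# Independent oracles used across the suite. These are deliberately naive
# implementations, kept separate from the package's own code paths.

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Affine-gap global alignment score (Gotoh), end gaps penalised, gap of
# length g costing open + g * extend. Maximisation over all alignments,
# including adjacent opposite-direction gaps (two openings).
oracle_global_score <- function(a, b, submat = blosum62,
                                open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (A aligned to gap)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * extend)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * extend)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend,
                      Ix[i - 1, j] - extend,
                      Iy[i - 1, j] - open - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend,
                      Iy[i, j - 1] - extend,
                      Ix[i, j - 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Affine-gap local (Smith-Waterman) score.
oracle_local_score <- function(a, b, submat = blosum62,
                               open = 10, extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      M[i, j] <- max(M[i, j], 0)
      Ix[i, j] <- max(M[i - 1, j] - open - extend, Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend, Iy[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Exhaustive Mann-Whitney AUC: fraction of (positive, negative) pairs in
# which the positive outscores the negative, ties counting one half.
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) for (q in sn) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(sp) * length(sn))
}

random_protein <- function(len) {
  paste(sample(poreformer::CANONICAL_RESIDUES, len, replace = TRUE),
        collapse = "")
}
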