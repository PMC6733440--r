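# Independent brute-force affine-gap local alignment oracle (Gotoh DP,
# plain R). Convention: a gap run of length k costs
# gap_open_penalty + k * gap_extend_penalty; N never matches.
# Used to verify the aligner; must stay independent of local_align().
oracle_local_score <- function(q, t, params) {
  a <- strsplit(q, "", fixed = TRUE)[[1]]
  b <- strsplit(t, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  go <- params$gap_open_penalty; ge <- params$gap_extend_penalty
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)  # gap in query (consumes target)
  F <- matrix(-Inf, n + 1L, m + 1L)  # gap in target (consumes query)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (a[i - 1L] == b[j - 1L] && a[i - 1L] != "N")
        params$match_reward else params$mismatch_penalty
      E[i, j] <- max(H[i, j - 1L] + go + ge, E[i, j - 1L] + ge)
      F[i, j] <- max(H[i - 1L, j] + go + ge, F[i - 1L, j] + ge)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + s, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# best local score over both query orientations
oracle_best_score <- function(q, t, params) {
  max(oracle_local_score(q, t, params),
      oracle_local_score(reverse_complement(q), t, params))
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
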