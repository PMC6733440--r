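# Half-up decimal rounding (R's round() is round-half-even); report
# percentages are printed with this convention.
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' N50 of a set of sequence lengths
#'
#' The largest length `L` in the set such that sequences of length at
#' least `L` together cover at least half the total length. When several
#' lengths satisfy the condition the largest is returned.
#'
#' @param lengths vector of positive sequence lengths.
#' @return the N50 in bp; `0` with a warning for empty input.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4: 5 + 4 = 9 >= 15/2
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) {
    warning("n50 of empty length set is 0")
    return(0)
  }
  stopifnot(all(lengths > 0))
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Per-assembly summary statistics
#'
#' The standard assembly report columns: sequence count, total bp, N50,
#' and the gap load (count of maximal N-runs, total N bp, percentage of
#' the assembly that is N). `gap_pct` is rounded half-up to 2 decimals,
#' the precision used in printed assembly tables.
#'
#' @param records a record table ([dna_records()] shape).
#' @param min_gap_len see [find_gaps()].
#' @return list of class `assembly_stats` with fields `n_seqs`,
#'   `total_bp`, `n50`, `gap_count`, `gap_bp`, `gap_pct`.
#' @export
assembly_stats <- function(records, min_gap_len = 1L) {
  lens <- nchar(records$seq)
  gaps <- lapply(records$seq, find_gaps, min_gap_len = min_gap_len)
  gap_count <- sum(vapply(gaps, nrow, integer(1)))
  gap_bp <- sum(vapply(gaps, function(g) sum(g$end - g$start), numeric(1)))
  total <- sum(as.numeric(lens))
  structure(list(
    n_seqs = nrow(records),
    total_bp = total,
    n50 = if (nrow(records)) n50(lens) else {warning("empty assembly"); 0},
    gap_count = gap_count,
    gap_bp = gap_bp,
    gap_pct = if (total > 0) round_half_up(100 * gap_bp / total, 2) else 0),
    class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "%d sequence(s), %.0f bp, N50 %.0f | gaps: %d runs, %.0f bp (%.2f%%)\n",
    x$n_seqs, x$total_bp, x$n50, x$gap_count, x$gap_bp, x$gap_pct))
  invisible(x)
}

#' Before/after gap-filling summary
#'
#' @param before,after [assembly_stats()] of the same assembly before
#'   and after filling.
#' @return list with `gap_bp_filled_pct` (percentage of gap bp removed;
#'   `NA` when `before` had no gap bp) and `n_seqs_reduction_pct`, both
#'   rounded half-up to 1 decimal, plus the absolute deltas.
#' @export
fill_summary <- function(before, after) {
  filled_pct <- if (before$gap_bp > 0)
    round_half_up(100 * (before$gap_bp - after$gap_bp) / before$gap_bp, 1)
  else NA_real_
  red_pct <- if (before$n_seqs > 0)
    round_half_up(100 * (before$n_seqs - after$n_seqs) / before$n_seqs, 1)
  else NA_real_
  list(gap_bp_filled_pct = filled_pct,
       n_seqs_reduction_pct = red_pct,
       gap_bp_delta = before$gap_bp - after$gap_bp,
       gap_count_delta = before$gap_count - after$gap_count,
       total_bp_delta = after$total_bp - before$total_bp)
}
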