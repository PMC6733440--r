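#' Locate N-gaps in a scaffold sequence
#'
#' A gap is a maximal run of `N` characters. Coordinates are 0-based
#' half-open (`start` inclusive, `end` exclusive), the package-internal
#' convention; reports convert to 1-based inclusive.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @param min_gap_len minimum run length to report (default 1: every N
#'   counts, matching assemblies where single-N gaps are real).
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   sorted by `start`; zero rows when the sequence has no qualifying
#'   N-run.
#' @export
find_gaps <- function(seq, min_gap_len = 1L) {
  stopifnot(length(seq) == 1L, min_gap_len >= 1L)
  r <- rle(strsplit(seq, "", fixed = TRUE)[[1]] == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_gap_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract alignment flanks around a gap
#'
#' The flanks are the contiguous known (non-N) sequence immediately left
#' and right of a gap, up to `flank_len` bp each. A flank stops early at
#' the scaffold end or at a neighbouring gap: anchors must be contiguous
#' known sequence, so flanks never cross another N-run.
#'
#' @param scaffold one-row record table (or any list with `$seq`).
#' @param gap one-row data.frame with `start`, `end` (0-based half-open)
#'   denoting an all-N interval of `scaffold$seq`.
#' @param flank_len maximum flank length in bp (default 300, the scale
#'   at which a local alignment comfortably exceeds the strict length
#'   and score thresholds).
#' @param min_flank_len flanks shorter than this fail (`ok = FALSE`);
#'   default 50 bp floors trivially short anchors.
#' @return list with elements `ok` (logical), `reason` (`NA`,
#'   `"no_left_anchor"` or `"no_right_anchor"`), `left` and `right`,
#'   each a list with `seq`, `scaffold_start`, `scaffold_end` (0-based
#'   half-open).
#' @export
extract_flanks <- function(scaffold, gap, flank_len = 300L,
                           min_flank_len = 50L) {
  seq <- scaffold$seq
  n <- nchar(seq)
  gs <- gap$start; ge <- gap$end
  if (gs < 0 || ge > n || gs >= ge)
    stop("gap coordinates outside scaffold")
  if (grepl("[^N]", substr(seq, gs + 1L, ge)))
    stop("gap interval is not all N")
  # scan left from gs-1 until N or start, at most flank_len bp
  ls <- gs
  while (ls > 0L && (gs - ls) < flank_len &&
         substr(seq, ls, ls) != "N") ls <- ls - 1L
  left <- list(seq = substr(seq, ls + 1L, gs), scaffold_start = ls,
               scaffold_end = gs, side = "left")
  # scan right from ge until N or end
  re <- ge
  while (re < n && (re - ge) < flank_len &&
         substr(seq, re + 1L, re + 1L) != "N") re <- re + 1L
  right <- list(seq = substr(seq, ge + 1L, re), scaffold_start = ge,
                scaffold_end = re, side = "right")
  reason <- NA_character_
  if (nchar(left$seq) < min_flank_len) reason <- "no_left_anchor"
  else if (nchar(right$seq) < min_flank_len) reason <- "no_right_anchor"
  list(ok = is.na(reason), reason = reason, left = left, right = right)
}
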