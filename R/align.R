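#' Scoring and filtering parameters for flank anchoring
#'
#' Raw-score model: `match_reward` per identical pair, `mismatch_penalty`
#' per substituted pair, and an affine gap cost of
#' `gap_open_penalty + k * gap_extend_penalty` for a gap run of length
#' `k` (penalties are stored as non-positive numbers). `N` in either
#' sequence always scores as a mismatch, never a match, so N-runs can
#' never self-anchor.
#'
#' The defaults are deliberately strict. BLAST-style gap-filling
#' defaults (raw score 25, 70% identity, up to 200 hits) are lenient
#' enough to let a single read fill many places in a large genome; here
#' a fill requires a unique anchor (`max_hits = 1`) clearing raw score
#' 50 at 80% identity over at least 100 aligned columns, with the
#' command-line-BLAST gap costs (open 5, extend 2) rather than the
#' permissive open/extend of 1. All are configurable.
#'
#' @param match_reward positive score per match (default 1).
#' @param mismatch_penalty non-positive score per mismatch (default -2).
#' @param gap_open_penalty non-positive cost charged once per gap run
#'   (default -5).
#' @param gap_extend_penalty non-positive cost per gapped position
#'   (default -2).
#' @param min_raw_score minimum accumulated alignment score (default 50).
#' @param min_identity minimum matches / alignment columns (default 0.80).
#' @param min_aln_len minimum alignment columns (default 100).
#' @param max_hits maximum surviving hits per (query, target) pair
#'   (default 1: anchors must be unique).
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(match_reward = 1L, mismatch_penalty = -2L,
                           gap_open_penalty = -5L, gap_extend_penalty = -2L,
                           min_raw_score = 50L, min_identity = 0.80,
                           min_aln_len = 100L, max_hits = 1L) {
  stopifnot(match_reward > 0, mismatch_penalty <= 0, gap_open_penalty <= 0,
            gap_extend_penalty <= 0, max_hits >= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(match_reward = as.integer(match_reward),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open_penalty = as.integer(gap_open_penalty),
                 gap_extend_penalty = as.integer(gap_extend_penalty),
                 min_raw_score = min_raw_score,
                 min_identity = min_identity,
                 min_aln_len = as.integer(min_aln_len),
                 max_hits = as.integer(max_hits)),
            class = "scoring_params")
}

# substitution matrix over ACGTN; N never matches anything, including N
.submat <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch_penalty, 5L, 5L, dimnames = list(bases, bases))
  diag(m) <- params$match_reward
  m["N", "N"] <- params$mismatch_penalty
  m
}

.empty_hits <- function() {
  data.frame(read_id = character(0), strand = character(0),
             read_start = integer(0), read_end = integer(0),
             target_start = integer(0), target_end = integer(0),
             raw_score = numeric(0), identity = numeric(0),
             aln_len = integer(0))
}

# one best local alignment of pat (character) vs subject, as a hit row
.one_alignment <- function(pat, target, params, submat) {
  al <- Biostrings::pairwiseAlignment(
    pattern = pat, subject = target, type = "local",
    substitutionMatrix = submat,
    gapOpening = abs(params$gap_open_penalty),
    gapExtension = abs(params$gap_extend_penalty))
  p <- as.character(Biostrings::alignedPattern(al))
  s <- as.character(Biostrings::alignedSubject(al))
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  matches <- sum(pc == sc & pc != "-" & pc != "N")
  list(score = Biostrings::score(al),
       q0 = Biostrings::start(Biostrings::pattern(al)) - 1L,
       q1 = Biostrings::end(Biostrings::pattern(al)),
       t0 = Biostrings::start(Biostrings::subject(al)) - 1L,
       t1 = Biostrings::end(Biostrings::subject(al)),
       aln_len = length(pc), matches = matches)
}

#' Local alignment of a read against a target region, both strands
#'
#' Affine-gap Smith-Waterman (via [Biostrings::pairwiseAlignment()])
#' of `query` and its reverse complement against `target`. Up to
#' `max_hits` hits are reported; after each accepted hit its target
#' interval is masked with `N` before realigning, so reported hits never
#' overlap on the target. Hits below `min_raw_score` (or with
#' non-positive score) are not reported.
#'
#' @param query DNA string (the read; reported coordinates are always on
#'   the forward read, with `strand` recording the orientation that
#'   aligned).
#' @param target DNA string (a scaffold region, typically a gap flank).
#' @param params a [scoring_params()] object.
#' @param query_id identifier stored in the `read_id` column.
#' @return data.frame of hits sorted by `raw_score` descending with
#'   columns `read_id`, `strand` (`+`/`-`), `read_start`, `read_end`,
#'   `target_start`, `target_end` (0-based half-open), `raw_score`,
#'   `identity`, `aln_len`.
#' @export
local_align <- function(query, target, params = scoring_params(),
                        query_id = "query") {
  stopifnot(nchar(query) >= 1L, nchar(target) >= 1L)
  submat <- .submat(params)
  qlen <- nchar(query)
  qrc <- reverse_complement(query)
  floor_score <- max(params$min_raw_score, 1)
  masked <- target
  out <- .empty_hits()
  for (i in seq_len(params$max_hits)) {
    fw <- .one_alignment(query, masked, params, submat)
    rv <- .one_alignment(qrc, masked, params, submat)
    use_fw <- fw$score >= rv$score  # '+' preferred on ties
    h <- if (use_fw) fw else rv
    if (h$score < floor_score || h$t1 <= h$t0) break
    if (use_fw) {
      rs <- h$q0; re <- h$q1
    } else {
      rs <- qlen - h$q1; re <- qlen - h$q0
    }
    out <- rbind(out, data.frame(
      read_id = query_id, strand = if (use_fw) "+" else "-",
      read_start = rs, read_end = re,
      target_start = h$t0, target_end = h$t1,
      raw_score = h$score, identity = h$matches / h$aln_len,
      aln_len = h$aln_len))
    substr(masked, h$t0 + 1L, h$t1) <- strrep("N", h$t1 - h$t0)
  }
  out[order(-out$raw_score, out$target_start, out$strand, out$read_id), ,
      drop = FALSE]
}

#' Filter alignment hits under the acceptance thresholds
#'
#' Keeps hits with `raw_score >= min_raw_score`, `identity >=
#' min_identity` and `aln_len >= min_aln_len`, then truncates to
#' `max_hits` by descending score; ties broken by target start, then
#' `+` strand first, then read id.
#'
#' @param hits a hit data.frame from [local_align()].
#' @param params a [scoring_params()] object.
#' @return the surviving hits, deterministically ordered.
#' @export
filter_hits <- function(hits, params = scoring_params()) {
  keep <- hits$raw_score >= params$min_raw_score &
    hits$identity >= params$min_identity &
    hits$aln_len >= params$min_aln_len
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(-hits$raw_score, hits$target_start, hits$strand,
                     hits$read_id), , drop = FALSE]
  utils::head(hits, params$max_hits)
}
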