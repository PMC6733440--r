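#' Decide whether one read can fill one gap
#'
#' The two-anchor rule: a gap may be filled by a read only when
#'
#' 1. the left flank and the right flank of the gap each produce exactly
#'    one surviving local-alignment hit against the read after
#'    [filter_hits()] (reasons `no_left_anchor` / `no_right_anchor`);
#' 2. both anchor hits lie on the same read strand (`strand_mismatch`);
#' 3. on the strand-oriented read the left anchor ends at or before the
#'    right anchor starts (`disordered_anchors`);
#' 4. the unaligned flank tails between each anchor and the gap edge
#'    (the trims) are at most `max_trim` bp, and the read subsequence
#'    spanned between the anchors is non-empty and N-free
#'    (`below_threshold`).
#'
#' The replacement is the oriented read subsequence between the left
#' anchor's end and the right anchor's start; it substitutes the gap
#' plus the trimmed flank tails.
#'
#' @param scaffold one-row record table (needs `$seq`, `$id`).
#' @param gap one-row data.frame/list with `start`, `end` (0-based
#'   half-open all-N interval).
#' @param read one-row record table (needs `$seq`, `$id`).
#' @param params a [scoring_params()] object.
#' @param flank_len,min_flank_len see [extract_flanks()].
#' @param max_trim maximum bp of known flank sequence that a fill may
#'   overwrite at each gap edge (default 10; bounds erosion of known
#'   sequence while letting alignments end a few noisy bases early).
#' @return a `fill_decision`: list with `gap`, `read_id`, `status`
#'   (`FILLED`/`REJECTED`), `replacement`, `left_trim`, `right_trim`,
#'   `reason` (`NA` when filled).
#' @export
plan_fill <- function(scaffold, gap, read, params = scoring_params(),
                      flank_len = 300L, min_flank_len = 50L,
                      max_trim = 10L) {
  dec <- function(status, reason = NA_character_, replacement = "",
                  left_trim = 0L, right_trim = 0L) {
    structure(list(gap = list(start = gap$start, end = gap$end),
                   read_id = read$id, status = status,
                   replacement = replacement, left_trim = left_trim,
                   right_trim = right_trim, reason = reason),
              class = "fill_decision")
  }
  fl <- extract_flanks(scaffold, gap, flank_len, min_flank_len)
  if (!fl$ok) return(dec("REJECTED", fl$reason))
  lh <- filter_hits(local_align(read$seq, fl$left$seq, params,
                                query_id = read$id), params)
  if (nrow(lh) != 1L) return(dec("REJECTED", "no_left_anchor"))
  rh <- filter_hits(local_align(read$seq, fl$right$seq, params,
                                query_id = read$id), params)
  if (nrow(rh) != 1L) return(dec("REJECTED", "no_right_anchor"))
  if (lh$strand != rh$strand) return(dec("REJECTED", "strand_mismatch"))
  qlen <- nchar(read$seq)
  if (lh$strand == "+") {
    oriented <- read$seq
    l_end <- lh$read_end; r_start <- rh$read_start
  } else {
    oriented <- reverse_complement(read$seq)
    l_end <- qlen - lh$read_start; r_start <- qlen - rh$read_end
  }
  if (l_end > r_start) return(dec("REJECTED", "disordered_anchors"))
  left_trim <- nchar(fl$left$seq) - lh$target_end
  right_trim <- rh$target_start
  replacement <- substr(oriented, l_end + 1L, r_start)
  if (left_trim > max_trim || right_trim > max_trim ||
      !nzchar(replacement) || grepl("N", replacement, fixed = TRUE))
    return(dec("REJECTED", "below_threshold"))
  dec("FILLED", replacement = replacement,
      left_trim = left_trim, right_trim = right_trim)
}

#' Apply a FILLED decision to a scaffold
#'
#' Splices `prefix[0, gap.start - left_trim) + replacement +
#' suffix[gap.end + right_trim, )`. Every base outside that window is
#' byte-identical to the input. Errors if the decision's gap interval is
#' no longer an all-N run of the stated length (a stale decision).
#'
#' @param scaffold one-row record table.
#' @param decision a `fill_decision` with status `FILLED`.
#' @return the modified one-row record table.
#' @export
apply_fill <- function(scaffold, decision) {
  stopifnot(inherits(decision, "fill_decision"),
            decision$status == "FILLED")
  seq <- scaffold$seq
  gs <- decision$gap$start; ge <- decision$gap$end
  if (gs < 0 || ge > nchar(seq) ||
      grepl("[^N]", substr(seq, gs + 1L, ge)))
    stop("stale fill decision: gap interval is not an N-run anymore")
  pre_end <- gs - decision$left_trim
  suf_start <- ge + decision$right_trim
  scaffold$seq <- paste0(substr(seq, 1L, pre_end),
                         decision$replacement,
                         substr(seq, suf_start + 1L, nchar(seq)))
  scaffold
}

.gap_key <- function(scaffold_id, start, end) {
  sprintf("%s:%d-%d", scaffold_id, start + 1L, end)
}

# One serial pass over the reads of a single scaffold; gaps in
# `aborted_keys` are never attempted. Returns the updated record, the
# per-gap state table and the consumed reads.
.fill_scaffold_pass <- function(scaffold, reads, params, flank_len,
                                min_flank_len, max_trim, min_gap_len,
                                aborted_keys) {
  gaps0 <- find_gaps(scaffold$seq, min_gap_len)
  n <- nrow(gaps0)
  state <- data.frame(
    key = if (n) .gap_key(scaffold$id, gaps0$start, gaps0$end) else character(0),
    orig_start = gaps0$start, orig_end = gaps0$end,
    cur_start = gaps0$start, cur_end = gaps0$end,
    status = rep("OPEN", n), read_id = rep(NA_character_, n),
    reason = rep(NA_character_, n),
    replacement_len = rep(0L, n), left_trim = rep(0L, n),
    right_trim = rep(0L, n), stringsAsFactors = FALSE)
  state$status[state$key %in% aborted_keys] <- "ABORTED_CONFLICT"
  state$reason[state$key %in% aborted_keys] <- "conflict"
  cur <- scaffold
  consumed <- character(0)
  if (n > 0L && nrow(reads) > 0L) {
    for (ri in seq_len(nrow(reads))) {
      read <- reads[ri, , drop = FALSE]
      open <- which(state$status == "OPEN")
      open <- open[order(state$cur_start[open])]
      for (gi in open) {
        gap <- list(start = state$cur_start[gi], end = state$cur_end[gi])
        d <- plan_fill(cur, gap, read, params, flank_len, min_flank_len,
                       max_trim)
        if (d$status == "FILLED") {
          cur <- apply_fill(cur, d)
          delta <- nchar(d$replacement) -
            (gap$end - gap$start) - d$left_trim - d$right_trim
          shift <- state$cur_start >= gap$end
          state$cur_start[shift] <- state$cur_start[shift] + delta
          state$cur_end[shift] <- state$cur_end[shift] + delta
          state$status[gi] <- "FILLED"
          state$read_id[gi] <- read$id
          state$reason[gi] <- NA_character_
          state$replacement_len[gi] <- nchar(d$replacement)
          state$left_trim[gi] <- d$left_trim
          state$right_trim[gi] <- d$right_trim
          consumed <- c(consumed, read$id)
          break  # a read is consumed by its first fill: used only once
        } else {
          state$reason[gi] <- d$reason
          state$read_id[gi] <- read$id
        }
      }
    }
  }
  # defensive: recomputed gaps must match the tracked open/aborted ones
  left_over <- find_gaps(cur$seq, min_gap_len)
  open_now <- state[state$status != "FILLED", , drop = FALSE]
  if (!identical(unname(left_over$start), unname(open_now$cur_start)) ||
      !identical(unname(left_over$end), unname(open_now$cur_end)))
    stop("internal error: gap bookkeeping diverged from sequence")
  state$status[state$status == "OPEN"] <- "REJECTED"
  state$reason[state$status == "REJECTED" & is.na(state$reason)] <- "no_reads"
  list(record = cur, gaps = state, consumed = consumed)
}

#' Fill the gaps of one scaffold with its own evidence reads
#'
#' The serial loop: for each read, in evidence order, every remaining
#' gap (in coordinate order on the current draft) is attempted with
#' [plan_fill()]; a successful fill is applied immediately, the draft
#' updated, and the read consumed — a consumed read attempts no further
#' gaps, so each read is used at most once. After the pass, same-well
#' origin conflicts are resolved with [check_conflicts()]: every gap
#' implicated in a conflict is marked `ABORTED_CONFLICT` and the pass is
#' re-run with those gaps excluded, until no conflict remains (fills on
#' conflicted gaps never reach the output).
#'
#' @param scaffold one-row record table.
#' @param reads record table of the reads associated with this scaffold,
#'   in evidence order. Offering a scaffold only its own reads is what
#'   keeps filling scaffold-local.
#' @param params a [scoring_params()] object.
#' @param flank_len,min_flank_len,max_trim see [plan_fill()].
#' @param min_gap_len see [find_gaps()].
#' @param aborted_keys gap keys (see report) to exclude up front, used
#'   by [run_pipeline()] for cross-scaffold conflicts.
#' @return list with `record` (the filled scaffold), `gaps` (per-gap
#'   state table with terminal `status` in `FILLED`, `REJECTED`,
#'   `ABORTED_CONFLICT`), `conflicts` (conflict report rows) and
#'   `consumed` (read ids used by fills).
#' @export
fill_scaffold <- function(scaffold, reads, params = scoring_params(),
                          flank_len = 300L, min_flank_len = 50L,
                          max_trim = 10L, min_gap_len = 1L,
                          aborted_keys = character(0)) {
  conflicts <- NULL
  repeat {
    res <- .fill_scaffold_pass(scaffold, reads, params, flank_len,
                               min_flank_len, max_trim, min_gap_len,
                               aborted_keys)
    filled <- res$gaps[res$gaps$status == "FILLED", , drop = FALSE]
    cc <- check_conflicts(origin_assignments(filled$read_id, filled$key))
    if (nrow(cc$conflicts) == 0L) break
    for (i in seq_len(nrow(cc$conflicts)))
      warning(sprintf(
        "origin conflict: subreads of %s/%d anchor distinct gaps [%s]; filling aborted",
        cc$conflicts$movie[i], cc$conflicts$well[i], cc$conflicts$gap_ids[i]),
        call. = FALSE)
    conflicts <- rbind(conflicts, cc$conflicts)
    aborted_keys <- union(aborted_keys,
                          unlist(strsplit(cc$conflicts$gap_ids, ",")))
  }
  if (is.null(conflicts))
    conflicts <- check_conflicts(origin_assignments(character(0),
                                                    character(0)))$conflicts
  c(res, list(conflicts = conflicts))
}

#' Run the whole gap-filling pipeline
#'
#' Every scaffold of the draft appears in the output exactly once and in
#' input order: scaffolds with evidence are filled where the two-anchor
#' rule allows, all others pass through untouched. Fills never merge or
#' split sequences. Cross-scaffold same-well conflicts are resolved
#' globally: implicated gaps are aborted and the affected scaffolds
#' re-filled without them.
#'
#' @param scaffolds record table of the draft assembly.
#' @param reads record table of the long reads.
#' @param evidence an `evidence_map` from [parse_evidence()], or a named
#'   list of read-id vectors keyed by scaffold id.
#' @param params a [scoring_params()] object.
#' @param flank_len,min_flank_len,max_trim,min_gap_len see
#'   [fill_scaffold()].
#' @param threads number of worker processes; scaffolds are partitioned
#'   across workers and results merged in input order, so the output is
#'   identical to a single-threaded run.
#' @return list with `records` (final assembly), `report` (see
#'   [write_report()]): per-gap table `gaps`, `conflicts`, `consumed`,
#'   `before`/`after` [assembly_stats()] and `summary` via
#'   [fill_summary()].
#' @export
run_pipeline <- function(scaffolds, reads, evidence,
                         params = scoring_params(), flank_len = 300L,
                         min_flank_len = 50L, max_trim = 10L,
                         min_gap_len = 1L, threads = 1L) {
  evidence <- lapply(evidence, as.character)
  unknown_scf <- setdiff(names(evidence), scaffolds$id)
  if (length(unknown_scf))
    stop("evidence references unknown scaffold id(s): ",
         paste(unknown_scf, collapse = ", "))
  unknown_reads <- setdiff(unlist(evidence, use.names = FALSE), reads$id)
  if (length(unknown_reads))
    stop("evidence references unknown read id(s): ",
         paste(unknown_reads, collapse = ", "))
  with_ev <- intersect(scaffolds$id, names(evidence))

  worker <- function(sid, aborted_keys) {
    scf <- scaffolds[scaffolds$id == sid, , drop = FALSE]
    rds <- reads[match(evidence[[sid]], reads$id), , drop = FALSE]
    fill_scaffold(scf, rds, params, flank_len, min_flank_len, max_trim,
                  min_gap_len, aborted_keys)
  }
  results <- list()
  aborted <- character(0)
  todo <- with_ev
  while (length(todo)) {
    out <- if (threads > 1L) {
      parallel::mclapply(todo, worker, aborted_keys = aborted,
                         mc.cores = threads)
    } else {
      lapply(todo, worker, aborted_keys = aborted)
    }
    for (e in out) if (inherits(e, "try-error")) stop(e)
    results[todo] <- out
    all_gaps <- do.call(rbind, lapply(results, `[[`, "gaps"))
    filled <- all_gaps[all_gaps$status == "FILLED", , drop = FALSE]
    cc <- check_conflicts(origin_assignments(filled$read_id, filled$key))
    newly <- setdiff(unlist(strsplit(cc$conflicts$gap_ids, ",")), aborted)
    if (length(newly) == 0L) break
    aborted <- union(aborted, newly)
    todo <- with_ev[vapply(with_ev, function(sid)
      any(startsWith(newly, paste0(sid, ":"))), logical(1))]
  }

  out_records <- scaffolds
  gap_tables <- list(); conflicts <- NULL; consumed <- character(0)
  for (sid in names(results)) {
    res <- results[[sid]]
    out_records$seq[out_records$id == sid] <- res$record$seq
    res$gaps$scaffold <- sid
    gap_tables[[sid]] <- res$gaps
    conflicts <- rbind(conflicts, res$conflicts)
    consumed <- c(consumed, res$consumed)
  }
  # gaps of untouched scaffolds still belong in the report
  for (sid in setdiff(scaffolds$id, names(results))) {
    g <- find_gaps(scaffolds$seq[scaffolds$id == sid], min_gap_len)
    if (nrow(g))
      gap_tables[[sid]] <- data.frame(
        key = .gap_key(sid, g$start, g$end),
        orig_start = g$start, orig_end = g$end,
        cur_start = g$start, cur_end = g$end,
        status = "REJECTED", read_id = NA_character_,
        reason = "no_reads", replacement_len = 0L,
        left_trim = 0L, right_trim = 0L, scaffold = sid,
        stringsAsFactors = FALSE)
  }
  gaps <- do.call(rbind, gap_tables[intersect(scaffolds$id, names(gap_tables))])
  if (is.null(gaps))
    gaps <- data.frame(key = character(0), orig_start = integer(0),
                       orig_end = integer(0), cur_start = integer(0),
                       cur_end = integer(0), status = character(0),
                       read_id = character(0), reason = character(0),
                       replacement_len = integer(0), left_trim = integer(0),
                       right_trim = integer(0), scaffold = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(conflicts) && nrow(conflicts))
    conflicts <- unique(conflicts)
  rownames(gaps) <- NULL
  before <- assembly_stats(scaffolds, min_gap_len)
  after <- assembly_stats(out_records, min_gap_len)
  list(records = out_records,
       report = list(gaps = gaps, conflicts = conflicts,
                     consumed = unique(consumed),
                     before = before, after = after,
                     summary = fill_summary(before, after)))
}

#' Write the per-gap fill report as TSV
#'
#' One row per gap with its terminal decision. Coordinates are 1-based
#' inclusive (human-readable convention); `start`/`end` refer to the
#' gap's position in the input draft.
#'
#' @param report the `report` element of [run_pipeline()]'s result (or
#'   any list with a `gaps` table).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  g <- report$gaps
  out <- data.frame(scaffold = g$scaffold,
                    start = g$orig_start + 1L, end = g$orig_end,
                    status = g$status, read_id = g$read_id,
                    reason = g$reason,
                    replacement_len = g$replacement_len,
                    left_trim = g$left_trim, right_trim = g$right_trim,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
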