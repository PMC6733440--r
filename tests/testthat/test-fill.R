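# toy scale: 40 bp flanks, 15 bp gap, permissive-but-real thresholds
tp <- function() toy_params()

test_that("plan_fill fills from an exact spanning read with zero trims", {
  fx <- toy_gap_scaffold(seed = 101)
  read <- dna_records("m1/1/0_95",
                      paste0(fx$left, fx$truth, fx$right))
  d <- plan_fill(fx$scaffold, fx$gap, read, tp(),
                 flank_len = 40L, min_flank_len = 10L, max_trim = 5L)
  expect_equal(d$status, "FILLED")
  expect_equal(d$replacement, fx$truth)
  expect_equal(d$left_trim, 0L)
  expect_equal(d$right_trim, 0L)

  # the reverse-complemented read fills identically
  rc_read <- dna_records("m1/2/0_95", reverse_complement(read$seq))
  d2 <- plan_fill(fx$scaffold, fx$gap, rc_read, tp(),
                  flank_len = 40L, min_flank_len = 10L, max_trim = 5L)
  expect_equal(d2$status, "FILLED")
  expect_equal(d2$replacement, fx$truth)
})

test_that("plan_fill rejection reasons fire in the specified order", {
  fx <- toy_gap_scaffold(seed = 102)
  p <- tp()
  args <- list(flank_len = 40L, min_flank_len = 10L, max_trim = 5L)

  # read matching only the left flank
  d <- do.call(plan_fill, c(list(fx$scaffold, fx$gap,
                                 dna_records("r", fx$left), p), args))
  expect_equal(d$status, "REJECTED")
  expect_equal(d$reason, "no_right_anchor")

  # read matching nothing
  withr::with_seed(1, junk <- random_dna(90))
  d <- do.call(plan_fill, c(list(fx$scaffold, fx$gap,
                                 dna_records("r", junk), p), args))
  expect_equal(d$reason, "no_left_anchor")

  # flanks on opposite read strands
  chimera <- dna_records("r", paste0(fx$left, fx$truth,
                                     reverse_complement(fx$right)))
  d <- do.call(plan_fill, c(list(fx$scaffold, fx$gap, chimera, p), args))
  expect_equal(d$reason, "strand_mismatch")

  # anchors in the wrong order on the read
  swapped <- dna_records("r", paste0(fx$right, fx$truth, fx$left))
  d <- do.call(plan_fill, c(list(fx$scaffold, fx$gap, swapped, p), args))
  expect_equal(d$reason, "disordered_anchors")

  # flank tail beyond max_trim: read missing the last 8 bp of the left
  # flank (alignment must stop 8 bp before the gap) with max_trim 5
  clipped <- dna_records("r", paste0(substr(fx$left, 1, 32), fx$truth,
                                     fx$right))
  d <- do.call(plan_fill, c(list(fx$scaffold, fx$gap, clipped, p), args))
  expect_equal(d$reason, "below_threshold")
})

test_that("apply_fill splices exactly and checks staleness", {
  scf <- dna_records("s", "AAAANNNTTTT")
  dec <- structure(list(gap = list(start = 4L, end = 7L), read_id = "r",
                        status = "FILLED", replacement = "GGG",
                        left_trim = 0L, right_trim = 0L,
                        reason = NA_character_), class = "fill_decision")
  expect_equal(apply_fill(scf, dec)$seq, "AAAAGGGTTTT")

  # with a trim, the replacement supplies the trimmed base too
  dec$left_trim <- 1L; dec$replacement <- "AGGG"
  out <- apply_fill(scf, dec)
  expect_equal(out$seq, "AAAAGGGTTTT")
  # length accounting: delta = |replacement| - gap_len - trims
  expect_equal(nchar(out$seq) - nchar(scf$seq), 4L - 3L - 1L - 0L)

  # shorter replacement shortens the scaffold
  dec$left_trim <- 0L; dec$replacement <- "G"
  expect_equal(apply_fill(scf, dec)$seq, "AAAAGTTTT")

  # stale decision: the interval is no longer N
  expect_error(apply_fill(dna_records("s", "AAAAGGGTTTT"), dec), "stale")
})

test_that("fill_scaffold: serial loop, single use, locality", {
  # two gaps, two spanning reads -> both filled
  withr::with_seed(201, {
    ref <- random_dna(400)
  })
  scf_seq <- ref
  substr(scf_seq, 101, 120) <- strrep("N", 20)
  substr(scf_seq, 281, 300) <- strrep("N", 20)
  scf <- dna_records("s", scf_seq)
  r1 <- dna_records("m1/1/0_160", substr(ref, 41, 200))
  r2 <- dna_records("m1/2/0_160", substr(ref, 221, 380))
  res <- fill_scaffold(scf, rbind(r1, r2), tp(), flank_len = 40L,
                       min_flank_len = 10L, max_trim = 5L)
  expect_equal(res$gaps$status, c("FILLED", "FILLED"))
  expect_identical(res$record$seq, ref)
  expect_equal(sort(res$consumed), sort(c(r1$id, r2$id)))

  # one read spanning both gaps fills only the first (single use);
  # a later read may fill the second
  rspan <- dna_records("m1/3/0_400", ref)
  res2 <- fill_scaffold(scf, rspan, tp(), flank_len = 40L,
                        min_flank_len = 10L, max_trim = 5L)
  expect_equal(res2$gaps$status, c("FILLED", "REJECTED"))
  expect_equal(res2$gaps$read_id[1], rspan$id)
  res3 <- fill_scaffold(scf, rbind(rspan, r2), tp(), flank_len = 40L,
                        min_flank_len = 10L, max_trim = 5L)
  expect_equal(res3$gaps$status, c("FILLED", "FILLED"))
  expect_equal(res3$gaps$read_id, c(rspan$id, r2$id))
  # no read id in two FILLED decisions
  expect_false(any(duplicated(
    res3$gaps$read_id[res3$gaps$status == "FILLED"])))

  # empty read list -> unchanged
  res4 <- fill_scaffold(scf, r1[0, ], tp())
  expect_identical(res4$record$seq, scf$seq)
  expect_equal(res4$gaps$status, c("REJECTED", "REJECTED"))
  expect_equal(res4$gaps$reason, c("no_reads", "no_reads"))

  # locality: bytes outside the fill windows are untouched
  g <- res$gaps
  for (i in seq_len(nrow(g))) {
    w0 <- g$orig_start[i] - g$left_trim[i]
    w1 <- g$orig_end[i] + g$right_trim[i]
    expect_identical(substr(res$record$seq, 1, 40),
                     substr(scf$seq, 1, 40))
    expect_lte(w0, g$orig_start[i])
  }
  expect_identical(substr(res$record$seq, 1, 100 - 0),
                   substr(scf$seq, 1, 100))
})

test_that("run_pipeline preserves structure and validates ids", {
  tr <- simulate_fixture(seed = 301, ref_len = 8000L, n_gaps = 2L)
  extra <- dna_records("lonely_scaffold", strrep("ACGT", 50))
  scaffolds <- rbind(tr$scaffolds, extra)

  # empty evidence: output identical to input
  res0 <- run_pipeline(scaffolds, tr$reads, stats::setNames(list(), character(0)))
  expect_identical(res0$records, scaffolds)
  expect_equal(res0$report$summary$gap_bp_filled_pct, 0)

  # full run: count preserved, order preserved, untouched untouched
  res <- run_pipeline(scaffolds, tr$reads, tr$evidence)
  expect_equal(res$records$id, scaffolds$id)
  expect_equal(nrow(res$records), nrow(scaffolds))
  expect_identical(res$records$seq[2], extra$seq)
  expect_equal(sum(res$report$gaps$status == "FILLED"), 2L)
  expect_identical(res$records$seq[1], tr$reference)

  # monotonicity
  expect_lte(res$report$after$gap_bp, res$report$before$gap_bp)
  expect_lte(res$report$after$gap_count, res$report$before$gap_count)

  # id validation
  expect_error(run_pipeline(scaffolds, tr$reads,
                            list(nope = tr$evidence[[1]])),
               "unknown scaffold")
  expect_error(run_pipeline(scaffolds, tr$reads,
                            stats::setNames(list(c("ghost_read")),
                                            tr$scaffolds$id)),
               "unknown read")
})

test_that("conflicting same-well reads abort exactly their gaps", {
  tr <- make_conflict_fixture(
    simulate_fixture(seed = 401, n_gaps = 3L, per_gap_reads = 0L))
  expect_equal(nrow(tr$reads), 2L)
  res <- suppressWarnings(
    run_pipeline(tr$scaffolds, tr$reads, tr$evidence))
  g <- res$report$gaps
  keys <- attr(tr, "conflict_keys")
  expect_setequal(g$key[g$status == "ABORTED_CONFLICT"], keys)
  expect_equal(g$status[!g$key %in% keys], "REJECTED")
  expect_equal(nrow(res$report$conflicts), 1L)
  expect_match(res$report$conflicts$gap_ids, keys[1], fixed = TRUE)
  # the conflicted gaps are untouched N-runs in the output
  expect_identical(res$records$seq, tr$scaffolds$seq)

  # counterfactual: dropping one of the pair restores normal filling
  tr2 <- tr
  tr2$reads <- tr2$reads[1, , drop = FALSE]
  tr2$evidence[[1]] <- tr2$reads$id
  res2 <- run_pipeline(tr2$scaffolds, tr2$reads, tr2$evidence)
  g2 <- res2$report$gaps
  expect_equal(g2$status[g2$key == keys[1]], "FILLED")
  expect_equal(sum(g2$status == "ABORTED_CONFLICT"), 0L)
})

test_that("write_report emits one row per gap and round-trips counts", {
  tr <- simulate_fixture(seed = 501, n_gaps = 3L)
  res <- run_pipeline(tr$scaffolds, tr$reads, tr$evidence)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(res$report, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$status %in%
                    c("FILLED", "REJECTED", "ABORTED_CONFLICT")))
  expect_equal(sum(tab$status == "FILLED"),
               sum(res$report$gaps$status == "FILLED"))
  # 1-based inclusive coordinates
  expect_equal(tab$start, res$report$gaps$orig_start + 1L)
  expect_equal(tab$end, res$report$gaps$orig_end)
})
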