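#' Simulate a random reference sequence
#'
#' I.i.d. bases with `P(G or C) = gc`. All simulator randomness is
#' locally seeded ([withr::with_seed()]): the caller's RNG state is
#' untouched and identical seeds give identical output.
#'
#' @param length sequence length in bp.
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed integer seed (mandatory).
#' @return a DNA string.
#' @export
simulate_reference <- function(length, gc = 0.5, seed) {
  stopifnot(length >= 1, gc >= 0, gc <= 1)
  withr::with_seed(seed, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
}

#' Replace reference windows with N-runs of equal length
#'
#' Emulates what scaffolding leaves behind: the scaffold is the
#' reference with `n_gaps` disjoint internal windows overwritten by N,
#' so each gap's true sequence is known. Gaps keep at least
#' `min_segment` known bp between one another and `end_margin` bp to
#' each scaffold end (so full-length flanks always exist). By default
#' the N-run length equals the truth length (no length misestimation);
#' `gap_len_jitter` perturbs the N-run length by up to that many bp in
#' either direction to emulate a scaffolder's gap-size errors.
#'
#' @param reference DNA string.
#' @param n_gaps number of gaps (0 allowed).
#' @param gap_len_range integer `c(min, max)` of truth lengths, sampled
#'   uniformly (default 100-500 bp).
#' @param min_segment minimum known bp between gaps (default 700).
#' @param end_margin minimum known bp before the first / after the last
#'   gap (default 500).
#' @param seed integer seed.
#' @param gap_len_jitter max absolute N-run length perturbation
#'   (default 0).
#' @param scaffold_id id for the returned record.
#' @return list with `record` (one-row record table) and `truths`
#'   (data.frame `start`, `end` 0-based half-open on the scaffold,
#'   `truth_start`, `truth_end` on the reference, `seq`).
#' @export
make_gapped_scaffold <- function(reference, n_gaps,
                                 gap_len_range = c(100L, 500L),
                                 min_segment = 700L, end_margin = 500L,
                                 seed, gap_len_jitter = 0L,
                                 scaffold_id = "scaffold_1") {
  L <- nchar(reference)
  if (n_gaps == 0L)
    return(list(record = dna_records(scaffold_id, reference),
                truths = data.frame(start = integer(0), end = integer(0),
                                    truth_start = integer(0),
                                    truth_end = integer(0),
                                    seq = character(0))))
  withr::with_seed(seed, {
    lens <- sample(seq.int(gap_len_range[1], gap_len_range[2]), n_gaps,
                   replace = TRUE)
    slack <- L - 2L * end_margin - sum(lens) - (n_gaps - 1L) * min_segment
    if (slack < 0L)
      stop("infeasible gap geometry: reference too short for ", n_gaps,
           " gaps with these margins")
    extra <- sort(floor(stats::runif(n_gaps, 0, slack + 1)))
    starts <- end_margin + extra +
      cumsum(c(0L, lens[-n_gaps] + min_segment))
    jit <- if (gap_len_jitter > 0L)
      sample(seq.int(-gap_len_jitter, gap_len_jitter), n_gaps,
             replace = TRUE) else rep(0L, n_gaps)
  })
  ends <- starts + lens
  truths <- data.frame(start = starts, end = ends,
                       truth_start = starts, truth_end = ends,
                       seq = substring(reference, starts + 1L, ends),
                       stringsAsFactors = FALSE)
  # splice with possibly jittered N-run lengths; recompute scaffold coords
  pieces <- character(0); pos <- 0L; scf_starts <- integer(0)
  off <- 0L
  for (i in seq_len(n_gaps)) {
    pieces <- c(pieces, substr(reference, pos + 1L, starts[i]),
                strrep("N", lens[i] + jit[i]))
    scf_starts[i] <- starts[i] + off
    off <- off + jit[i]
    pos <- ends[i]
  }
  pieces <- c(pieces, substr(reference, pos + 1L, L))
  truths$gap_start <- scf_starts
  truths$gap_end <- scf_starts + lens + jit
  list(record = dna_records(scaffold_id, paste(pieces, collapse = "")),
       truths = truths)
}

#' Apply a PacBio-like error model to a sequence
#'
#' Per-base, with probability `rate` an error occurs; its kind is drawn
#' from `mix` (substitution : insertion : deletion, default 6:2:2 of the
#' rate). A substitution always changes the base; an insertion adds one
#' uniform base after the position; a deletion drops the base.
#'
#' @param seq DNA string.
#' @param rate per-base error probability in `[0, 1)`.
#' @param mix length-3 non-negative weights `c(sub, ins, del)`.
#' @param seed integer seed.
#' @return the mutated DNA string.
#' @export
mutate_sequence <- function(seq, rate, mix = c(sub = 6, ins = 2, del = 2),
                            seed) {
  stopifnot(rate >= 0, rate < 1, length(mix) == 3L, all(mix >= 0))
  if (rate == 0) return(seq)
  withr::with_seed(seed, {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    n <- length(ch)
    op <- rep("M", n)
    err <- stats::runif(n) < rate
    op[err] <- sample(c("S", "I", "D"), sum(err), replace = TRUE,
                      prob = mix / sum(mix))
    bases <- c("A", "C", "G", "T")
    is_s <- op == "S"
    if (any(is_s)) {
      # substitute with one of the three other bases, uniformly
      cur <- match(ch[is_s], bases)
      shift <- sample(1:3, sum(is_s), replace = TRUE)
      ch[is_s] <- bases[((cur - 1L + shift) %% 4L) + 1L]
    }
    is_i <- op == "I"
    if (any(is_i))
      ch[is_i] <- paste0(ch[is_i],
                         sample(bases, sum(is_i), replace = TRUE))
    paste(ch[op != "D"], collapse = "")
  })
}

#' Simulate gap-spanning long reads
#'
#' For each gap, `per_gap_reads` reads are cut from the ungapped
#' reference over `[truth_start - flank_margin, truth_end +
#' flank_margin)`, mutated at `error_rate`, and each reverse-complemented
#' with probability one half. Names follow the PacBio subread
#' convention `movie/well/start_end` with one unique well per read.
#'
#' @param reference DNA string (the ungapped truth).
#' @param truths the `truths` table of [make_gapped_scaffold()].
#' @param flank_margin bp of known sequence captured on each side of the
#'   gap (default 400; must be at least the `flank_len` used when
#'   filling, so that full anchors lie inside the read).
#' @param error_rate per-base error probability (default 0).
#' @param per_gap_reads reads per gap (default 2).
#' @param seed integer seed.
#' @param movie movie token used in read names.
#' @param first_well well number of the first read.
#' @param error_mix see [mutate_sequence()].
#' @return a record table of reads, grouped by gap in gap order.
#' @export
simulate_spanning_reads <- function(reference, truths, flank_margin = 400L,
                                    error_rate = 0, per_gap_reads = 2L,
                                    seed, movie = "m54321_190909_010203",
                                    first_well = 1L,
                                    error_mix = c(sub = 6, ins = 2, del = 2)) {
  L <- nchar(reference)
  ids <- character(0); seqs <- character(0)
  well <- first_well
  k <- 0L
  for (i in seq_len(nrow(truths))) {
    w0 <- max(0L, truths$truth_start[i] - flank_margin)
    w1 <- min(L, truths$truth_end[i] + flank_margin)
    for (j in seq_len(per_gap_reads)) {
      k <- k + 1L
      s <- substr(reference, w0 + 1L, w1)
      s <- mutate_sequence(s, error_rate, error_mix, seed = seed + 7L * k)
      flip <- withr::with_seed(seed + 7L * k + 3L,
                               stats::runif(1) < 0.5)
      if (flip) s <- reverse_complement(s)
      ids <- c(ids, sprintf("%s/%d/0_%d", movie, well, nchar(s)))
      seqs <- c(seqs, s)
      well <- well + 1L
    }
  }
  if (k == 0L)
    return(dna_records(character(0), character(0)))
  dna_records(ids, seqs)
}

#' Simulate a complete gap-filling fixture with ground truth
#'
#' Reference, gapped scaffold, spanning reads and evidence map in one
#' call; the package's stand-in for a real assembly + scaffolding run,
#' with every gap's true sequence known.
#'
#' @param ref_len reference length (default 20000 bp).
#' @param gc GC fraction (default 0.5).
#' @param n_gaps gaps per scaffold (default 3).
#' @param gap_len_range,min_segment,end_margin,gap_len_jitter see
#'   [make_gapped_scaffold()].
#' @param flank_margin,error_rate,per_gap_reads,error_mix see
#'   [simulate_spanning_reads()].
#' @param seed integer seed driving all stages.
#' @param scaffold_id scaffold record id.
#' @return list of class `sim_truth`: `reference`, `scaffolds` (record
#'   table), `truths`, `reads`, `evidence` (named list scaffold ->
#'   read ids), `config` (the resolved arguments).
#' @export
simulate_fixture <- function(ref_len = 20000L, gc = 0.5, n_gaps = 3L,
                             gap_len_range = c(100L, 500L),
                             min_segment = 700L, end_margin = 500L,
                             flank_margin = 400L, error_rate = 0,
                             per_gap_reads = 2L, gap_len_jitter = 0L,
                             error_mix = c(sub = 6, ins = 2, del = 2),
                             seed, scaffold_id = "scaffold_1") {
  reference <- simulate_reference(ref_len, gc, seed)
  gs <- make_gapped_scaffold(reference, n_gaps, gap_len_range,
                             min_segment, end_margin, seed = seed + 1L,
                             gap_len_jitter = gap_len_jitter,
                             scaffold_id = scaffold_id)
  reads <- simulate_spanning_reads(reference, gs$truths, flank_margin,
                                   error_rate, per_gap_reads,
                                   seed = seed + 2L,
                                   error_mix = error_mix)
  evidence <- stats::setNames(list(reads$id), scaffold_id)
  if (nrow(reads) == 0L) evidence <- stats::setNames(list(), character(0))
  structure(list(reference = reference, scaffolds = gs$record,
                 truths = gs$truths, reads = reads, evidence = evidence,
                 config = list(ref_len = ref_len, gc = gc, n_gaps = n_gaps,
                               gap_len_range = gap_len_range,
                               min_segment = min_segment,
                               end_margin = end_margin,
                               flank_margin = flank_margin,
                               error_rate = error_rate,
                               per_gap_reads = per_gap_reads,
                               gap_len_jitter = gap_len_jitter,
                               seed = seed)),
            class = "sim_truth")
}

#' Add a same-well conflict pair to a fixture
#'
#' Prepends two error-free subreads sharing one `(movie, well)` key, the
#' first spanning the fixture's first gap and the second its second gap:
#' exactly the situation the origin guard must abort, since one physical
#' molecule cannot anchor two disparate loci. The pair comes first in
#' evidence order so that, absent the guard, it would be the pair that
#' fills those gaps.
#'
#' @param truth a `sim_truth` with at least 2 gaps.
#' @param well well number shared by the pair (default 999).
#' @param movie movie token of the pair.
#' @return the augmented `sim_truth`, with attribute `conflict_keys`
#'   naming the two gap keys the pair spans.
#' @export
make_conflict_fixture <- function(truth, well = 999L,
                                  movie = "m99999_190909_999999") {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$truths) < 2L)
    stop("conflict fixture requires at least 2 gaps")
  fm <- truth$config$flank_margin
  L <- nchar(truth$reference)
  pick <- function(i, range_start) {
    w0 <- max(0L, truth$truths$truth_start[i] - fm)
    w1 <- min(L, truth$truths$truth_end[i] + fm)
    s <- substr(truth$reference, w0 + 1L, w1)
    list(seq = s,
         id = sprintf("%s/%d/%d_%d", movie, well, range_start,
                      range_start + nchar(s)))
  }
  r1 <- pick(1L, 0L)
  r2 <- pick(2L, nchar(r1$seq))
  extra <- dna_records(c(r1$id, r2$id), c(r1$seq, r2$seq))
  truth$reads <- rbind(extra, truth$reads)
  sid <- truth$scaffolds$id[1]
  truth$evidence[[sid]] <- c(extra$id, truth$evidence[[sid]])
  attr(truth, "conflict_keys") <- .gap_key(
    sid, truth$truths$gap_start[1:2], truth$truths$gap_end[1:2])
  truth
}

#' Write a fixture to disk as plain-text files
#'
#' Writes `reference.fasta`, `scaffolds.fasta`, `reads.fasta`,
#' `evidence.tsv` and `truth.json` into a directory.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dna_records("reference", truth$reference),
              file.path(dir, "reference.fasta"))
  write_fasta(truth$scaffolds, file.path(dir, "scaffolds.fasta"))
  write_fasta(truth$reads, file.path(dir, "reads.fasta"))
  ev <- data.frame(
    scaffold = rep(names(truth$evidence), lengths(truth$evidence)),
    read = unlist(truth$evidence, use.names = FALSE))
  utils::write.table(ev, file.path(dir, "evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(config = truth$config, truths = truth$truths),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
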