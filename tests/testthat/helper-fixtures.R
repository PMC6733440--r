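# permissive thresholds for unit tests on short synthetic sequences
loose_params <- function(...) {
  args <- list(min_raw_score = 0L, min_identity = 0, min_aln_len = 1L,
               max_hits = 1L)
  ovr <- list(...)
  args[names(ovr)] <- ovr
  do.call(scoring_params, args)
}

# strict-but-short: anchor rules active at toy flank scale
toy_params <- function(...) {
  args <- list(min_raw_score = 10L, min_identity = 0.8,
               min_aln_len = 12L, max_hits = 1L)
  ovr <- list(...)
  args[names(ovr)] <- ovr
  do.call(scoring_params, args)
}

write_tmp_fasta <- function(records, width = 60L) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  write_fasta(records, path, width = width)
  path
}

# a handcrafted scaffold around one gap, with everything known
toy_gap_scaffold <- function(seed = 1, flank = 40L, gap = 15L) {
  withr::with_seed(seed, {
    left <- random_dna(flank)
    truth <- random_dna(gap)
    right <- random_dna(flank)
  })
  list(scaffold = dna_records("scf", paste0(left, strrep("N", gap), right)),
       left = left, truth = truth, right = right,
       gap = data.frame(start = flank, end = flank + gap))
}
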