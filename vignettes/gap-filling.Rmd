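---
title: "Flank-anchored gap filling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flank-anchored gap filling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfillr)
```

## The procedure and its assumptions

A draft assembly after long-read scaffolding consists of scaffolds in
which the unknown sequence between joined contigs is written as runs of
`N`. The reads that created each join usually span the corresponding
gap, so the missing sequence can be read off them — provided the read
is placed correctly. `gapfillr` operationalises "placed correctly" as
the **two-anchor rule**. For a gap `[s, e)` on a scaffold:

1. Extract the **flanks**: up to `flank_len` bp of contiguous non-N
   sequence immediately left of `s` and right of `e`. Flanks stop at
   the scaffold end or at a neighbouring gap — anchors must be
   contiguous known sequence.
2. Locally align each flank against the candidate read, on both
   strands, under an affine-gap model, and filter the hits by raw
   score, identity and alignment length. Exactly one hit must survive
   per flank (`max_hits = 1` makes "at most one" into "the unique
   best").
3. Both hits must be on the same read strand, and on the
   strand-oriented read the left anchor must end at or before the right
   anchor starts.
4. The **replacement** is the oriented read subsequence between the two
   anchors. The unaligned flank tails between each anchor and the gap
   edge (the *trims*) must not exceed `max_trim`; the fill overwrites
   gap plus trims with the replacement.

The loop over (read, gap) pairs is strictly serial: reads are taken in
evidence order; after every applied fill the draft is updated and the
remaining gap coordinates recomputed; a read that has filled a gap is
consumed and attempts no further gaps; a rejected attempt leaves the
read available for other gaps. This is the strictest reading of
"each read used once" that still lets one read be *tested* against
several gaps. Gaps are attempted in coordinate order, scaffolds in
input order, so the output is deterministic.

The method assumes (i) the scaffolder's read-to-scaffold evidence is
trustworthy enough to restrict the search — a read listed under
scaffold A is never allowed to fill scaffold B; (ii) gap length
estimates may be wrong (no constraint ties the replacement length to
the N-run length); and (iii) flanks of a few hundred bp are unique
within the read, which the uniqueness requirement enforces rather than
presumes.

### The origin guard

PacBio subread names follow `movie/well/start_end`; subreads sharing
`(movie, well)` come from one sequenced molecule and must therefore
anchor near-identical genomic loci. When fills by same-well subreads
would touch two *different* gaps, all those fills are aborted and a
conflict is logged (such conflicts also flag likely scaffolding
errors). Because the loop is serial, the first of the conflicting fills
has already been applied by the time the second is attempted; the
engine therefore resolves conflicts as a fixpoint: run the pass, detect
conflicts among the applied fills, mark every implicated gap
`ABORTED_CONFLICT`, and re-run the pass with those gaps excluded until
no conflict remains. Aborted gaps are terminal — they stay as N. The
same fixpoint runs across scaffolds at pipeline level. Same-well
subreads filling the *same* gap are consistent and never conflict;
reads whose names do not parse are exempt from the guard.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `match_reward` / `mismatch_penalty` | +1 / −2 | score | BLAST-like nucleotide scoring |
| `gap_open_penalty` / `gap_extend_penalty` | −5 / −2 | score | command-line BLAST convention; a gap run of length k costs open + k·extend |
| `min_raw_score` | 50 | score | twice the classic "raw score 25" floor, which is typical even of unrelated sequences |
| `min_identity` | 0.80 | fraction | above the lenient 0.70 often used; CLR error rates still pass comfortably |
| `min_aln_len` | 100 | bp | an anchor must be a third of a full flank |
| `max_hits` | 1 | count | anchors must be unique — the core correctness requirement |
| `flank_len` / `min_flank_len` | 300 / 50 | bp | 300 bp gives headroom over `min_aln_len`; shorter than 50 bp is no anchor |
| `max_trim` | 10 | bp | local alignments may shed a few noisy bases at the gap edge; bounded so fills cannot erode known sequence |
| `min_gap_len` | 1 | bp | every N counts as gap currency |

Defaults are deliberately stricter than permissive BLAST-based fillers;
all are exposed on the API and the CLI. Relax them only with an
independent post-hoc check of the fills.

## What the simulator emulates — and what it does not

`simulate_fixture()` builds a stated world with full ground truth: an
i.i.d. random reference (default 20 kb, GC 0.5); 3 internal windows of
100–500 bp replaced by N-runs of the same length (≥ 700 bp of known
sequence between gaps, ≥ 500 bp to the ends, so full flanks always
exist); and, per gap, 2 spanning reads cut from the ungapped reference
with 400 bp margins, each reverse-complemented with probability ½ and
named `movie/well/0_len` with unique wells. Errors are applied per base
at a configurable rate with a substitution : insertion : deletion mix
of 6 : 2 : 2. All randomness flows from one explicit seed through
locally scoped generators; the session RNG is untouched.

This emulates enough structure to test the *engine*: anchored recovery,
strand handling, trims, single use, the origin guard
(`make_conflict_fixture()` prepends an error-free same-well pair
spanning two different gaps), and gap-length misestimation
(`gap_len_jitter`). It does **not** emulate repeats, chimeric reads,
coverage biases, realistic PacBio indel-heavy error profiles, or
scaffolding mistakes other than the same-well conflict. A green
recovery test therefore establishes that the discipline is implemented
correctly, not that real drafts will fill at any particular rate.

## Numerical and design choices

* **Alignment backend.** Hits are computed with
  `Biostrings::pairwiseAlignment` (affine Smith–Waterman in C); the
  wrapper enforces the package's conventions: `N` scores as a mismatch
  against everything including `N` (so N-runs cannot self-anchor), a
  gap of length k costs `open + k·extend`, coordinates are reported
  0-based half-open on the forward read with an explicit strand. The
  test suite re-derives optimal scores with an independent plain-R
  Gotoh dynamic program on ~10³ random pairs, so the backend is checked
  against an oracle rather than trusted.
* **Multiple hits.** For `max_hits > 1` the target interval of each
  accepted hit is masked with `N` and the search repeated; reported
  hits never overlap on the target. With the default `max_hits = 1`
  this machinery only ever returns the unique best hit.
* **Tie-breaking.** Hit ordering is fully specified: score descending,
  then target start, then `+` strand, then read id. Equal-scoring
  forward/reverse alignments prefer `+`.
* **Rejection reasons** are assigned in a fixed order
  (`no_left_anchor`, `no_right_anchor`, `strand_mismatch`,
  `disordered_anchors`, `below_threshold`); trim-bound violations and
  empty or N-containing replacements report `below_threshold`; a gap
  never attempted reports `no_reads`. An ambiguous anchor (more than
  one surviving hit, possible only when `max_hits > 1`) counts as no
  unique anchor.
* **Coordinates** are 0-based half-open internally and 1-based
  inclusive in reports. After each fill, downstream gap coordinates are
  shifted by `|replacement| − gap_len − trims` and cross-checked
  against a re-scan of the sequence; a mismatch is an internal error,
  not a warning.
* **Rounding** of report percentages is half-up (gap % to 2 decimals,
  fill/reduction % to 1), matching how such tables are conventionally
  printed; R's banker's rounding would differ on exact halves.
* **Degenerate inputs.** Empty evidence returns the input unchanged
  with a complete report; a gap whose flank is shorter than
  `min_flank_len` is rejected, not an error; unknown scaffold or read
  ids in the evidence are hard errors; the empty-assembly N50 is 0 with
  a warning.
* **Parallelism.** The unit of parallel work is the scaffold
  (`threads > 1` uses forked workers); results are merged in input
  order and the conflict fixpoint runs globally afterwards, so output
  is byte-identical to the serial run.
* **One pass.** The pipeline does not iterate gap filling to a
  fixpoint over the whole assembly (multi-pass refilling is a
  different tool's strategy); a single serial pass matches the design
  being emulated.

## Known limitations

* Only plain-text FASTA input; no FASTQ/BAM or compressed files.
* The evidence dialects are this package's own documented formats; the
  commercial scaffolder's internal directory layout is not publicly
  specified, so an import shim may be needed.
* Flank-sized exact alignment is cheap, but offering every read to
  every gap is O(reads × gaps) per scaffold; very read-rich scaffolds
  pay for the strictness in time (linear in reads, as expected for the
  serial design).
* The origin guard keys on read *names*; renamed or merged reads
  bypass it.

## A worked check

```{r example}
tr  <- simulate_fixture(seed = 7, ref_len = 15000, n_gaps = 2)
res <- run_pipeline(tr$scaffolds, tr$reads, tr$evidence)
res$report$gaps[, c("key", "status", "replacement_len")]
identical(res$records$seq, tr$reference)
```

Every number shown in the package documentation is produced by the
package's own tests, examples or the acceptance script at run time.
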