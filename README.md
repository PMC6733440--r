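# gapfillr

Strict, flank-anchored filling of N-gaps in draft genome scaffolds,
using only the long reads that built each scaffold.

## The problem

Scaffolding joins contigs into scaffolds and marks the unknown sequence
between them as runs of `N` ("gaps"). The long reads that created those
joins usually contain the missing sequence, but naive BLAST-style gap
filling with lenient defaults lets a single read align — and fill — in
many places at once, corrupting large drafts. `gapfillr` implements a
disciplined alternative:

* **scaffold-local evidence** — a scaffold is only ever offered the
  reads the scaffolder associated with it;
* **two-anchor rule** — a gap is filled only when both of its flanks
  (up to 300 bp of contiguous known sequence on each side) have exactly
  one surviving local-alignment hit on the read, on the same strand and
  in the right order; the replacement is the read subsequence spanned
  between the anchors;
* **strict thresholds** — affine-gap Smith–Waterman hits must clear a
  raw score of 50 at ≥ 80 % identity over ≥ 100 columns (raw score
  `= #match·m + #mismatch·x + Σ_gaps (g_open + k·g_ext)`, defaults
  `m=+1, x=−2, g_open=−5, g_ext=−2`); all configurable;
* **single use** — a read is consumed by its first successful fill and
  never used again;
* **ZMW origin guard** — PacBio subreads sharing a `(movie, well)` key
  come from one molecule; if such subreads anchor two different gaps,
  both fills are aborted and the conflict logged.

Gaps are recomputed on the current draft after every applied fill, the
loop is strictly serial and deterministic, and the output always has
exactly as many sequences as the input (the tool never merges or
splits scaffolds). Assembly statistics (N50, gap count/bp/%) are
reported before and after.

N50 is the largest length `L` such that sequences of length ≥ `L`
contain at least half of the total assembly length.

## Worked example

Simulate a 15 kb reference, cut two gaps of known truth into it, span
them with error-free PacBio-style reads, and fill:

```r
library(gapfillr)
tr  <- simulate_fixture(seed = 7, ref_len = 15000, n_gaps = 2)
res <- run_pipeline(tr$scaffolds, tr$reads, tr$evidence)
print(res$report$before)
print(res$report$after)
res$report$gaps[, c("key", "status", "read_id", "replacement_len")]
identical(res$records$seq, tr$reference)
```

prints

```
1 sequence(s), 15000 bp, N50 15000 | gaps: 2 runs, 858 bp (5.72%)
1 sequence(s), 15000 bp, N50 15000 | gaps: 0 runs, 0 bp (0.00%)
                     key status                       read_id replacement_len
1   scaffold_1:8612-9062 FILLED m54321_190909_010203/1/0_1251             451
2 scaffold_1:11602-12008 FILLED m54321_190909_010203/3/0_1207             407
[1] TRUE
```

Both gaps were closed (858 N bp → 0), each by a single consumed read,
and the final scaffold is byte-identical to the reference the fixture
was cut from — the simulator knows every gap's true sequence, so
recovery is checked exactly.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "gapfillr.R", package = "gapfillr"))') \
  fill --scaffolds scaffolds.fasta --reads reads.fasta \
       --evidence evidence.tsv --out final.fasta --report report.tsv \
       [--min-identity 0.8 --min-score 50 --min-aln-len 100 \
        --flank-len 300 --max-trim 10 -t 4]
```

Subcommands: `fill` (above; `-t N` partitions scaffolds across workers
with byte-identical output), `stats --in FA [--compare FA]` (sequence
count, total bp, N50, gap #, gap bp, gap %), and
`simulate --out-dir D --seed N [...]` (writes reference, scaffolds,
reads, evidence and truth files). Exit codes: 0 success, 2 usage error,
3 data error.

Evidence formats: a two-column TSV (`scaffold_id<TAB>read_id`, no
header) or a directory of per-scaffold files named `<scaffold_id>.*`
(FASTA record ids or one read id per line). The optional FASTA index
sidecar `<fasta>.gfidx` is a tab-separated `id / byte offset / length`
table.

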