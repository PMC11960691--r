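---
title: "Delineating a male-specific region from X-Y divergence and sex-linked markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating a male-specific region from X-Y divergence and sex-linked markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msyscan)
```

## The problem

On a young sex chromosome pair, most of the Y still recombines with the X
(the pseudoautosomal region, PAR) and only a limited segment is inherited
strictly through males (the male-specific region, MSY). Where recombination
stops, the Y accumulates substitutions, indels and transposable elements
independently of the X, so the PAR/MSY boundary leaves several signatures
at once:

* windowed X-Y sequence divergence jumps from autosome-like levels to a
  markedly higher plateau;
* RAD-seq tags present in males and absent in all females map into the
  distal segment;
* in pooled sequencing of each sex, sites heterozygous in every XY male
  (allele frequency ~0.5 in the male pool, 0 in the female pool) cluster
  distally;
* repeats are denser and, having inserted after recombination arrest,
  younger (lower Kimura two-parameter distance to their family consensus).

`msyscan` implements this whole evidence chain as testable components: a
trio-binning read classifier for building haplotype-resolved assemblies, an
orthologous X-Y aligner with a windowed SNP+indel divergence statistic and
changepoint detection, the RAD and pool-seq marker scans, an
evidence-synthesis gene annotation merger, the repeat age contrast, and a
consensus report. A seeded synthetic generator produces every input with
planted ground truth, so each stage is verifiable end to end without any
external data.

## The divergence statistic

The Y is the alignment target throughout; all windows are Y-indexed.
Alignment proceeds in the classic chain/net style:

1. **Seeding** — all maximal runs of exact k-mer matches (default k = 15)
   that are unique in both sequences.
2. **Chaining** — dynamic-programming selection of co-linear anchor chains
   maximising anchored bases minus an affine cost
   `gap_open + gap_extend * |dt - dq|` on the coordinate offset between
   consecutive anchors. A bounded predecessor lookback (64) keeps the scan
   near-linear; for small anchor sets it is exhaustively optimal, which the
   test suite checks against a subset-enumeration oracle.
3. **Gap filling** — banded affine-gap global alignment (match +1,
   mismatch -1, gap open 2, gap extend 1, a length-L gap costing
   `2 + L`) of every inter-anchor region up to `max_gap` (20 kb); larger
   regions stay unaligned and are flagged. The same scores drive the
   full-matrix `Biostrings::pairwiseAlignment` oracle the tests compare
   against: on random pairs up to 2 kb the seed-chain-fill divergence
   agrees within 0.1 percentage points.
4. **Netting** — chains are accepted greedily by descending score and
   trimmed at column resolution so that every Y base is covered at most
   once, retaining the orthologous alignment at each locus.

Each alignment column is classified as match, mismatch (SNP), `t_gap`
(gap in the Y) or `q_gap` (gap in the X). Per window the divergence is

```
divergence_pct = 100 * (n_snp + n_indel_cols) / max(aligned_cols, 1)
```

**Numerical choices.** Windows are non-overlapping 10 kb tiles by default
(`step_bp = window_bp`); an overlapping mode exists but one value per tile
is what the windowed plot of such analyses shows. The numerator counts
indel *columns* (gap bases), which keeps the statistic a per-column
proportion bounded by 100%; an event-count mode (`indel_mode = "events"`)
is available since either convention is defensible. The denominator is the
number of aligned columns, not the window length, so sparsely aligned
windows are not artificially deflated — instead windows below 25% aligned
coverage are flagged low-confidence and excluded from boundary detection
by default. Columns are assigned to windows by the Y coordinate of their
left flank; `t_gap` columns, which consume no Y base, attach to the left
flanking position.

**Boundary detection.** A single changepoint is chosen by exhaustive scan
over window edges, minimising the total within-segment squared error of the
divergence series (at least 5 windows per side; ties broken to the
rightmost edge). A single split is the default because a lone divergence
stratum is the expected configuration for a young Y; the fold change
`mean_after / mean_before` is reported, and calls with fold < 1.5 are
flagged `no_transition`. The flag guards against segmenting flat series:
on a uniform-rate null with window counts near the real-data regime
(tens to hundreds of events per window) it fires in ≥95% of runs. At
extreme down-scaling (≈10 events per window) the SSE-optimal split can
isolate noise tails with fold ≥ 1.5, so very small windows on very short
chromosomes should not be over-interpreted — a general caveat for windowed
scans, not only this one.

## The synthetic scenario

The generator's defaults encode the reference study conditions: a 28.5 Mb
Y with the PAR/MSY transition at 23.5 Mb; substitution/indel rates of
0.008/0.0005 per base in the PAR and 0.048/0.003 in the MSY with geometric
indel lengths of mean 4. With these rates the expected windowed difference
is ~1% proximally and ~6% distally — a fivefold-to-sixfold contrast — which
is what the divergence scan must recover. Telomere-like `(TTAGGG)n` termini
(3 kb) are placed on both sequences; they are repeat-only DNA that the
unique-seed aligner must handle via gap filling.

`scale` (default 0.1 for a 2.85 Mb test chromosome) multiplies
genome-coordinate quantities only: chromosome length, boundary, telomere,
marker-placement cutoffs, the pool mapping mask. Per-base rates and
instrument-scale lengths (indel mean length, 95 bp tag length, read
lengths, repeat element lengths) are deliberately not scaled, so expected
divergence percentages and marker properties are scale-invariant; truth
coordinates scale linearly. Window sizes scale alongside (1 kb windows at
scale 0.1 stand in for the 10 kb windows of a full-size analysis).

Other planted structure:

* **RAD design** — 25 males and 25 females, 2,000 tag loci of 95 bp cut
  from the simulated Y, of which 200 are truly male-limited: each lands
  distal of the 24 Mb-equivalent cutoff with probability 0.70, otherwise
  uniformly in the 20-23.5 Mb-equivalent range, mirroring the observed
  distal concentration of male-only markers with a proximal scatter.
  Depths are Poisson (mean 20) with 10% per-individual dropout;
  male-limited loci have zero depth in every female.
* **Pools** — Poisson depth 50 per site. MSY sites segregate at frequency
  0.5 in the male pool and 0 in the female pool (one X and one Y per male).
  PAR differences are emitted as ordinary polymorphisms with one shared
  random frequency in both pools: in a recombining region a variant cannot
  be sex-linked across a pool, so treating planted PAR edits as fixed X-Y
  differences would fabricate sex-specific signal where the biology
  forbids it. A terminal 300 kb-equivalent interval receives no reads at
  all, emulating the mapping failure expected where the two species'/
  haplotypes' sequences have diverged too far; the window scan must flag
  such windows low-coverage rather than report confident zeroes.
* **Trio** — two 150 kb parental haplotypes at 2% substitution divergence;
  1,000 child reads with lognormal lengths (median 3 kb) and 1% read
  error. At k = 21 a 2 kb read carries hundreds of parent-unique k-mers,
  so the majority-count classifier should misassign well under 1%.
* **Genes** — ~30 true multi-exon models. For a fraction of genes the
  best homology model carries a terminal exon extended into unsupported
  sequence while a lower-scoring model retains the correct exon: the exact
  constellation in which terminal-exon rescue must fire and restore the
  truth. Ab initio models are truth-equal and fully supported where
  homology evidence is absent, plus unsupported decoys and fully supported
  duplicates overlapping homology clusters (which must not be recruited).
* **Repeats** — alternating exponential gaps and lognormal element
  lengths tuned to 35% (PAR) / 55% (MSY) merged base fraction; element
  ages are truncated-normal Kimura distances (PAR mean 0.20, MSY mean
  0.15, sd 0.06), converted to transition/transversion proportions under a
  two-parameter substitution process with transition/transversion rate
  ratio 2, so `kimura2p()` recovers the target age exactly.

What the generator does **not** emulate: read-level quality profiles,
reference bias, paralogy and repeat-induced mismapping, population-level
polymorphism segregating within the sexes, assembly errors. Passing tests
therefore demonstrate the correctness of the statistics and algorithms
under a clean generative model, not robustness to every artefact of real
data.

## Marker modules

**RAD tags.** Catalog construction collapses identical reads per
individual and merges tags across individuals by single-linkage at ≤2
substitutions between equal-length sequences (the convention of standard
RAD catalog software). Presence is depth ≥ 1 by default — real data would
warrant a higher floor, which is exposed. Male-only calling requires
presence in at least `min_males` males (half the males in the pipeline
default) and at most 0 females. Mapping is ungapped seed-and-extend on
both strands with match +1 / mismatch -2, scored hits converted to a
Karlin-Altschul E-value `E = K * m * n * exp(-lambda * S)` with ungapped
nucleotide constants (lambda = 1.28, K = 0.46); the classic `e-40` cutoff
keeps a perfect 95 bp hit on a chromosome-sized target and discards
short or degraded ones. Positional enrichment is a one-sided exact
binomial test of the fraction of best hits inside a region against the
region's length fraction.

**Pool scan.** A site is male-specific when some allele sits within
[0.40, 0.60] in the male pool and at ≤0.05 in the female pool, with both
pools at depth ≥10 (female-specific symmetric). The thresholds are
conventions of pooled sex-scan tools, recorded in output headers; a
criterion of this shape is forced by XY heterogamety (expected frequency
0.5 vs 0), and the band/tolerance widths trade power against depth noise
at Poisson 50.

**Gene evidence.** Support of a model is
`0.5 * mean(per-exon covered fraction) + 0.5 * fraction of matched
junctions` (single-exon models: exon term only) — the equal weighting is
an artifact choice; "best supported" is all the upstream description pins
down, and both the weights and the rescue threshold tau = 0.5 are
parameters. Clusters are connected components of same-strand exonic
overlap (exon-level, not span-level, so intron-nested genes stay
separate). Rescue replaces a terminal exon with coverage < tau by a
strictly better-covered terminal exon from an eliminated cluster member
that shares all other junctions of the kept model and meets it at the
same inner junction boundary — identity of the shared structure prevents
chimeras, and a replacement that would create overlapping exons is
rejected. "Fully supported" for ab initio recruitment is strict
(coverage 1.0 on every exon, every junction matched): the rule's word is
"fully", and softening it would recruit partially confirmed predictions.
The merge is idempotent, and on the generator's output it reproduces the
planted truth exactly.

**Repeat ages.** Kimura distances come from supplied per-element
transition/transversion proportions (`kimura2p()`, with domain checking),
or from paired element/consensus alignments via `pq_from_alignment()`.
The PAR/MSY age contrast is a two-sided Wilcoxon rank-sum test with
medians reported — a rank test is the checkable surrogate for the
"younger elements" claim since it assumes nothing about the age
distributions' shape; samples under 5 per side are flagged underpowered.
No CpG-adjusted Kimura variant is implemented.

## Consensus report

The divergence MSY is `[changepoint, chrom_end)`. The RAD interval spans
from the lower edge of the upper 90% mass of male-only hit positions to
the chromosome end; the consensus is the **intersection** of the two
(union available). Intersection is the conservative choice because
different marker sets can genuinely delimit different proximal borders
when recombination suppression expanded differently across populations —
the report therefore presents both intervals rather than electing one.
The pool scan and repeat contrast are reported as supporting / neutral /
conflicting flags; the pool evidence in particular can lose signal
exactly where divergence is highest (mapping failure), so it flags rather
than vetoes.

## Problem sizes and determinism

The package's own test and acceptance runs use the scale-0.1 scenario
(2.85 Mb, 1 kb windows, seeds 1-5), a 600 kb uniform-rate null with 4 kb
windows for the no-transition check (100 replicates), 50 random pairs up
to 2 kb for the alignment oracle, and 10 seeds for exact annotation
recovery — sizes chosen so the full evidence chain, including one hundred
null alignments, completes on a single CPU in minutes while every
statistic keeps enough events per window to be meaningful. All randomness
descends from one scenario seed through fixed per-component substreams,
so any stage can be regenerated independently and byte-identically.

## Known limitations

* The chaining lookback is a heuristic: pathological anchor sets (massive
  off-diagonal repetition) could hide the optimal chain beyond the
  lookback window. Unique-seed anchoring makes this rare on real-ish
  input.
* Netting trims at column level but keeps the largest remaining block of
  a trimmed chain; a chain split into many fragments by a higher-scoring
  competitor is not re-scored.
* The boundary model is a single mean shift (one stratum). Multiple
  strata would need the multi-split mode and a model-selection rule.
* The E-value model is ungapped with fixed constants; it is a threshold
  rule, not a full aligner statistics model.
* `run_pipeline()` is single-threaded; the `--threads` style options of
  the CLI are accepted but advisory.
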