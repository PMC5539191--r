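---
title: "Reference-free plastome assembly from k-mer frequency structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free plastome assembly from k-mer frequency structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plastid)
```

## The model

Whole-genome shotgun (WGS) libraries from plants contain chloroplast DNA at
a far higher molar concentration than nuclear DNA, because every cell
carries many plastids and every plastid many genome copies. `plastid`
exploits the signature this leaves in the canonical k-mer frequency
spectrum of the raw reads:

* sequencing errors produce a large population of k-mers seen once or a
  handful of times (the *error peak* at the left edge of the spectrum);
* the single-copy nuclear genome contributes k-mers at a low frequency
  proportional to the nuclear coverage;
* single-copy plastome sequence (the LSC and SSC regions) forms a distinct
  peak at the plastome coverage; and
* the inverted repeat (IR), present in two exact reverse-complement
  copies, forms a second peak at **exactly twice** the single-copy peak
  frequency.

That 2x relation is the anchor of the whole method: no other genomic
component produces a locked pair of peaks, so the pair identifies the
chloroplast band without any reference sequence. Reads carrying k-mers
from the band covering both peaks are highly enriched for plastome
origin; nuclear repeats that happen to fall in the band are removed later
by homology, size and re-selection filters rather than up front.

K-mers are counted canonically: of a window and its reverse complement,
the representative whose **middle base is A or C** is tallied (k must be
odd; the middle base of the reverse complement is always the complement of
the middle base, so exactly one of the two qualifies). The *volume*
histogram weights each frequency f by the number of distinct k-mers at f
times f, which makes the histogram proportional to read volume rather
than to distinct-k-mer counts and renders the peaks visible above the
error population.

## The five stages

1. **Counting.** `count_kmers()` builds the sorted canonical k-mer table
   (k = 31 by default) and `kmer_histogram()` its frequency/volume
   histogram, exportable at bin widths 1, 10, 25, 100 and 250.
2. **Band selection and initial assembly.** A frequency band covering both
   chloroplast peaks is chosen — by inspection, or automatically by
   `detect_peaks()`, which smooths the volume curve, takes local maxima
   above the error floor, and calls the maxima pair (p, q) with
   |q − 2p| ≤ 0.15·2p maximising combined volume, with default band
   [p/2, 3q/2]. Reads containing a band k-mer are selected, shuffled once,
   and assembled as nested batches of increasing size across a sweep of De
   Bruijn K values (all odd 63..99 by default; data volume and K both
   shape assembly quality, so the sweep hedges against both). Candidates
   are filtered by reference k-mer containment (when a reference is
   configured), by scaffold size (< 2K dropped), and by a total-length
   sanity range, then ranked.
3. **Iterative re-selection.** The current best assembly's own k-mers
   re-select reads from the raw set, the sweep re-runs, and the internal
   overlap merger — aware that a circle with an IR is expected — joins
   scaffolds. Only strict rank improvements are accepted; the stage stops
   on circularity, no improvement, or an iteration cap.
4. **End extension and re-scaffolding.** If the assembly is linear, reads
   are mapped back (internal exact-seed, ungapped-extension mapper); reads
   overhanging scaffold ends, plus unmapped mates of end-anchored reads,
   are assembled per end and merged in. After the last iteration, read
   pairs linking two scaffold ends are tallied in a connectivity matrix
   and supported junctions are bridged with N runs — sometimes closing the
   circle.
5. **Gap filling.** For each N run, flanking context (500 bp a side) is
   extracted; a *positive* k-mer table from the contexts selects reads, a
   *negative* table from everything outside the contexts discards reads,
   and the survivors are assembled in small nested batches (1000
   read-pairs increments) across the K sweep. Candidate scaffolds shorter
   than K are dropped; the rest are anchored onto both flanks and the best
   closure per gap is spliced in. Iteration stops when all gaps close, no
   gap improves, or the cap is reached.

## Ranking

Candidates are ranked by (a) fewest scaffolds, (b) fewest gaps, (c)
longest total length. The published criteria are applied lexicographically
by default (`ranking_mode = "lexicographic"`); the alternative
`"scaffolds_plus_gaps"` minimises scaffolds + gaps before length, which
matches the manual re-selection applied in two of the original case
studies where the lexicographic best was over-long or gap-ridden. Both
modes break remaining ties by fewer N bases, then by sweep order (smaller
batch, then smaller K), making the ranking a deterministic total order.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_count` | 31 | selection k-mer size (odd; canonical middle-base rule) |
| `K_values` | 63..99 odd | De Bruijn assembly sweep |
| `batch_start` / `batch_increment` | 100,000 / 100,000 | read-pair batch sizes |
| `gap_flank` | 500 bp | gap context on either side |
| `gap_batch` | 1000 | stage-5 batch size and increment |
| `size_ranges$total` | 100–250 kb | assembly sanity range |
| `min_edge_coverage` | 3 | De Bruijn coverage cutoff |
| `min_links` | 3 | pair support to scaffold two contigs |
| `min_overlap` | 50 bp | scaffold end overlap for merging |
| `gap_n` | 100 | N bases per bridged junction |
| `ir_min_length` | 1 kb | minimum IR to annotate |
| `max_iterations` | 10 | per-stage iteration cap |

`min_edge_coverage`, tip length (2K), `min_links` and `min_overlap` are
internal to the replaced external assembler in the original workflow and
are therefore our own choices: coverage 3 removes isolated error k-mers at
any realistic plastome depth while tolerating 30x data; tips shorter than
2K are overwhelmingly error spurs; 3 read pairs is the conventional
scaffolding support floor; 50 bp makes a chance exact overlap
(4^-50) impossible in practice. `gap_n = 100` is a fixed placeholder run
length — bridged gap lengths are unknown by construction, and a fixed
value keeps reruns byte-identical (an insert-size estimate would make
output depend on mapping detail).

## Numerical and design choices

* **Windows containing N are skipped** in counting and matching (raw
  Illumina data contains N calls); the skipped count is retained as an
  attribute.
* **Odd k is enforced** everywhere: the middle-base canonicalization is
  undefined for even k.
* **Greedy overlap merging takes the longest overlap first**, with two
  repeat-aware refinements. First, a scaffold whose *both* physical ends
  are each contested by two junction candidates matches the IR signature
  (one fragment used forward and reverse-complemented in two contexts); it
  is duplicated so both junctions can be made. Second, when the longest
  candidate overlap competes with others for a scaffold end — which is how
  a repeat longer than the true junction overlap manifests — each
  competitor is tried as the forced first merge, the greedy pass completes
  from there, and the arrangement that best closes the genome (circular,
  then fewest scaffolds, then longest) wins. Without the second rule a
  partial IR copy shared by two fragments can win on length and
  misassemble the circle.
* **Containment absorption**: scaffolds that are exact substrings of
  another (either strand) are absorbed before merging.
* **Circle closure has three rungs.** A single merged scaffold first
  closes on a direct suffix/prefix self-overlap; because the two copies of
  a terminal redundancy are assembled independently, this comparison
  tolerates a sequencing-error-scale mismatch rate (1%) even when
  junction merging is exact. If that fails, a *fold* closure looks for an
  interior reoccurrence of the scaffold's prefix — the period of a walk
  that went around the circle more than once, possibly switching SSC
  orientation at the second pass — and accepts the implied circle only if
  every window of the whole walk maps back onto it at high identity.
  Finally, an *IR completion* handles a linear scaffold that consumed its
  only IR copy (LSC + IR + SSC): its two ends are reverse complements of
  interior IR positions, and when both anchors match uniquely the circle
  is completed by regenerating the second IR copy between them.
* **Accepted assemblies must be read-supported.** Stages 3 and 4 accept a
  candidate only when every interior non-N position is covered, with a
  10 bp margin on both sides, by at least one read placed at >= 90%
  identity (circular candidates are checked across their origin on the
  pseudo-circularized sequence). A repeat-mediated misjoin juxtaposes
  sequence no read spans — such reads accumulate mismatches and fail the
  identity filter — so the false junction shows up as an uncovered run of
  about twice the margin; isolated uncovered bases, which arise from read
  subsampling, are tolerated.
* **Stage 3 merges the incumbent first.** The stage-2 best is raw
  assembler output whose contigs often still share junction overlaps;
  applying the internal merger to it before any re-selection round can
  close the circle outright instead of waiting for a sweep candidate to
  do so.
* **Gap closures are ranked by read support**: among closures anchored on
  both flanks, the minimum read-k-mer count across the gap-spanning
  windows decides, then total anchored overlap. A De Bruijn bubble caused
  by a few co-located sequencing errors can survive the coverage cutoff
  and produce a closure differing by one base; its support minimum is the
  error depth, so the read-consensus closure wins.
* **SSC orientation is not resolvable** from short-range pairs (inserts
  never span a full IR); layouts expose both configurations
  (`two_circular`), the three fragments (`three_linear`), or one
  configuration chosen by seeded RNG (`one_circular`, required by stages
  4–5). `circular_identity()` and `plastome_orientations()` compare
  assemblies up to rotation, strand and SSC orientation.
* **Pair policy**: whether read selection keeps whole pairs or individual
  mates is unspecified in the original description; the default
  `either_mate` keeps pairs intact for the assembler, with `both_mates`
  and `per_read` exposed.
* **Stage-3 re-selection draws from the full raw read set** each
  iteration. Re-selecting from the previous subset would monotonically
  shrink the pool and can lock in an early loss; the raw set lets a
  cleaner assembly re-attract reads its predecessor missed.
* The sanity ranges (total 100–250 kb, LSC 60–140 kb, SSC 5–30 kb, IR
  10–60 kb) bracket the published spread of finished plastomes
  (135–174 kb in the original case studies) with generous margins and are
  user-configurable; layout tolerates SSC length 0, the IR-expansion
  morphology.

## The simulator, and what passing tests do and do not show

`make_plastome()` draws uniform-random LSC/IR/SSC sequences and closes the
circle as LSC + IR + SSC + revcomp(IR); `make_nuclear()` adds a random
background with repeat families at stated copy numbers so that repeat
k-mers can deliberately collide with the chloroplast band;
`simulate_reads()` samples fragments uniformly (wrapping on the circle),
applies Normal(300, 30) fragment lengths, 100 bp mates and per-base
substitution errors, and writes the origin and coordinate of every pair
into its read id.

The default simulated conditions used throughout the tests are a 34 kb
plastome (LSC 20 kb, IR 5 kb, SSC 4 kb) at 100x single-copy coverage with
1% substitution errors over a 100 kb nuclear background at 2x. Real data
differ in ways the generator deliberately omits: GC-dependent coverage
bias (emulated only as an optional hard coverage hole, used to test gap
persistence), indel errors (the substitution-only model keeps ungapped
extension exact), quality-score structure, PCR duplicates, organellar
insertions in the nuclear genome (NUPTs), and heteroplasmy. Passing the
simulation suite therefore demonstrates the pipeline's logic — peak
pairing, enrichment, IR-aware circularization, gap repair — not its
robustness to every artifact of a particular sequencing chemistry.

## Problem sizes

The `toy_profile()` used by the test-suite and validation runs scales the
sweep to the simulated genomes: K in {21, 31, 41} (the published 63..99
sweep assumes far deeper read budgets than a 34 kb toy genome provides),
batches starting at 10,000 pairs with 10,000-pair increments (two nested
batches at toy coverage — enough to exercise the batch dimension while
keeping a full sweep to a handful of assemblies), overlap merging at the
smallest junction the K = 21 graph can produce (20 bp), IR annotation
from 500 bp, and sanity ranges bracketing a toy plastome. End-to-end
validation runs the complete pipeline on ten independently seeded
simulations and requires nine or more to finish as a circle at >= 99.9%
identity to the truth (up to rotation, strand and SSC orientation).

## Known limitations

* Exact counting is in-memory; gigabase-scale WGS datasets need the
  counting step swapped for an external counter behind the same table
  interface (the module boundary is designed for that).
* The internal assembler implements coverage cutoff, tip clipping and
  unambiguous-path contigs but no bubble popping; heterozygous or
  high-error data will fragment contigs sooner than a full-featured
  assembler would. The `assemble_fn` adapter in `sweep_assemble()`
  accepts an external assembler for that case.
* The internal mapper is ungapped; indel-rich data degrades end harvesting
  (an external SAM-producing mapper can stand in).
* Long reads are out of scope; the read model and the mapper both assume
  short, low-indel reads.
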