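---
title: "Mining 5S rDNA ribotypes from short reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining 5S rDNA ribotypes from short reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant 5S ribosomal DNA is organized as tandem arrays of a repeat unit that
couples a strongly conserved ~120-bp coding sequence (CDS) with a rapidly
evolving intergenic spacer (IGS), typically 155–360 bp. Within one genome
the array is not homogeneous: it carries a mixture of IGS sequence
variants — *ribotypes* — at very different copy proportions, alongside
pseudogenized repeats whose CDS is disabled by indels or multiple
substitutions. The set of ribotypes, their relative genomic content, and
IGS features such as GC content, internal tandem duplications, RNA
polymerase III promoter motifs and group-specific structural variants are
informative both for phylogenetic inference and for understanding
concerted evolution of the arrays.

`ribomine5s` reconstructs this picture from short sequencing reads:

1. **filter** reads containing 5S fragments with exact-matching 20-bp CDS
   probes;
2. **assemble** a strand-canonical k-mer graph (k = 31) of the filtered
   reads and resolve complete repeat units (one full IGS flanked by CDS
   fragments);
3. **call** ribotypes: deduplicate units, exclude pseudogenes, estimate
   each ribotype's relative content by mapping the complete library back
   to the catalog, and classify ribotypes as major (≥10%), minor (5–10%)
   or rare (<5%);
4. **characterize** the IGS (GC, lengths, similarity ranges, duplications,
   promoter motifs, structural variants);
5. **relate** ribotypes in a median-joining haplotype network.

A seeded simulator generates tandem arrays with a known ribotype
structure so that every stage is testable without downloading data.

## The synthetic-data generator

`sim_config()` fixes the study conditions. The defaults describe a
*Solanum*-like locus:

* repeat unit = 120-bp CDS + 210-bp IGS (the typical 190–220-bp range),
  IGS GC fraction 0.5;
* three ribotypes at geometrically decreasing proportions (0.571, 0.286,
  0.143) — surveys of real genomes consistently find one or two dominant
  ribotypes carrying most of the array;
* every ribotype derived from a *latent* ancestral spacer by 6 private
  substitutions. Six substitutions over 210 bp reproduce the ~97%
  intragenomic similarity that per-species spacer surveys report. The
  star-like structure (all ribotypes are children of an unsampled
  ancestor) is the shape intragenomic ribotype sets display in haplotype
  networks; it also means every ribotype owns private diagnostic columns.
* canonical Pol III signals planted in the ancestral IGS and protected
  from mutation — TTTAATA starting at offset −30, GC dinucleotides at −14
  and −12, GA at −3, a pyrimidine at −1 (offsets counted so −1 is the
  base immediately 5′ of the next CDS), and the oligo-T terminator TTTTT
  at the IGS 5′ end. These motifs are conserved in real spacers, which is
  why the generator treats them as immutable.
* a 20-copy array, 10% of copies pseudogenized (one 1–2-bp CDS indel or
  three CDS substitutions — exactly the lesions the detection rule
  triggers on), 300-bp random flanks;
* single-end 150-bp reads at 100× coverage, substitution errors only,
  both strands sampled uniformly.

Copy order in the array is a seeded shuffle: in vivo, variants may be
interleaved, and no stage of the pipeline is allowed to depend on order
(this is tested). Pseudogene CDS indels are planted away from the CDS
termini because a lesion at the very unit boundary is formally ambiguous
between a CDS indel and a length variant of the neighboring spacer — no
observer could attribute it.

What the generator does **not** emulate: realistic Illumina error
profiles (quality decay, indel errors), PCR duplicates, GC-coverage bias,
and copy numbers in the hundreds-to-thousands typical of real 5S arrays
(desk-scale tests run 20–50 copies; the array size mainly scales
coverage, not the combinatorics of variant resolution). Passing tests
therefore demonstrate correctness of the algorithms under a clean error
model, not robustness to every artifact of real libraries.

## Read filtering

All overlapping 20-mers of the CDS, closed under reverse complement, form
the probe set; a read is kept iff one of its windows equals a probe
exactly. Exact matching mirrors web-based SRA pre-filters; a sequencing
error inside the matched window loses that window, but because probes
tile the whole CDS a read overlapping the CDS by clearly more than 20 bp
is still caught. For paired data a pair is kept when either mate matches,
preserving junction-spanning information.

One systematic consequence matters downstream: reads lying entirely
inside a long IGS carry no CDS 20-mer and are removed. The filtered set
is therefore depleted exactly where ribotypes are most distinguishable.
Two stages compensate: branch support and coverage fitting during path
resolution use the *complete* library, and so does the abundance map-back
(which is also what the original workflow mapped).

## Assembly and repeat-unit resolution

The k-mer graph uses strand-canonical 31-mers (lexicographic minimum of a
k-mer and its reverse complement) since reads come from both strands.
Nodes below `min_kmer_coverage` are pruned — the package default of 5
suits 100× synthetic libraries; deep real libraries warrant the ~100
scale. `prune_and_assemble()` reports classical unitigs (maximal
unbranched paths, cycles linearized at a declared rotation), which is
what a homogeneous tandem array reduces to: one cycle plus flank tails.

With several ribotypes, however, every intra-genomic variant opens an
allelic bubble, and the shared CDS is a hub connecting all units; no
single unbranched contig spans a complete repeat. `resolve_repeat_paths()`
therefore works on the graph directly:

* **Seeded traversal.** Candidate units are all graph traversals from a
  CDS-start k-mer back to a CDS-start k-mer. The seed set contains the
  CDS 5′ k-mer plus every graph k-mer within 5 mismatches of it, so
  diverged or pseudogenized CDS copies both start and terminate
  traversals and every candidate spans exactly one unit. CDS copies whose
  lesions hide their start k-mer even from that set (an indel inside the
  first bases) are discovered adaptively: one representative over-long
  cycle is split by alignment, the hidden CDS start is added to the seed
  set, and enumeration repeats.
* **Branch support.** At graph branch points an extension is only
  followed if the trailing window of the grown path (default
  `read_length − 30` bp) occurs at least twice among the reads of the
  complete library. Requiring two occurrences rejects windows forged by a
  single sequencing error while true junctions are covered tens of times.
  Mosaic (chimeric) paths that combine variants of different ribotypes
  lying closer than the window are thereby excluded outright.
* **Coverage-balanced decomposition.** Variants farther apart than a read
  cannot be phased by any read-based evidence, so the remaining
  candidates (true units plus long-range chimeras) are disambiguated
  globally: candidate weights are fitted by non-negative least squares to
  the observed k-mer counts of the complete library, with candidates
  selected by orthogonal matching pursuit plus a forward–backward
  refinement when the dictionary is large. Chimeras receive no flow in
  this fit — at distinct ribotype proportions the decomposition is
  identifiable — and candidates below `min_flow` (2% of repeat flow) are
  dropped. Ribotypes below that flow are declared outside the desk-scale
  detection limit.

`extract_repeat_units()` then anchors the CDS in each resolved (or
user-provided) contig: full-length ungapped scan at ≤5 mismatches,
supplemented by an indel-tolerant prefix/suffix scan, a local-alignment
sweep for copies that defeat every ungapped scan, and a gapped refinement
of the CDS/IGS boundary so indel-bearing copies do not shift it. Each
pair of consecutive co-oriented anchors yields one unit, reported on the
CDS-sense strand with canonical start at the CDS first base.

As a final guard, `drop_unsupported_ribotypes()` removes catalog entries
with no uniquely best-mapping read: a chimera is never strictly better
than both its sources for any real read, whereas a true ribotype's
private columns attract strictly-best placements.

## Ribotype calling

The CDS consensus is the column-majority over the modal-length CDS set;
a unit is a pseudogene when its CDS alignment to the consensus shows any
indel or ≥3 substitutions ("several" operationalized as 3, because a
normal copy carries at most about two). Any IGS difference — substitution
or indel — separates ribotypes.

Relative content is estimated by mapping reads to each representative
unit doubled head-to-tail (so junction-spanning reads place), ungapped,
both strands, ≤2 mismatches. A read's unit weight is split equally among
the references tying at its minimum mismatch count; only reads whose best
placement overlaps the IGS by ≥20 bp contribute, and reads tying across
the *entire* catalog are excluded — both read classes are uninformative
about relative content and would only pull the estimates toward
uniformity. Pseudogene records serve as additional mapping references
whose weight folds into the catalog ribotype with the identical IGS:
the IGS copies carried by pseudogenized repeats still count among "all
IGS copies in the genome", and without those references the junction
reads of pseudogenized copies are lost and rare ribotypes are
systematically under-counted.

Classes follow the fixed thresholds: major ≥10%, minor 5–10%, rare <5%.
Note that a ribotype whose true content sits exactly at a class boundary
cannot be classified reliably by any finite-coverage estimator — at 100×
the estimates scatter with a standard deviation near 0.01, so a true 10%
ribotype lands on either side of the major threshold in a substantial
fraction of runs. The test suite accordingly asserts the modal
classification across seeds together with a strict bound (<0.02) on the
mean absolute content error.

## IGS features

* **GC content** is (G+C)/(A+C+G+T) with N excluded, reported to one
  decimal as a percent.
* **Pairwise identity** uses global alignment (match +1, mismatch −1, gap
  open −2, extend −0.5) with the alignment length as default denominator.
  Optional masking removes gap runs longer than 5 bp from numerator and
  denominator, so one long deletion does not swamp the point-mutation
  signal when survey-style similarity ranges are computed.
* **Tandem duplications** are found by self-comparison: shared 15-mers
  vote for a duplication period, the earliest seed of the best-supported
  period anchors the first copy, and further copies are located by gapped
  global–local alignment of the first copy against the immediately
  following sequence (adjacency gap ≤5 bp; divergence ≤20% of the unit).
  The search runs on the full unit because long spacer duplications can
  span the CDS 3′ end; the call reports the unit length, copy count, SNP
  and indel divergence between copies, and the CDS-derived/IGS-derived
  split when the CDS length is supplied. Duplication phase is only
  defined up to rotation, so copy spans may shift by a few chance-matching
  bases while the unit length and divergence stay exact.
* **Promoter/terminator motifs** are scanned in an offset window (±5)
  around their expected positions with per-motif mismatch budgets (1 for
  the 7-bp TATA-like box, 0 for dinucleotides), the terminator within the
  first 15 bp of the IGS 5′ end.
* **Structural variants** A–D are typed by presence/absence of two
  group-specific indel segments and a GC duplication on a reference
  alignment. The packaged reference alignment is synthetic (clearly
  labelled so in its filename): the decision logic is thereby fully
  testable, and users supply a real alignment plus YAML coordinates to
  type real material. A segment is present when ≥50% of its aligned
  columns carry query bases — robust to ragged alignment edges; segments
  the query's closest reference row lacks are assessed against the best
  row that carries them, so an inserted segment is not lost as an
  unmappable insertion.

## Haplotype networks

`align_small()` is a deterministic center-star progressive aligner (the
center maximizes the summed pairwise score; ties break by name), adequate
for the tens of catalog sequences a genome yields. `mj_network()` builds
a median-joining network: a minimum spanning network with tolerance
epsilon (default 0, the common default of network software) over distinct
haplotypes, iteratively augmented with quasi-medians of linked triples
whenever they reduce the total network cost, followed by deletion of
medians that no longer pay for themselves. Distances count differing
columns with the gap character as a fifth state — aligned spacers carry
many indels and ignoring gap columns would erase exactly the signal the
networks display. "Main clusters" are formalized as connected components
after removing edges heavier than `max_edge` (default 3 steps); the
original descriptions identify clusters visually and give no numeric
rule, so the threshold is exposed.

The greedy median insertion is deterministic (candidates ranked by cost
saving, then lexicographically) and is validated in the tests against
exhaustive small-instance checks: every observed haplotype present, edge
weights equal to recomputed distances, total cost never above the
observed-haplotype minimum spanning tree, and never above the best
single-median augmentation found by exhaustive candidate enumeration.

## Numerical and design choices

* All randomness flows from one integer seed per run; stage-specific
  seeds are derived deterministically, and identical configurations give
  byte-identical outputs.
* Problem sizes in tests and the acceptance script: 20-copy arrays at
  100× (about 4,800 reads) for the standard conditions, and 50-copy
  arrays for the mixture containing an 8% ribotype — the smallest array
  on which 8% is realizable exactly (on 20 copies, largest-remainder
  rounding turns 0.08 into 2/20 = 10%).
* Degenerate inputs: an empty read set gives an empty graph (warning), a
  probe-only background library completes with an empty catalog, single
  sequences give trivial alignments, and all-identical haplotypes give a
  single-node network.
* The 12-contig reporting cap of `prune_and_assemble()` mirrors the
  deep-library practice of keeping the highest-coverage contigs; the
  path-resolution stage works on the full pruned graph and is unaffected.

## Known limitations

* Variants of one ribotype separated by more than a read length cannot be
  phased by evidence; the coverage-balanced decomposition resolves them
  only when ribotype proportions are distinct. Near-equal proportions
  leave the decomposition non-identifiable in principle.
* Mismatch-only map-back ignores gapped placements; references assembled
  from the same data make this mostly harmless, but reads spanning a
  pseudogene's CDS indel can only be captured via the pseudogene
  reference, not the intact one.
* The SV typer ships with a synthetic reference; real structural-variant
  coordinates must be supplied by the user.
* Real 5S arrays are orders of magnitude deeper than the simulated ones;
  the per-k-mer coverage threshold must be scaled accordingly (the
  original deep-library setting is ~100 read support).
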