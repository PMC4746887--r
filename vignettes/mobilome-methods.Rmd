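---
title: "Methods: comparative mobilome annotation with mobilome"
author: "mobilome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mobilome annotation with mobilome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilome)
```

## Scope and model

`mobilome` implements a comparative transposable-element (TE) analysis
pipeline of the kind used to contrast mobilome density, diversity and
activity across related genomes: curate a non-redundant TE library, mask
each genome against it, convert per-hit divergences into a Jukes-Cantor
corrected "landscape" of TE activity through time, classify autonomous
LINE/LTR elements into families by amino-acid identity, and relate genome
size to TE content across species.  Every stage is exercised on synthetic
genomes with planted TE copies, so the statistical behavior of the whole
chain is testable without any external downloads.

The core quantities are:

* **Divergence `D`** — the percent of sites at which a genomic TE fragment
  differs from its library consensus, measured over aligned substitution
  columns only (gap columns excluded).  This matches the substitution-only
  assumption of the correction below; no CpG adjustment is applied, and
  that choice is deliberate and documented rather than configurable.
* **Corrected divergence `K`** — the estimated number of substitutions per
  site under the one-parameter Jukes-Cantor model,
  `K = -300/4 * ln(1 - 4D/300)` (both in percent).  `K >= D`, with
  equality only at zero; the correction compensates for multiple hits at a
  site.  Its domain ends at `D = 75`; hits at or beyond it (biologically
  implausible, usually parsing artifacts) are diverted to a spill bucket
  with a warning rather than silently dropped.
* **The 80-80 rule** — two nucleotide sequences belong to one family when
  a local alignment covers more than 80% of a sequence's length at more
  than 80% identity.  Whether "their length" means the shorter or the
  longer sequence is genuinely ambiguous in the literature; we default to
  the *shorter* sequence (the common 80-80-80 convention, which lets a
  fragment join its parent's family) and expose the denominator as a
  configuration switch (`coverage_denominator` in `curation_params()`).

## The synthetic mobilome

`simulate_genome()` draws an i.i.d. background at a configured GC content
(default 0.40, a typical teleost-like value) and plants TE copies of named
consensus sequences.  Each copy is:

1. mutated to a per-copy divergence drawn from the configured model —
   a point mass, a uniform range, a mixture of point masses, or a
   Jukes-Cantor Poisson process (`model = "jc"`), in which each site
   receives `Poisson(k)` substitution events and multiple hits can revert
   a site;
2. optionally 5'-truncated (LINE-like fragmentation, the single
   fragmentation mode — the simplest model that exercises partial-hit
   handling);
3. reverse-complemented with probability `strand_prob`;
4. written over the background at a uniformly drawn non-overlapping
   position (bounded rejection sampling; an infeasible packing raises an
   error rather than looping forever).

For the point-mass and uniform models exactly `round(p * L)` sites are
substituted, chosen without replacement, so the realized divergence of
every copy is known exactly and recorded in the truth annotation — the
oracle for all recovery tests.  The default mutation model is
substitution-only (no indels), matching the assumption under which `D` and
the Jukes-Cantor correction are defined and keeping truth divergences
exactly computable.

What the simulator does *not* emulate: nested insertions, transduction,
CpG-context mutation bias, segmental duplication, indel accumulation, and
non-uniform insertion-site preferences.  Tests that pass on these
synthetic genomes therefore demonstrate the correctness of the analysis
chain under its own model assumptions — not sensitivity parity with
production repeat annotators on real genomes, where those complications
are material.

## The homology masker

`mask_genome()` is a seed-and-extend nucleotide search: exact `k`-mer
seeds (default length 11, every consensus k-mer) located with
`Biostrings::matchPDict()` on both strands propose candidate loci, which
are refined by local (Smith-Waterman, affine-gap) alignment of the
consensus against a windowed genomic region.  Scoring defaults are
match +1, mismatch −1, gap open −2, gap extend −1; hits need a score of at
least 30 over at least 50 bp.  Overlaps between surviving hits are
resolved greedily by descending score, with a deterministic tie-break
(earlier start, then lexicographic library name) so output never depends
on input order; the lower-scoring hit is trimmed to its longest unclaimed
run or dropped.

With these defaults, an 11-mer survives in a 20%-diverged copy with
probability `0.8^11 ≈ 0.086` per seed position; a 400 bp consensus offers
~390 seed positions, so the probability that a ≤20%-diverged copy escapes
seeding entirely is negligible, while the joint score/length thresholds
keep random high-scoring segments out (a chance alignment of length ≥50
*and* score ≥30 is rare in 1 Mb of background).  On the package's standard
validation simulation (1 Mb genome, 400 bp consensus, 200 copies at 0–25%
divergence with 20% truncation), the acceptance suite measures ≥95% bp
recall of copies diverged ≤20%, ≤1% falsely masked bp, and a mean
absolute divergence error ≤1 percentage point; the exact values are
recomputed by `scripts/acceptance.R` on every run.

Real RepeatMasker `.out` annotation is accepted interchangeably through
`read_rm_out()`, so the internal masker is never a forced choice.  Two
RepeatMasker behaviors are intentionally not reproduced: CpG-adjusted
divergences (we always report the raw substitution proportion) and
simple-repeat/low-complexity masking (the internal masker handles
interspersed repeats only; those table rows appear only when ingesting
real `.out` files).

## Library curation

`collect_copies()` gathers the top-scoring non-overlapping genomic copies
of a query (default cap 40, at least 2 required), each with 500 bp of
flanking context clipped at contig ends.  Protein queries are searched by
exact amino-acid word seeds against six-frame translations, refined with
BLOSUM62 local alignment and mapped back to nucleotide coordinates — a
deliberately small TBLASTN-like search.  Significance is controlled by an
alignment-score threshold rather than an E-value: score thresholds are
directly reproducible across runs, and on shuffled-sequence nulls the
default (50) sits far above the best chance alignment score observed on
megabase-scale backgrounds.

`build_consensus()` takes the per-column majority base over non-gap
characters when those form the column majority, drops gap-majority columns
(this also trims flanking genomic sequence, which aligns as gaps in most
rows), and breaks base ties by the fixed precedence A > C > G > T so
consensus construction is deterministic.

`cluster_80_80()` computes the full pairwise 80-80 relation and returns
its single-linkage connected components.  Single linkage is the minimal
closure of a pairwise membership rule — no stronger merging criterion is
implied by the rule itself.  The representative of a cluster is a known
(database-derived) member when present, else the longest member, ties by
name; `merge_libraries()` therefore always preserves the classification of
known entries when de novo repeats duplicate them.

## Autonomous elements and families

`find_orfs()` enumerates ATG-to-stop ORFs in all six frames.
`detect_rt()` calls a reverse-transcriptase domain *intact* when a local
BLOSUM62 alignment against a user-supplied reference RT covers ≥80% of the
reference at ≥25% identity.  "Intact" has no standard operational
definition; these two thresholds are configuration (`rt_profile()`), and
the identity floor is set low deliberately — RT domains are detected
across superfamilies at low sequence identity, and the coverage
requirement is what rejects shuffled or fragmentary matches (verified
against shuffled-sequence nulls in the test suite).

`is_autonomous()` implements the autonomy filters: a LINE is autonomous
when its RT-bearing ORF (defined as ORF2 — by function, not position,
which is robust to 5' truncation) exceeds 700 aa *and* a second ORF lies
outside that ORF's footprint (overlapping ORFs on other frames of the same
region do not satisfy the two-ORF structure); an LTR element is autonomous
when some ORF above 500 aa carries an intact RT.  Both length thresholds
are strict (`>`), so a 700 aa ORF2 does not qualify while 701 aa does.

`cluster_families_aa()` groups autonomous elements at 80% amino-acid
identity of the comparison ORF (ORF2 for LINEs, the RT-bearing ORF for
LTRs), again by single linkage.  Identity is measured on an ends-free
(semi-global) alignment — terminal gaps excluded, because family members
legitimately differ in length by truncation — with the denominator floored
at the shorter protein's length.  The floor matters: a score-optimal
ends-free alignment of two unrelated proteins is typically a short
high-identity overlap, and without the floor such pairs would merge
spuriously.  A published variant of this family rule also invokes "the
structure of ORFs" as a secondary criterion; no operational definition of
that criterion exists, so only the identity criterion is implemented here
(noted as a known limitation).

## Landscapes and coverage tables

`landscape()` bins each hit's masked base pairs by its corrected
divergence `K` into half-open bins `[k, k + width)` (default width 1
percentage point), per classification group, and reports genome fractions.
Binning is per fragment, not per family average.  Whether published
landscape figures of this kind bin raw `D` or corrected `K` is usually
unstated; the default here is corrected, with `corrected = FALSE`
selecting raw `D`.  Mass is conserved exactly: bin totals plus the spill
bucket equal total hit bp.

`coverage_table()` produces hierarchical count/bp/percent tables
(class → superfamily by default).  Counts are hit (fragment) counts, as in
RepeatMasker-style summaries, not estimated element copy numbers; bp are
union-collapsed within each group; parent rows are exact sums of their
children via `coverage_rollup()`.  Percent denominators use total assembly
length including Ns — published denominators are typically unstated, and
total length is the only choice computable from the FASTA alone.

`size_te_regression()` is ordinary least squares of TE percent on genome
size (Mb) with the Pearson correlation, requiring ≥3 species and non-zero
variance (degenerate inputs error rather than returning NaN).

## Phylogenetics

`p_distance()` computes uncorrected amino-acid p-distances with pairwise
deletion by default (complete deletion available) — the common default of
distance-based protein phylogenies; the substitution model behind
published trees of this kind is often unstated, so the simplest model is
the default and the choice is explicit.  `nj_tree()` is a direct
Saitou-Nei neighbor-joining implementation (Q-criterion, standard branch
lengths).  Negative branch lengths are clamped to zero with the deficit
moved to the sister branch, preserving the path length through the joined
node — standard practice that keeps lengths interpretable.  Tie-breaks in
the Q matrix are deterministic (first minimum in column-major order).  On
additive matrices NJ provably recovers the generating topology; the test
suite checks exact topology and path-length recovery on random additive
4–8 taxon matrices and agreement with `ape::nj()` (an independent
implementation used only as a cross-check) on noisy ones.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the NJ tree per replicate, and reports for each internal split of
the full-data tree the percentage of replicates containing it.  Splits are
encoded as canonical bipartition signatures (the side not containing the
alphabetically first taxon), and taxa are sorted internally, so supports
are invariant to input order under a fixed seed.  The production-scale default
is 1000 replicates; validation runs use 100 replicates on small planted
designs, where family clades at ~50% between / ~5% within divergence are
recovered with ≥95% support.

## Determinism and numerical choices

* All stochastic stages consume a single seeded RNG in documented order;
  `simulate_genome()` and `bootstrap_support()` save and restore the
  caller's RNG state.  The pipeline derives per-species seeds from the
  global seed, and an unchanged config reproduces byte-identical outputs
  (verified by MD5 in the run manifest).
* Coordinates are 1-based inclusive everywhere, matching the
  RepeatMasker `.out` dialect, and `C` strand codes map to `-` on read.
* Greedy overlap resolution, consensus tie precedence, cluster
  numbering by sorted first member, and NJ tie-breaks are all
  deterministic, so no output depends on input order or hash iteration.
* Problem sizes used by the validation and acceptance runs — 1 Mb
  genomes with 200 planted copies of a 400 bp consensus, 100 kb
  round-trip sequences, 50-trial clustering oracles on ≤30-entry
  libraries, 100 bootstrap replicates — were chosen as the smallest
  designs at which the measured properties are stable, and they are
  stated in the tests themselves.

## Known limitations

* The masker targets interspersed repeats only and makes no claim of
  sensitivity parity with production annotators on real genomes;
  translated-space masking and HMM search are out of scope.
* The family rule for LINEs omits the undefined "ORF structure"
  criterion (identity only).
* Clade labels (e.g. named LINE or Gypsy clades) are not assigned
  automatically; they come from reference-anchored trees plus curation,
  with reference sequences supplied by the user as extra taxa.
* The simulator's realism limits are listed above; conclusions about
  real genomes require real annotation inputs, which the package accepts
  via `read_rm_out()`.
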