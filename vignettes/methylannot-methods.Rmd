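---
title: "Methods: models, parameters and design choices in methylannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in methylannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylannot)
```

`methylannot` rebuilds an expanded annotation of Infinium-style methylation
array probes and the statistics used to evaluate it. This vignette records
the models, the tunable parameters and their defaults, the numerical
choices that were genuinely open, and what a green test does and does not
establish. It states no empirical result that the test suite does not
itself compute.

## Coordinates and probe geometry

All internal coordinates are 0-based half-open; manifest MAPINFO (the
1-based genomic position of the C in the target CpG) and UCSC-style table
coordinates are converted on ingest, and BED output needs no conversion.

With `c0 = MAPINFO - 1`, the target CpG is always `[c0, c0 + 2)`. The
50-bp probe footprint depends on assay type and design strand:

| type | strand | footprint            | probe-without-CpG length |
|------|--------|----------------------|--------------------------|
| I    | F      | `[c0 - 49, c0 + 1)`  | 49                       |
| II   | F      | `[c0 - 50, c0)`      | 50                       |
| I    | R      | `[c0 + 1, c0 + 51)`  | 49                       |
| II   | R      | `[c0 + 2, c0 + 52)`  | 50                       |

The four offsets are not documented anywhere usable; they are fixed by the
package's own arbiter, sequence round-trip validation:
`validate_probe_against_genome()` rebuilds the expected probe sequence from
the genome (F designs are complementary to the bisulfite-converted minus
strand, so their sequence is the plus-strand footprint with convertible
minus-strand cytosines — plus-strand Gs — read out as A, G or the
degenerate R; R designs are the reverse complement of the converted plus
strand) and must reproduce the stored sequence exactly, with R matching A
or G. The generator builds probes by the same geometry, and the round-trip
test covers all four combinations — so the table above is internally
consistent by construction, which is all that desk-scale data can
establish. Type I probes carry both allele sequences (unmethylated A /
methylated B readings); type II carry one sequence with R at CpG-context
positions.

## CpG-density landscape

Island classes use strict thresholds on CG content, the
Gardiner-Garden–Frommer observed/expected CpG ratio
`(N_CpG × L) / (N_C × N_G)`, and length:

* HC: CG > 0.55, Obs/Exp > 0.75, length > 500 bp
* IC: CG > 0.50, Obs/Exp > 0.48, length > 200 bp
* UCSC: CG > 0.50, Obs/Exp > 0.60, length > 200 bp

The scanner seeds every minimum-length window that passes, merges
overlapping seeds, greedily extends a passing region 1 bp at a time while
it keeps passing, and trims failing merged regions 1 bp at a time from
whichever end scores better (higher CG content, then higher Obs/Exp; ties
trim the right end) until the region passes or dies. Windows containing N
never qualify, so assembly gaps break islands. Two contracts are enforced
by tests: every emitted island re-satisfies its thresholds when recomputed
over its final extent, and on fixtures with sharp (N-delimited) boundaries
the emitted base set equals the union of *all* threshold-passing windows
(the exhaustive oracle). Two caveats are worth recording. First, with
diffuse boundaries the greedy single-base extension is a local search: a
density dip wider than 1 bp can stop it short of where a larger jump would
still pass, so emitted boundaries are algorithm-defined to within the
boundary slack the tests assert (±50 bp on planted fixtures), not uniquely
determined by the thresholds. Second, raising the minimum length is not
guaranteed to shrink the called base set in diffuse surroundings (longer
minimum windows can legitimately reach further into a flank); the
monotonicity property is asserted for the density thresholds generally and
for length on sharp-boundary fixtures.

HIL merging: any base of HC density is HC; IC-density bases outside HCs
are ICshore when their maximal IC run overlaps or directly abuts an HC
(`gap_tol = 0` by default; the knob documents the ambiguity in "next to"),
otherwise IC; everything else is LC. Probe classes are decided by the base
under the target C; UCSC classes use distance from the target C to the
nearest island edge (1–2000 bp = shore, 2001–4000 bp = shelf). Island
names use 1-based inclusive coordinates (`chr8_IC:49890018–49891221`
style) while BED records stay 0-based half-open.

## Cross-hybridization screen

Four genome variants model bisulfite PCR products: all C→T (unmethylated)
and CpG-C preserved (methylated), each on the forward sequence and on its
reverse complement. Type II sequences containing R are expanded to exactly
two concrete versions (all-R→A, all-R→G). Candidates come from exact
12-mer seeds (every 12 bp plus the 3'-terminal seed, so placements with an
aligned 50th base are always generated), are scored ungapped, and the
intended target is always scored even if unseeded. Scoring trims terminal
mismatch runs — the aligned region runs from the first to the last
matching base, internal mismatches stay inside it — which mirrors how a
local aligner reports alignments and is the only reading under which the
acceptance rules ("identity ≥ 90% over the aligned region" *and* "≥ 40 of
50 matching bases") can both bind: an end-to-end region makes the identity
rule strictly stronger than the match floor and a 42/50 decoy could never
be accepted. The filter keeps a hit iff identity ≥ 0.90, matches ≥ 40,
no gaps, and the 50th base lies in the aligned region. Accepted hits are
collapsed to distinct loci by genomic footprint (chrom, start, end) across
variants, orientations, degenerate versions and alleles; a probe is
non-specific iff it has more than one distinct locus. An exhaustive
all-offsets scan over all variants and both orientations serves as the
oracle and must return the identical accepted-locus set on fixture
genomes. Repetitive content is the count of soft-masked (lowercase) bases
under the intended footprint; more than 25 flags a repetitive probe, and
50 lowercase bases on a specific probe flags the
"specific repetitive" class.

## SNP overlap

Only 1-bp, weight-1 SNP records survive ingest (one record per genomic
base). A SNP annotates the target CpG iff it sits on the C or the G — also
when the probe footprint excludes the G, since the G of the interrogated
dinucleotide affects the assay regardless of probe coverage. Proximity
classes measure inclusively from the nearest target-CpG base: within 10 bp
(inside the footprint) versus further into the footprint; probes with a
target-CpG SNP are removed from the `<10 bp` class for analyses. The fast
path is interval-tree overlap (IRanges); a vectorised all-pairs scan is
the test oracle at 10^4 × 10^4 scale.

## Gene features and TSS

Per transcript, each base carries exactly one component (first exon — the
most upstream exon in transcription direction — vs other exon vs intron)
and one region (5'UTR / body / 3'UTR from the tx/cds boundaries,
strand-aware; both label sets are asserted to partition the transcript).
The nine features are their intersections; a probe collects the feature at
its target C from every overlapping transcript, deduplicated by
(feature, transcript), with a per-gene collapsed view. Non-coding
transcripts (cdsStart = cdsEnd) have no definable UTR; all their bases are
labeled body and the transcript is flagged. Closest-TSS distances are
measured from the target C to each transcript's strand-aware TSS,
regardless of gene membership; ties go to the lexicographically smallest
transcript id and are flagged; a signed companion column (negative =
probe upstream in transcription direction) accompanies the unsigned
distance, since both conventions exist downstream.

## Methylation statistics

β = 2^M/(2^M + 1); the inverse clamps β ∈ {0, 1} inward by 1e-6
(configurable, logged) before taking log2(β/(1−β)). M from intensities
uses +1 pseudocounts on both channels. Within-group SDs use the n−1
denominator. The KS statistic is max |ECDF₁ − ECDF₂| with the asymptotic
two-sided tail (matching `ks.test(exact = FALSE)`; exact small-sample
tails were not needed for any contract here). The SD screen removes
probes with SD < 0.10 before distribution comparisons and flags SD ≥ 0.25
as highly variable. Methylation levels are boundary-inclusive exactly as
published: hypo ≤ 0.2, hyper ≥ 0.8.

Tissue-differential (tDM) selection averages per tissue and computes
`z = (μ₁ − μ₂)/√(s₁²/n₁ + s₂²/n₂)` with a two-sided normal tail and
Bonferroni correction at 0.05 (a pooled-variance option exists). A known
limitation, documented rather than patched: with per-tissue n as small as
4 the statistic is t-distributed with ~6 df and the normal tail is
anticonservative, so the family-wise error guarantee is asymptotic in n.
The null-calibration test therefore runs at n = 200/tissue, while the
power contract (planted Δβ = 0.3, SD = 0.05, detected at ≥ 90%) runs at
the published n = 4.

Percentage relative enrichment is `100 (f_tDM − f_all)/f_all` per class
(negative = depletion), invariant under duplicating every probe; the
composition test is a two-sided Fisher's exact test on the 2×2 tDM ×
class table with significance at p < 1e-7. The sex-difference screen runs
a limma moderated t on M values with Benjamini–Hochberg FDR — an explicit
stand-in for the original SAM machinery, tagged `method = "standin"` in
its output — crossed with a minimum |Δβ| between sex means; `min_delta =
0` reduces it to a pure FDR screen.

## The synthetic world

The generators produce every input the pipeline consumes, with
machine-readable truth, under explicit seeds (same seed, same bytes).

*Genome.* AT-biased background (default GC 0.36 with a trace CpG rate,
emulating repeat-poor intergenic sequence) with planted CpG-dense blocks,
lowercase repeat tracts, and an optional sex chromosome. Planted blocks
are drawn from a token model (CG dinucleotide with probability q, else a
single base with GC bias) and accepted only if (a) their realized CG
content sits in a narrow band just above the class threshold — so a block
qualifies for its class but cannot drag flanking sequence over the
threshold, keeping planted boundaries sharp — (b) IC blocks contain no
HC-qualifying window, and (c) the block is recovered as a single clean
island when scanned between AT pads. Rejected draws are redrawn from the
seeded stream, so determinism is preserved. For boundary-slack tests the
background is set to near-pure AT, which is the regime in which ±50 bp
recovery is a meaningful contract (in GC 0.36 background any
threshold-faithful scanner legitimately extends further into flanks).

*Decoys.* A cross-hybridization decoy copies a host probe's footprint
(with 1 bp of context) elsewhere and plants A↔T swaps: these survive every
bisulfite conversion and can never create or destroy CpG context, so the
decoy scores exactly 50 − k matches in every variant. The first four
swaps form a contiguous run at the probe's 5' terminus (trimmed from the
aligned region), the rest are internal; the 3'-terminal 12-mer stays
intact. The default 8 swaps give an accepted 42/46 = 91.3%-identity hit;
11 swaps give 39 matches, rejected.

*β matrices.* Per-probe models: `null` (a uniform-drawn mean with noise),
`trimodal` (Hardy–Weinberg genotypes at a declared allele frequency with
class centers 0.05/0.5/0.95 — the signature of a target-CpG SNP),
`tissue_diff` and `sex_diff` (planted effects). Noise is normal, clipped
to [0, 1] (a bounded stand-in; no heteroscedastic intensity artifacts are
emulated). Technical noise defaults to SD 0.05; when a test needs the
filtered-SD landscape of real data (SD comparisons presuppose probes
surviving the SD ≥ 0.10 filter), null probes can draw a per-probe
biological SD from a declared range — genotype-driven probes keep the
technical noise, so their flag rate is a model consequence, not a tuning
knob. Under the declared trimodal model the probability that a probe's
within-tissue SD reaches 0.25 is bounded by Hardy–Weinberg sampling: with
n = 24 and allele frequency 0.5, heterozygote-heavy draws (≈3% of
multinomials) stay below the flag threshold, so the measured flag rate is
≈0.96–0.97, not ≥0.99; the acceptance test asserts the stated 0.99 and is
expected to stay red, with the analysis recorded alongside the tests.

What a green suite establishes: internal consistency of the geometry,
filters and statistics on worlds whose truth is known, and equality with
independent brute-force oracles at desk scale. What it does not establish:
agreement with vendor annotation files, behavior on real intensity-level
artifacts (dye bias, probe-type shift, detection failures), or the
published full-genome headline counts, which require the external
reference inputs and are out of scope here.

## CLI and provenance

`methylannot_cli()` exposes `fixtures`, `islands`, `snps`, `genes`,
`specificity`, `stats` and `annotate` subcommands; every threshold is a
flag whose default is the published value, so the zero-configuration run
uses the reference thresholds throughout. Each run serializes its
resolved options to
`run_config.json` in the output directory; logs are line-delimited JSON;
exit codes are 0 (success), 2 (input error), 3 (partial annotation —
sections skipped for missing optional inputs).
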