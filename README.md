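# methylannot

Expanded probe annotation for Infinium-style DNA methylation arrays.

Genome-wide methylation arrays interrogate a CpG with a 50-nt probe, and a
probe's usefulness depends on things the vendor manifest only partly
records: whether a documented SNP sits in the interrogated CpG itself
(turning a genotype difference into an apparent methylation difference),
whether the probe hybridizes to more than one genomic locus after bisulfite
conversion (mixing signal across sites), how much of its footprint lies in
repeat-masked sequence, what kind of CpG-density neighborhood it measures,
and where it sits within gene structure. `methylannot` rebuilds all of this
annotation from first principles — manifest, genome FASTA, dbSNP-style and
refGene-style tables in; one merged per-probe table out — and implements the
downstream statistics used to evaluate the annotation classes on β-value
matrices. Everything runs on deterministic synthetic fixtures, so the full
pipeline is testable offline.

## What it computes

* **Probe intervals** — from the manifest's 1-based MAPINFO (the C of the
  target CpG), the three genomic intervals of each probe: the 2-bp target
  CpG, the 50-bp probe footprint (type I includes the C at its terminus,
  type II the 50 adjacent bases; F/R designs mirror), and the footprint
  minus the CpG. Validated by reconstructing each probe sequence from the
  genome (strand complementation + in-silico bisulfite conversion; the
  degenerate base R matches A/G).
* **Target-CpG SNPs** — 1-bp, weight-1 SNPs at the C *or* G of the target
  CpG; `<10 bp` / `>10 bp` proximity classes; heterozygosity bins.
* **Cross-hybridization screen** — probes aligned, ungapped, against four
  bisulfite genome variants (unmethylated/methylated x forward/reverse
  complement); type II R expanded to all-A and all-G versions; a hit is
  accepted iff identity ≥ 90% over the aligned region, ≥ 40/50 matching
  bases, no gaps, and the 3'-terminal (50th) base aligns. Probes with > 1
  distinct accepted locus are non-specific; hits are summarized by sex
  vs autosomal chromosome and repeat-masked (lowercase) bases are counted
  under each footprint.
* **CpG landscape** — island scanning with the Gardiner-Garden & Frommer
  Obs/Exp ratio `(N_CpG · L)/(N_C · N_G)`: HC islands (CG > 55%,
  Obs/Exp > 0.75, > 500 bp), IC islands (CG > 50%, Obs/Exp > 0.48,
  > 200 bp) and UCSC-style islands (CG > 50%, Obs/Exp > 0.60, > 200 bp).
  Probes get one HIL class (HC / IC / ICshore / LC, where ICshore is an
  IC-density run abutting an HC) and one UCSC class (island / shore =
  2 kb flanks / shelf = next 2 kb / sea).
* **Gene features** — nine classes from {first exon, exon, intron} x
  {5'UTR, body, 3'UTR} per transcript (strand-aware, multi-transcript),
  plus the closest TSS with unsigned and signed distances.
* **Methylation statistics** — β = 2^M/(2^M + 1) and its inverse;
  within-tissue SD screens (remove SD < 0.10, flag SD ≥ 0.25);
  hypo (≤ 0.2) / heterogeneous / hyper (≥ 0.8) levels; two-sample KS
  comparisons; tissue-differential probes by z-score with Bonferroni;
  percentage relative enrichment `100 (f_tDM − f_all)/f_all` per class with
  Fisher composition tests; a moderated-test + BH sex-difference screen
  (a documented stand-in for SAM) crossed with a Δβ floor.

## Worked example

```r
library(methylannot)

gg     <- gen_genome(seed = 1, sex_chrom_len = 20000)   # 100 kb chr1 + chrX
probes <- gen_probes(gg$genome, n = 20, seed = 2)       # all 4 type x strand designs
demo   <- altsplice_gene_models()                       # 5-transcript demo gene
snps   <- data.frame(rs_id = "rs1", chrom = "chr1",
                     pos = probes$mapinfo[1], weight = 1L, het = 0.3)

res <- annotate_all(probes, gg$genome, snps = snps, gene_models = demo$models)
table(res$table$HIL_CpG_class, res$table$UCSC_CpG_class)
```

```
          island sea shore
  HC           2   0     0
  ICshore      1   0     0
  LC           0  14     3
```

Probes landing in the planted high-density islands are classed `HC` (and
`island` under the UCSC criteria); the probe in the IC-density run next to
an HC is `ICshore`; background probes are `LC`/`sea`, with `shore` for the
three LC probes within 2 kb of an island (no probe of this draw falls in
the shelf band). `res$table` carries the merged columns
(`target CpG SNP`, `AlleleA_Hits`, `XY_Hits`, `n_bp_repetitive`,
`HIL_CpG_class`, `Closest_TSS`, the nine feature indicators, ...), and
`validate_probe_against_genome(probes, gg$genome)` confirms 20/20 sequence
round-trips.

A command-line front-end wraps the same pipeline:

```sh
Rscript -e 'methylannot::methylannot_cli()' fixtures make --seed 1 --out fx
Rscript -e 'methylannot::methylannot_cli()' annotate \
  --manifest fx/manifest.tsv --genome fx/genome.fa \
  --snp-table fx/snps.tsv --gene-table fx/genes.tsv --out annot
```

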