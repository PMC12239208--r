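# emsmapr

Bulked-segregant mapping and sector phasing of EMS-induced mutations.

`emsmapr` is an R package for geneticists running forward screens in plants
(or any diploid) with ethyl methanesulfonate (EMS) mutagenesis. It implements
the two computational workflows such screens rely on:

1. **BSA mapping** — locate a recessive causal locus from pooled
   whole-genome variant calls of phenotypically selected F2 segregants, and
   rank candidate lesions by protein-level consequence.
2. **Sector analysis** — identify a *novel, noncomplementing* allele from
   paired sterile/fertile chimeric-sector sequencing of a mutagenized
   heterozygote, including read-backed cis/trans phasing of the new lesions
   against the pre-existing allele.

A fully deterministic synthetic-screen generator (reference genome, gene
models, F2 segregation, read sampling, planted confounders, chimeric
sectors) ships with the package so every stage can be exercised and
validated against known ground truth without any external data.

## The model in brief

* **Homozygosity enrichment.** In a pool of *n* F2 individuals selected
  homozygous for a recessive mutation, every chromosome carries the
  causal-parent allele at the causal locus. At a linked site at genetic
  distance *d* Morgans, each pooled chromosome carries that allele with
  probability 1 − *r*, where *r* = ½(1 − e^(−2d)) (Haldane). Homozygous
  nonreference variants (allele frequency ≥ 0.99 at ≥ 2 reads, recomputed
  from allelic depths) therefore cluster around the causal locus; binning
  them per Mbp and finding where the density returns to background yields
  the mapping interval, and intersecting two independent F2 families'
  variant sets refines it.
* **EMS spectrum.** EMS induces G:C→A:T transitions, so candidate SNPs are
  restricted to G>A / C>T changes; sibling-pool-shared variants and known
  error-prone sites are subtracted first.
* **Consequence ranking.** Candidate SNPs are mapped into spliced CDS
  coordinates (strand-aware), their codons retranslated with the standard
  genetic code, and classified SnpEff-style (`stop_gained`/HIGH,
  `missense_variant`/MODERATE, ...) with HGVS.p notation such as `p.Q150*`.
* **Phasing.** Two heterozygous variants are *cis* when reads covering both
  sites are (almost) all both-mutant or both-wild-type, and *trans* when
  they are alternate at exactly one site in both orientations. A novel
  allele that fails to complement must lie *trans* to the prior allele —
  i.e. on the formerly functional homolog.

## Worked example

Simulate a compact two-family screen and run the full BSA workflow:

```r
library(emsmapr)

cfg <- sim_config(seed = 42, n_chrom = 2, chrom_length = 3e5, genes_per_chrom = 4,
                  ems_rate = 2e-3, recomb_rate = 0.05,
                  n_mutant_individuals = c(40, 40), n_wildtype_individuals = c(40, 40),
                  mean_depth = 60, seq_error_rate = 0.001,
                  n_shared_background = 15, n_blacklist = 15)
simulate_screen(cfg, "demo/data")

res <- run_bsa(pipeline_config(list(
  genome       = "demo/data/genome.fasta",
  gff3         = "demo/data/genes.gff3",
  blacklist    = "demo/data/blacklist.bed",
  mutant_vcfs  = c("demo/data/mutant_pool1.vcf", "demo/data/mutant_pool2.vcf"),
  sibling_vcfs = c("demo/data/sibling_pool1.vcf", "demo/data/sibling_pool2.vcf"),
  bin_size     = 5e4, outdir = "demo/bsa")))
```

The run log prints every filter step's input/output counts:

```
pool 1: homozygous (depth >= 2, freq >= 0.99): 654 -> 283
pool 1: sibling-shared subtraction: 283 -> 254
pool 1: blacklist removal: 254 -> 254
pool 1: EMS-spectrum filter: 254 -> 254
pool 1: interval: Chr1:1-300000 (peak 53)
...
two-pool intersection: 213 shared variant(s); refined interval Chr1:1157-298459
```

(Here the blacklisted error-prone sites were already caught by the sibling
subtraction, so that step removes nothing further.) The ranked candidate
table puts the planted causal stop-gain first:

```r
res$candidates
#>    Chr Position Ref Alt     Variant_type   Impact  Effect       Gene_ID
#> 1 Chr1   180447   C   T      stop_gained     HIGH p.Q150* SYNG_Chr1_003
#> 2 Chr1    60354   G   A missense_variant MODERATE p.G119R SYNG_Chr1_001
```

`Position`/`Ref`/`Alt` are the genomic SNP, `Effect` the protein change
(`p.Q150*` = glutamine 150 replaced by a premature stop — a HIGH-impact
truncation), and `Gene_ID` the gene model hit. `run_sector()` continues the
workflow on sterile/fertile sector VCFs plus a read-observation table and
reports the nominated noncomplementing allele with its phase verdicts; see
`vignettes/emsmapr-methods.Rmd` for the full methodology.

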