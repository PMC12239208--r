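---
title: "Mapping and phasing EMS-induced mutations: models and methods"
author: "emsmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and phasing EMS-induced mutations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
genetic model behind bulked-segregant mapping of an EMS-induced recessive
mutation, the filters and their parameters, the codon-level consequence
classifier, the read-backed phasing rule used to recognise a novel
noncomplementing allele in a chimeric sector, and the design of the
synthetic-screen generator that the whole pipeline is validated against.

## 1. The genetic model

An EMS screen starts from a mutagenized parent carrying a recessive causal
lesion plus a load of background mutations, all on one parental haplotype.
Crossing to a second parent and selfing yields an F2 in which a pool of
individuals *selected for the recessive phenotype* is homozygous for the
causal-parent haplotype at the causal locus. For a site at genetic distance
$d$ Morgans from the causal locus, each pooled chromosome carries the
causal-parent allele with probability $1-r$ where

$$r = \tfrac12\left(1 - e^{-2d}\right)$$

is Haldane's map function (`haldane_r()`). Unlinked background mutations
segregate at expected frequency $\tfrac12$; in the fertile siblings the
causal allele itself sits at chromosome frequency $\tfrac13$ (one third of
fertile F2 plants are homozygous wild type, two thirds heterozygous). The
pooled sequencing allele frequency at a site is then a binomial read sample
around the chromosome frequency. These three facts — near-fixation under
selection, decay with $1-r$, and $\tfrac12$/$\tfrac13$ elsewhere — are what
make a sliding count of *homozygous* nonreference variants peak at the
causal locus.

## 2. The BSA filter chain

Each mutant/sibling pool pair passes through four deterministic filters,
applied in an order that the tests show is immaterial for the set
operations (they commute):

| step | rule | default |
|---|---|---|
| `call_homozygous()` | depth ≥ `min_depth` and alt frequency ≥ `freq_threshold` | 2 reads; 0.99 |
| `subtract_shared()` | drop sites homozygous (same thresholds) in the wild-type sibling pool | — |
| `apply_blacklist()` | drop known error-prone positions (BED/TSV input) | — |
| `filter_ems_spectrum()` | keep only G>A and C>T changes (the EMS signature) | — |

Allele frequency is always recomputed as `alt_depth / depth` from the VCF
`AD`/`DP` fields, never trusted from an INFO annotation, so the 0.99
threshold has exactly one definition. Only biallelic SNPs are considered;
indel and multi-allelic records are skipped on read with a counted warning.

**Binning and interval detection.** Filtered variants are counted per
`bin_size` (default 1 Mbp) bins tiling every chromosome
(`bin_variant_counts()`; the bin of position $p$ is
$\lfloor (p-1)/\text{bin\_size} \rfloor$). `detect_mapping_interval()` takes
the genome-wide maximum bin as the peak (ties broken by chromosome order
then lowest start, and logged), defines *background* as the median of all
bin counts, and extends the interval from the peak until
`consecutive_background` (default 2) successive bins fall to or below
background — an explicit operationalisation of "density returns to
background", which is otherwise a judgement call made on a plot. A peak
must exceed background by more than `min_peak_excess` (default 3) counts to
be reported at all, so flat noise never yields an interval.

**Two-pool intersection.** With two independent F2 families,
`intersect_pools()` keeps variants identical in (chrom, pos, ref, alt) —
exact allele identity, not position only, since EMS sites are biallelic —
and refines the interval to the span of the shared variants clipped by the
overlap of the two single-pool intervals. If one pool yields no detectable
interval the shared set is still returned, with a warning and no
refinement.

**Candidate ranking.** `classify_variants()` + `rank_candidates()` restrict
to protein-altering variants and order them HIGH-impact first, then by
position, mirroring the standard candidate-table layout (Chr, Position,
Ref, Alt, Variant type, Impact, Effect, Gene ID).

## 3. Codon-level consequence classification

`classify_variant()` maps a SNP into spliced CDS coordinates honouring
strand (minus-strand genes are reverse-complemented), extracts the codon
containing the site, translates reference and alternate codons with the
standard nuclear genetic code, and assigns:

* `stop_gained` / `stop_lost` → HIGH,
* `missense_variant` → MODERATE,
* `synonymous_variant` → LOW,
* `intron_or_utr` / `intergenic` → MODIFIER,

with the protein change in HGVS.p short form (`p.Q150*`, `p.D209N`).
Variants covered by several gene models are annotated against all of them
and the highest-impact annotation wins (ties to the lexicographically
smallest gene id — a determinism rule, not a biological claim). A variant
whose stated reference base disagrees with the genome is a data-integrity
error, reported with the site named. Splice-site, start-loss and indel
consequences are deliberately out of scope: the pipeline consumes an
SNP-only call set, and none of those classes can arise from it. The test
suite checks this classifier against an independent oracle that rebuilds
and translates the entire mutant CDS.

## 4. Sector analysis and phasing

A chimeric sector screen sequences a sterile and a fertile sector of one
inflorescence (~60×). The individual is a heterozygote for a prior mutant
allele; a sterile sector arises when a new lesion knocks out the remaining
functional copy — so the novel allele must be (a) heterozygous in the
sterile sector, (b) absent from the fertile sector, and (c) *trans* to the
prior allele.

* `call_heterozygous()`: depth ≥ `het_min_depth` (10), frequency inside
  `freq_window` ([0.25, 0.75] — a tolerant operationalisation of "~50%"
  that admits binomial sampling at 60× while excluding homozygous calls and
  low-level somatic noise), EMS spectrum only.
* `differential_sterile_unique()`: within the mapped interval, a sterile
  het call is *unique* when the fertile sector shows alt fraction ≤
  `err_max` (0.02) or no call at all — "not present" is defined against an
  error floor rather than mere call absence, to be robust to caller
  sensitivity differences. Genome-wide tallies are reported alongside.
* `confirm_prior_allele()`: the prior allele must be ~50% in *both*
  sectors, which proves the plant was a heterozygote before mutagenesis.
* `phase_variant_pair()`: only reads observing both sites count. With $n$
  informative reads the verdict is **cis** when both-alt + both-ref reads
  are ≥ $(1-f)\,n$, **trans** when alt-at-exactly-one reads are ≥
  $(1-f)\,n$ *in both orientations*, else **ambiguous**; $n <$
  `min_informative` (3) is always ambiguous. The discordance allowance
  $f =$ `max_discord_frac` (0.05) tolerates sequencing error while keeping
  the all-or-none read pattern that genuine linkage produces. A base that
  is neither ref nor alt at a site makes the read uninformative (it is
  evidence for neither haplotype).
* `nominate_allele()`: a gene is nominated when its sterile-unique coding
  variants are cis among themselves and at least one is trans to the prior
  allele with none cis to it. Genes with coding variants but no phasing
  support are listed, never auto-nominated.

## 5. The synthetic-screen generator

`sim_config()` / `simulate_bsa_screen()` / `simulate_sector_pair()`
generate complete screens with known truth. Design choices, each of which
matters for interpreting validation results:

* **Per-site segregation.** Chromosome counts at each site are drawn
  binomially at that site's marginal frequency ($1-r$ linked, $\tfrac12$
  unlinked, $\tfrac13$-based in siblings). Marginals are exactly the
  quantities the mapping statistic uses; joint haplotype structure across
  sites within a pool is not simulated (and nothing downstream consumes
  it).
* **Reads.** Depth is Poisson around `mean_depth`; each read reports the
  true allele except with probability `seq_error_rate` it substitutes one
  of the other three bases uniformly. Reads whose observed base is neither
  ref nor alt are excluded from the biallelic call, so the emitted `DP`
  equals ref- plus alt-supporting reads — the convention of
  allelic-depth-consistent callers.
* **Caller sensitivity.** A variant record is emitted only with ≥ 2
  alt-supporting reads at ≥ 5% fraction; singleton sequencing errors do not
  surface as calls, just as a real caller does not emit 1-of-60 artifacts.
* **Planted confounders.** Sibling-shared background sites are homozygous
  in both pools; error-prone (blacklist) sites carry a fully inflated
  nonreference fraction in *every* sample. Both use EMS-type changes so
  that only the intended filter (not the spectrum filter) can remove them.
* **The causal gene.** Genes are planted as two-exon models (480 + 120 bp
  CDS, 100-bp intron) on alternating strands; the causal gene's codons 98,
  111 and 150 are rewritten to CCA/CAA/CAG so that C>T transitions at their
  first bases produce p.P98S, p.Q111* and p.Q150* — the lesion geometry of
  the screen being emulated, with the novel pair 39 bp apart and the
  third site 117 bp from the second.
* **Sector reads.** Read observations are emitted as a fragment-level
  site×allele table with span `read_span` (350 bp, modelling a 2 × 150 bp
  paired-end fragment with a short inner gap): co-observation within a
  fragment is exactly the evidence IGV-style phasing uses. Alignment is out
  of scope; the pipeline consumes calls and observations, not reads.
* **Determinism.** All randomness flows from the config seed; identical
  config gives byte-identical outputs, which the tests verify on the
  written artifacts.

What the generator does **not** emulate: mapping artifacts and coverage
biases beyond the planted error-prone sites, indels and structural
variants, multi-generation pedigrees, second-parent background mutations
(available but off by default), or homozygous somatic sector events (an M1
sector derives from a single-cell heterozygous lesion). Passing validation
on simulated screens therefore demonstrates the *inference logic* is
correct under the stated model, not that any particular real dataset will
behave as cleanly.

## 6. Validation design and known limitations

The self-validation (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) runs the whole pipeline on simulated screens at
fixed study conditions — a 5 × 10-Mbp genome, two F2 families of 40
selected homozygotes plus 40 siblings at 12× and 1% error with
0.5 Morgans/Mbp and 200 background mutations (20 replicates), and 60×
sector pairs (50 replicates) — sizes chosen so the full suite completes in
minutes on one CPU while still exercising every stage at realistic
mutation densities.

Two behaviours of the method itself are worth knowing, and the evaluation
quantifies both:

* **Homozygosity calling at low depth is fragile.** At 12× a single
  errored read pushes a truly homozygous site below the 0.99 threshold
  (probability $\approx 1 - e^{-\lambda e/3}$ per site at depth
  $\lambda$), so tightly linked variant counts — and occasionally the
  causal site itself — drop out of a pool's homozygous set. With strong
  recombination (0.5 Morgans/Mbp) the homozygous peak can stay below the
  detection floor entirely; real screens sit at far lower map densities
  per Mbp, which is why megabase-scale peaks are observable in practice.
  Deeper pools, more individuals, or a lower `freq_threshold` all relax
  this.
* **Hom-vs-hom sibling subtraction leaks.** A background site homozygous
  in both pools escapes subtraction whenever read sampling leaves it
  *looking* non-homozygous in the sibling pool only. This is inherent to
  subtracting one thresholded call set from another and is exactly why the
  workflow also subtracts a curated error-prone blacklist and intersects
  two independent families, which removes the leakage quadratically.

Numerical conventions: integer genomic coordinates are 1-based inclusive
(VCF/GFF3 convention; BED converted on read); ambiguity codes other than N
are rejected on input; all tie-breaks (peak bins, overlapping genes) are
deterministic and logged.
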