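---
title: "Methods: haplotype-based prioritization of recessive candidate variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-based prioritization of recessive candidate variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppdscan)
```

## The problem

`ppdscan` addresses a mapping design that is common in livestock and
companion-animal genetics but poorly served by population-scale tooling: a
handful of affected individuals segregating a (putatively) recessive
congenital phenotype — here, preaxial polydactyly (PPD) in pigs — inside one
or two small pedigrees, with deep whole-genome resequencing of every
available animal. With 4 cases and 13 controls there is no power for a
conventional GWAS; instead, several weak lines of evidence are combined:

1. **Shared haplotype stretches** in the affected group (cross-population
   extended haplotype homozygosity, XP-EHH);
2. **Allele-frequency differentiation** between affected and normal groups
   (Weir–Cockerham F\_ST in sliding windows, separately for SNPs and
   INDELs);
3. **Allelic case-control association** (Pearson chi-square on the 2×2
   allele-count table, 1 df);
4. **Mendelian filtering**: under a recessive model every affected animal
   must be homozygous for the causal derived allele and no unaffected
   animal may be.

A candidate gene is credible only where these tracks *replicate*; a variant
is flagged putatively causal only if it is concordant under the inheritance
model **and** protein-changing. The package reproduces this logic as a
deterministic, auditable pipeline.

## Statistics

### Weir–Cockerham F\_ST

Per site the two-population diploid estimator decomposes allelic variance
into among-population (*a*), among-individual-within-population (*b*) and
within-individual (*c*) components from the group sample sizes, allele
frequencies and *observed* heterozygote proportions; `fst = a/(a+b+c)`,
undefined when the pooled sample is monomorphic. Negative estimates are
kept — clamping would bias window sums. Windows (default 10 kb span, 2 kb
step, anchored at position 1 for determinism; the source analysis states no
origin) report the **weighted** statistic `Σa / Σ(a+b+c)`, the ratio of
sums, alongside the unweighted mean of per-site ratios. Screening keeps
windows with weighted F\_ST strictly `> 0.6` and `>= 10` variants, exactly
the printed operators; passing windows are merged into regions. For INDELs
the same estimator treats each site as bi-allelic presence/absence; because
it is unclear whether the published INDEL follow-up threshold (F\_ST > 0.2)
was per-site or windowed, it is exposed as a per-site selection
(`indel_site_fst`).

### EHH, iHH and XP-EHH

EHH at marker *x* is the probability that two haplotypes drawn at random
from the panel are identical at every site from the core out to *x*,
`Σ_h C(n_h,2)/C(n,2)` over extended-haplotype classes. At the core EHH = 1:
the core's own allele does not partition the panel, so the statistic
measures shared extension rather than core homozygosity. iHH is the
trapezoidal integral of EHH against *physical* distance (no pig genetic map
is used), both flanks summed. The raw score is `ln(iHH_case/iHH_control)`
(positive = longer shared haplotypes in the affected group) and scores are
genome-standardised to mean 0, SD 1. Regions are called where the mean
normalised score in a window exceeds 2, on the same 10 kb/2 kb grid as
F\_ST (the source gives no separate grid; both are configurable).

Numerical choices, all config-exposed:

* **Truncation** at EHH < 0.05 (the de-facto standard), including that
  marker's trapezoid;
* **Maximal extension** of the walk, default 200 kb. In a cohort of close
  relatives EHH plateaus above the cutoff across chromosome-scale
  identical-by-descent segments, so an unbounded walk would integrate to
  the chromosome ends everywhere (and cost quadratic time). Bounding the
  walk is the established device of EHH scanners; 200 kb is proportionate
  to the 5 Mb simulated chromosome and well above the implanted 50 kb
  haplotype.
* Sites whose walk reaches a **chromosome edge** while still above the
  cutoff are flagged `edge_truncated` and excluded from the normalisation
  statistics (their iHH is a lower bound, not an estimate); capped walks
  are not edge-flagged.
* Sites with zero iHH in either group are skipped and logged.

### Association, DAF, concordance

The allelic test is the Pearson chi-square on the 2×2 allele-count table
with **no continuity correction** — required to reproduce the published
chi-squares from their own genotype counts — and no minimum-count gate
(the published tables are themselves sparse); a `sparse_table` flag is
attached when an expected cell is below 5, and the asymptotic caveat
applies. Missing genotypes are dropped per site. Derived allele frequency
uses reference-is-ancestral by default, matching the published 0 =
reference / 1 = altered coding; a custom ancestral-allele vector is
accepted. Recessive concordance requires every affected homozygous derived
and no unaffected homozygous derived; the dominant variant is provided with
an optional strict (no-carrier) form. Multi-allelic sites are retained in
I/O but projected to reference vs. most frequent alternate for statistics,
with other alternates masked per genotype.

### Filtering

The hard-filter engine evaluates each clause of the SNP expression
(`QUAL<=40, QD<=2, MQ<=40, FS>=60, MQRankSum<=-12.5, ReadPosRankSum<-8,
MQ0>=4 & MQ0/DP>0.1`) and the INDEL expression (`QD<2, FS>200,
ReadPosRankSum<-20`) independently, with the inclusive/exclusive boundaries
exactly as printed (they are deliberately inconsistent across clauses, and
overridable). A record missing an annotation skips that clause — the
behaviour of the variant-filtration tool whose syntax the expressions
follow — rather than failing it. The cluster rule flags every SNP lying in
any 10 bp window containing 3 or more SNPs.

### Evidence integration

Candidates are genes (plus merged evidence regions hitting no gene,
reported as intergenic candidates). Each candidate collects four boolean
flags — overlap with an XP-EHH region, a passing SNP F\_ST window, a
passing INDEL F\_ST window, and containment of a top-10 association SNP —
plus audit columns (best p, concordant-variant count, nonsynonymous
presence). Ranking is by flag count, then best p, then position: the
source analysis offers no composite score, only qualitative replication,
so the package formalises it as a deterministic count and says so in its
output headers. Gene assignment uses direct interval overlap with a
configurable flank (default 0 bp): the published argument against a
neighbouring gene 800 kb away was evidential, not distance-based.

## The synthetic cohort generator

The generator emulates the *post-calling* state of the study data — 17
phased samples, two families, 4 affected / 13 normal — not the sequencing
process. Its defaults are the study conditions and are not tuned per run:

* **Chromosome**: 5 Mb, with ~20,000 background variants split 16,000
  SNPs / 4,000 INDELs (the ~4:1 genome-wide ratio of deep pig
  resequencing, ~3.2 SNPs/kb).
* **Founder allele frequencies**: Beta(0.2, 0.2), a U-shaped,
  drift-dominated spectrum appropriate for a bottlenecked livestock breed;
  sites are ascertained to be polymorphic among the founder haplotypes
  (variant sites exist because they are polymorphic), and sites monomorphic
  among the 17 sampled animals are removed, as in any called VCF.
* **Pedigree**: family 1 has a sire mated to two dams — a carrier dam
  producing the affected litter (3 affected + 1 normal) and a non-carrier
  dam producing 11 normals — with only the sire sampled among the parents;
  family 2 contributes one affected offspring of two unsampled carriers.
  Meioses follow Haldane recombination (Poisson crossovers at 1e-8/bp, no
  interference), and each meiosis is conditioned at the causal site by
  flipping the gamete's starting strand, which leaves the crossover process
  untouched. The default conditioning reproduces the genotype configuration
  the study printed at the missense site: cases `1/1` ×4, controls `0/1`
  ×4 (including the obligate-carrier sire) and `0/0` ×9, hence a
  two-family derived allele frequency of 12/34 = 0.3529.
* **Causal haplotype**: a 50 kb block centred on the causal SNP, identical
  across all carrier haplotypes, carrying the causal missense variant and
  100 carrier-private **tag SNPs** (~2/kb, placed outside CDS). The tags
  are essential realism, not decoration: the published screening tables
  show many near-identical highly differentiated SNPs on the causal
  haplotype (≥10 SNPs with F\_ST > 0.6 per passing window), and without
  them a randomly drawn implanted haplotype produces block windows with
  weighted F\_ST ≈ 0.3 — no recessive founder haplotype without private
  variation would ever have been detected by the published screen.
* **Gene model**: three structurally identical genes (two decoys, one
  causal). The causal gene is minus-strand so that the genomic `A>G`
  causal SNP is a coding `T>C` at codon position 2, turning codon 85 `ATC`
  (Ile) into `ACC` (Thr) — the `I85T` pattern — in the third exon. CDS
  frames are validated (length divisible by 3, CDS within exons), and
  when a gene has several transcripts the longest CDS is used.
* **QC annotations** are drawn from a pass-like component, with a
  configured fraction per clause switched to a fail-like component that
  violates exactly that clause, so filter tests have known expected
  outcomes; the causal site always passes. Penetrance defaults to 1;
  missingness defaults to 0 because the emulated input is post-phasing
  (a phased VCF has no missing genotypes).
* All randomness flows from one master seed through deterministic
  per-stage substreams; the same configuration yields byte-identical
  emitted files.

What the generator does **not** emulate: coalescent LD structure in the
founder haplotypes (founder alleles are independent across sites given
their frequencies), sequencing reads and genotyping error, mutation,
sex-specific recombination maps, and genome-scale multiple testing
(a 5 Mb segment stands in for 2.5 Gb). Passing the recovery test therefore
shows that the pipeline's statistics and integration logic recover a
planted signal under the study's sampling design — not that the thresholds
would behave identically genome-wide on real data.

## Problem sizes and determinism

The test suite exercises the estimators against independent oracles
(pair enumeration for EHH, a general-r variance-component implementation
for F\_ST, the closed form for the allelic chi-square), uses small cohorts
(0.2–0.6 Mb, 1,000–3,000 variants) for pipeline properties, and runs the
full default-scale recovery (5 Mb, ~20,000 variants, 20 seeds) once; one
such run takes a few seconds for simulation and under ten for the pipeline
on one CPU. Every pipeline output is a pure function of its inputs;
re-running a seed reproduces every table byte for byte.

## Known limitations

* XP-EHH normalisation is genome-wide over one simulated chromosome; on
  real multi-chromosome data, normalisation in allele-frequency bins is
  common and would need to be added.
* The evidence-count ranking treats tracks as exchangeable; a window
  passing two F\_ST tracks counts the same as XP-EHH plus association.
* The concordance filter assumes full penetrance and no phenocopies; a
  relaxed version would need per-individual exception budgets.
* Relatedness inflates the allelic test genome-wide (the test assumes
  independent alleles); the package reports the statistic as published and
  leaves family-based corrections out of scope.
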