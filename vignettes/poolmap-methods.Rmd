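---
title: "Mapping recessive mutations from pooled exomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive mutations from pooled exomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolmap)
```

## The mapping problem

poolmap implements bulk segregant analysis (BSA) for a recessive mutation
segregating in an F2 intercross. Two parents, each heterozygous for the
causal allele, are crossed; one quarter of their offspring are homozygous
and affected. DNA from a pool of affected offspring and from the parental
pair is exome-sequenced, and every called variant locus is summarized by a
single statistic:

$$\delta = \lvert \mathrm{AF}_{\mathrm{pool}} - \mathrm{AF}_{\mathrm{parents}} \rvert$$

where each AF is the percentage of reads supporting the variant allele.
Away from the causal locus, parental alleles segregate randomly into the
affected pool and $\delta$ is centred at 0. Around the causal locus,
selection distorts segregation in a characteristic way.

## Expected signal under recessive selection

Condition on an offspring being affected: it received the mutant causal
haplotype from both parents. For a variant with recombination fraction
$r$ to the causal site, the allele transmitted by a parent comes from the
transmitted causal haplotype with probability $1-r$.
`expected_delta_recessive()` enumerates the four equally likely
transmissions, discards the un-affected ones, and returns the
infinite-depth expectation. Three configurations anchor the
interpretation of the genome scan ($r = 0$ means complete linkage):

```{r expectations}
expected_delta_scenarios()
```

* **50 pp** — variant on the mutant haplotype of *both* parents (the
  causal variant itself, or anything riding fully in cis in both):
  pool 100% vs parents 50%.
* **25 pp** — variant on the mutant haplotype of exactly one parent:
  every affected offspring carries it on one of two chromosomes, so
  pool 50% vs parents 25%. A variant on one *non*-mutant haplotype
  mirrors this (pool 0% vs parents 25%).
* **0 pp** — unlinked variant: no distortion survives the conditioning.

A linked region therefore shows a depleted 0-pp band and enriched
25–50-pp band in the position-by-difference density map, which is exactly
what `build_density_map()` tabulates and `call_linked_regions()` detects.
Note that a variant heterozygous in both parents with one cis and one
trans placement has expectation 0 even at full linkage; roughly half of
the het-in-both loci inside a linked region are informative, while all
het-in-one loci are.

## Locus filters

`filter_config()` carries the two filters applied before the statistic:

* `min_coverage` (default **20** informative reads, i.e. ref + alt from
  the AD field, in *each* sample). Coverage is counted from AD rather
  than the DP field so that the filter's universe matches the
  denominator of the percentage.
* `hom_alt_fraction` (default **0.95**): a locus is excluded when the
  alt fraction reaches this value in *both* samples. Such loci are
  strain background shared by mutants and parents alike and carry no
  mapping information. Read counts cannot observe genotypes directly,
  so "homozygous" must be operationalized; 0.95 tolerates ~1% sequencing
  error at depth 20 without misclassifying a true homozygote.

Failure states are ordered (pool coverage, parent coverage, shared
homozygosity) so each locus carries one reason.

## The genome scan

`build_density_map()` bins passing loci into position × delta cells
(defaults: **1 Mb** × **5 pp**). The bin sizes resolve a multi-megabase
linkage peak while keeping exome-scale counts per cell informative; a
delta of exactly 100 goes into the closed top bin.

`call_linked_regions()` replaces visual inspection of the heat maps with
a sliding window (default **5 Mb** window, **1 Mb** step). A window's
score is the fraction of its loci with $\delta \ge$
`informative_delta_pp` (default **20 pp** — just under the 25-pp
analytic minimum for linked loci, leaving headroom for binomial sampling
noise at depth ~20–30, where the sd of $\delta$ is roughly 9–13 pp).
Windows with score ≥ `min_score` (0.5) and ≥ `min_loci` (5) are kept,
overlapping windows are merged with scores recomputed over the merged
span, and regions are ranked by score, then locus count, then position.
The window grid is anchored at position 1 of each chromosome, so region
boundaries are grid-aligned; shifting all loci by a multiple of the step
shifts the calls identically, except within one window of the chromosome
ends. Because linkage decays over tens of centimorgans, called regions
are deliberately broad — the candidate interval to annotate, not a point
estimate.

## Consequence annotation

`read_gene_models()` loads a GFF3 subset (gene / mRNA / exon / CDS with
ID–Parent links; first transcript per gene, with a warning) plus spliced
CDS sequences from FASTA. `project_to_cds()` maps genomic positions
through the CDS intervals, strand-aware; `classify_variant()` then
translates reference and alternate codons with the standard genetic code
and assigns `nonsense`, `synonymous`, `missense_conservative`,
`missense_nonconservative`, `splice_site` (intronic within
`splice_window` = 2 bases of an exon boundary, the canonical
donor/acceptor positions) or `noncoding`.

"Conservative" is not a universal definition; poolmap uses the most
common operationalization — a strictly positive BLOSUM62 score for the
amino-acid pair — with the matrix taken from Biostrings and the
threshold exposed as `conservative_min_score`. `filter_candidates()`
keeps damaging variants (`nonsense`, `missense_nonconservative`,
`splice_site`) absent from every control-panel VCF by exact
chrom/pos/ref/alt match; panel genotype or frequency is ignored, since a
single observation in an unrelated individual already rules the variant
out as the private causal lesion. Only single-nucleotide substitutions
are classified.

## The intercross simulator

`simulate_cross()` provides ground-truth data with the segregation
structure the analysis assumes:

* **Karyotype** — default 25 chromosomes of 50 Mb at 2 cM/Mb,
  zebrafish-scale round numbers (~1.25 Gb, ~100 cM per chromosome).
* **Loci** — 20,000 candidate biallelic positions scattered uniformly,
  each independently heterozygous per parent with probability 0.3, the
  alt allele on a random haplotype. Loci carried by no parental
  chromosome are dropped (a variant caller never reports them). The
  causal variant sits mid-chromosome-6 on one haplotype of each parent.
* **Meiosis** — Haldane model: Poisson crossover counts with mean equal
  to the map length in Morgans, uniform positions, no interference. The
  closed form $r = (1 - e^{-2d})/2$ gives an independent oracle for
  testing.
* **Selection** — offspring are rejection-sampled until `n_affected`
  (default **20**, the pooled-embryo design) homozygous-mutant
  individuals are accepted; the causal chromosome is simulated first so
  rejected draws cost little. A cap (10,000 × `n_affected` draws) turns
  a mis-specified cross into an error rather than a hang.
* **Reads** — per-locus depths are Poisson (default mean **30**) and alt
  counts binomial with a symmetric per-read error (default **0.01**)
  flipping alleles in either direction.
* **Cis markers** — optionally, loci placed 1 bp from the causal site
  (distinct positions, ~2×10⁻⁸ Morgans, i.e. effectively complete
  linkage) on the mutant haplotype of both parents or of parent 1 only.
  These realize the 50-pp and 25-pp expectations exactly and are flagged
  in the truth table for parameter-recovery checks.

One `master_seed` drives named substreams (`parents`, `pool`, `reads`),
so a given configuration reproduces byte-identical VCFs while stages
stay independently perturbable.

What the simulator does **not** emulate: alignment and calling artifacts
(mapping bias, duplicated reads, indel realignment), exome capture
unevenness (depth is homogeneous Poisson rather than target-driven),
linked background selection, shared strain homozygosity (the
`shared_homozygous` filter is exercised with constructed fixtures
instead), indels, multi-allelic sites and sex chromosomes. Passing
recovery tests on simulated crosses therefore demonstrates correctness
of the statistics and the scan under the stated segregation model, not
robustness to real exome artifacts.

## Parental libraries

Whether the parents were sequenced as one pooled library or two
individual ones is a design detail the pipeline does not need to know:
`read_paired_vcf()` sums allelic depths across all samples in the
parents file (`merge_parent_samples()` is the standalone equivalent),
which makes the two dialects equivalent at the level of the statistic.

Loci called in only one of the two files are retained by an outer join
with zero counts on the missing side rather than dropped: a variant
homozygous-absent in one sample is informative, and a genuinely
uncovered one is removed by the coverage filter anyway.

## Numerical conventions

Percentages are carried in double precision and rounded (1 decimal)
only when written to the records TSV. Coordinates are 1-based inclusive
everywhere except BED output (0-based half-open). Degenerate inputs are
errors, not guesses: zero total depth in `delta_af()`, records outside
chromosome bounds in the density map, reference-mismatching variants in
the classifier.

## Problem sizes in the test suite

The checks bundled with the package run at sizes chosen to separate
signal from Monte-Carlo noise while staying quick: Haldane agreement on
20,000 gametes (3 standard errors), pool segregation on 200 replicate
crosses, full-scale recovery on one 25-chromosome / 20,000-locus cross
plus 25 smaller replicate crosses for the cis-marker median, and an
exhaustive base-by-base transcript walk for the CDS projection.
Tolerances on stochastic checks are fixed from the analytic standard
errors stated above, never from observed outcomes.

## Limitations

* The statistic is used without smoothing or significance testing; the
  scan is a formalized version of visual peak-finding, and its
  thresholds (`informative_delta_pp`, `min_score`, `min_loci`) are
  conventions, not estimates.
* Region boundaries are window-grid-aligned and deliberately coarse.
* Annotation handles one transcript per gene and SNVs only; frameshift
  and splice-regulatory effects beyond the ±2 window are out of scope.
* The simulator's read model is binomial at uniform Poisson depth;
  over-dispersion from capture or PCR is not modelled.
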