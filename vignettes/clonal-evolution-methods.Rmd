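---
title: "Methods: paired pre/post-treatment heterogeneity and clonal evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired pre/post-treatment heterogeneity and clonal evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonevo)
```

This vignette documents the statistical models, the tunable parameters, the
numerical choices, and the deliberate design decisions behind `clonevo`, and
states what the synthetic cohorts can and cannot show about real data.

## Study design and data model

The unit of analysis is a patient with two tumor samples — one before a
systemic therapy ("pre"), one after progression ("post") — and a matched
normal. Inputs per sample are annotated somatic variant calls with tumor and
normal allelic counts (MAF, or VCF with `AD` fields), copy-number segments
with integer copy number or log2 ratios (SEG), and a manifest row carrying
tumor purity and the patient's progression-free survival (PFS). Coordinates
are 1-based inclusive everywhere; chromosome names are compared after
stripping any `chr` prefix.

## Variant filtering

Four criteria are applied as a conjunction, with boundary semantics fixed as:
depth ≥ 20 in both tumor and normal (depth = ref + alt allelic counts),
germline alternate reads ≤ 5, tumor alternate reads ≥ 5, and population
allele frequency strictly < 1%. The population frequency of a variant is the
maximum over whichever annotation columns are present; an un-annotated
variant is treated as frequency 0, because a variant that no database
reports cannot exceed the cutoff. The kept set is order-free; the
per-criterion attrition report charges each removed variant to the first
failing criterion in the fixed order depth → germline → tumor → population
frequency, so reports are deterministic and sum to the input count.

## Heterogeneity indices

- **TMB** = nonsynonymous coding mutations / capture size. The nonsilent
  classes counted are missense, nonsense, frameshift, splice-site, nonstop
  and translation-start. The capture size defaults to 38 Mb, a typical
  whole-exome footprint, and is configurable — analyses should set it to
  their panel's actual size.
- **CNA burden** = percentage of segments deviating from neutral (integer
  copy number ≠ 2, or |log2 ratio| > 0.25). Counting *segments* rather than
  base pairs follows the "fraction of detected regions" convention; a
  length-weighted alternative is what wGII provides.
- **wGII**: per autosome, the fraction of covered length in segments whose
  copy number differs from the rounded ploidy; averaged unweighted across
  autosomes (sex chromosomes excluded), so large and small chromosomes
  contribute equally.
- **MATH** = 100 × 1.4826 × MAD(VAF) / median(VAF), the scaled median
  absolute deviation of the variant allele fractions as a percentage of
  their median. The 1.4826 constant makes the MAD consistent with a normal
  standard deviation.
- **ITH** = number of retained subclone clusters present in the sample,
  where presence means cellular prevalence ≥ 0.10 (the shared
  `presence_threshold`).
- **SDI** = Shannon entropy (natural log) of the mutation counts of the
  clusters present in the sample. A single present cluster gives exactly 0;
  K equal clusters give ln K, the maximum.

## Subclonal clustering

Mutations are clustered on their joint pre/post allele counts. The link from
cellular prevalence φ to expected VAF at a locus with tumor total copy
number $C_t$, multiplicity $m$, normal copy number $c_n = 2$ and purity $t$
is

$$\xi(\phi) = \frac{t\,\phi\,m}{(1-t)\,c_n + t\,C_t},$$

the total-copy-number parameterization. Multiplicity defaults to 1; the
package does not attempt allele-specific phasing, a known simplification
that biases φ downward for mutations on amplified alleles.

The mixture is a Dirichlet process whose base measure is uniform over a
discrete grid of G = 101 equally spaced prevalences per sample, so a cluster
parameter is a grid pair (φ_pre, φ_post). The discrete base measure makes
every Gibbs update an exact finite sum — no Metropolis steps, no tuning —
which buys determinism (given the seed) and testability at the cost of a
prevalence resolution of 1/(G−1) = 0.01. The sampler runs 1000
Chinese-restaurant-process sweeps (first 500 discarded), with concentration
α = 1; all of these are configurable through `cluster_config()`, and the
seed is a required argument, never defaulted. Per-mutation grid
log-likelihoods are precomputed once, so each sweep is O(n·K); the sweep
loop is compiled (Rcpp).

The hard assignment is not the last sweep's state: the retained sweeps'
co-assignment frequencies are average-linkage clustered and the dendrogram
is cut at distance 0.5, i.e. two mutations share a final cluster when they
co-occurred in at least half the retained sweeps. This consensus is far more
stable than any single state. Per-cluster prevalences are then posterior
means over the grid *conditional on the final membership* — exact under the
model given the assignment, and deterministic. (Averaging sampled φ over
sweeps is not well defined after consensus clustering, because transient
sweep clusters have no persistent identity.)

A mutation observed in only one sample contributes no likelihood in the
other (its depth there is zero); a mutation with zero depth everywhere is
rejected by name. Clusters with fewer than two mutations are dropped after
sampling, and their mutations are reported unassigned.

## Clone trees

With K retained clusters there are K^(K−2) labeled rooted trees (Cayley);
for the cohort sizes this method targets (K ≤ 7) they are enumerated
exhaustively via Prüfer sequences, in lexicographic parent-vector order, and
scored by the sum rule: for every sample and node, children's prevalences in
excess of the parent's add to the violation score. The minimizer is returned
(ties go to the lexicographically smallest parent vector), with the root
fixed at the cluster with maximal mean prevalence across samples (ties:
larger cluster, then lower id). The stricter single-sample crossing rule is
deliberately not enforced: after a treatment that eradicates a lineage,
child prevalences legitimately exceed extinct parents in the post sample,
and a hard constraint would forbid exactly the configurations of interest.
Above K = 7 the enumeration refuses to run rather than silently switch to a
heuristic; the pipeline then records the patient's tree as skipped and
continues, since the evolution-model classification needs only prevalences.

## Evolution-model classification

The *main clone* is the retained cluster with the highest pre-treatment
prevalence — prevalence, not mutation count, because persistence language
("the main clone was present after treatment") describes cell populations.
A patient is **homogeneous-origin** when the main clone's post-treatment
prevalence is at or above `presence_threshold` (default 0.10), otherwise
**heterogeneous-origin**. The threshold is a design choice exposed as a
parameter: the underlying notion of a clone being "found" post-treatment has
no published numeric rule, and 0.10 sits comfortably above the prevalence
noise floor at the depths this method targets while staying below any
plausibly "present" clone. Clusters at or above the threshold in *both*
samples are flagged resistant. PFS is summarized per label as lists and
medians only — with two and three patients per group a hypothesis test would
be noise, and none is run.

## Cohort statistics

The pre/post comparison of each metric uses an unpaired exact Wilcoxon
rank-sum test, matching how such comparisons are conventionally reported for
this design; a paired signed-rank variant is available behind
`compare_pre_post(paired = TRUE)`. The exact two-sided p-value enumerates
all $\binom{n+m}{n}$ assignments of the pooled values (midranks for ties)
whenever n + m ≤ 12, and falls back to the tie-corrected normal
approximation beyond that. Gene partitions (repaired / shared / new) are set
algebra on normalized HUGO symbols — upper-cased, trimmed, no alias
resolution. Median dichotomization labels a value "high" only when strictly
above the median, so the median element itself is "low".

## The synthetic cohort generator

The generator exists because cohorts of this design rarely deposit raw
reads; it emulates the statistical structure the analysis assumes, with full
ground truth. Per patient: a random rooted clone tree (default 4 clusters of
~10 mutations); pre-treatment prevalences drawn top-down under the sum rule
with a truncal root near 0.9; scenario **homogeneous** keeps the root
(≈0.8–0.95) and perturbs subclones, scenario **heterogeneous** sets all
pre-existing prevalences to zero except one expanding non-main lineage
(≈0.6–0.9); both scenarios add one or two post-only clusters (new
mutations). Depths are negative-binomial (mean 500, size 50 — realistic
exome overdispersion), alternate counts binomial at ξ(φ) with per-sample
purity near 0.8 and segment-derived copy number. Germline-heterozygous
contaminants (normal alt reads > 5) and common polymorphisms (population
frequency > 1%) are injected to exercise the filters.

Each sample's MAF contains the *union* of the patient's variants with that
sample's allelic counts (force-call convention): a clone absent from a
sample appears with zero alternate reads, is removed from that sample's kept
set by the tumor-support criterion (so TMB and gene partitions behave
correctly), and still supplies the joint clustering with informative
zero-VAF evidence. This mirrors multi-sample pipelines that re-genotype all
patient variants in every sample.

The worked-example cohort (`worked_example_cohort()`) fixes five patients with
its reference design: scenarios heterogeneous/heterogeneous/heterogeneous/
homogeneous/homogeneous, PFS 23, 11.6, 7.3, 2.4, 2.9 months, per-sample
subclone counts 4, 1, 2, 6, 2 (pre) and 4, 4, 7, 6, 2 (post), `MUC7` and
`MUC5B` mutations only before treatment in the heterogeneous patients, and a
new `ZNF91` mutation in the homogeneous patients. Its prevalence patterns
are hand-specified to realize those counts; it is generated at 2000x mean
depth, because several of its post-treatment clusters sit ~0.03 apart in VAF
and would merge at 500x. One fixture patient has eight clusters in the
pre/post union (two present before, seven after, with the main clone lost),
which exceeds the exhaustive-tree bound; their tree is recorded as skipped
while classification proceeds.

What passing tests on these cohorts do **not** show about real data:
no FFPE artifacts or strand bias, no mutational-signature structure, no
subclonal copy number or multiplicity > 1, no shared driver landscape across
patients, and clean purity values — on real cohorts, purity and copy-number
misspecification are the dominant error sources for prevalence estimates.

## Validation scale and determinism

The test suite validates parameter recovery at the study's own scale: four
well-separated clusters of 40 mutations at 500x recover with mean adjusted
Rand index > 0.99 over 20 seeded replicates and retained-cluster prevalence
errors below 0.05; scenario classification over a 50-patient synthetic
cohort at 500x is ≥ 95% accurate; tree enumeration is cross-checked against
brute force over all parent vectors for K ≤ 4 and against Cayley's formula
to K = 6; every heterogeneity index matches an independently coded
re-evaluation of its definition on random fixtures to 1e-9; the exact
Wilcoxon matches full permutation enumeration for all pooled sizes up to 10.
Given identical inputs, configuration and seed, every stage of the pipeline
is bit-reproducible.

## Known limitations

- Binomial (not beta-binomial) read counts: real data are overdispersed;
  prevalence uncertainties are therefore optimistic.
- Total-copy-number VAF model with default multiplicity 1.
- Exhaustive tree search stops at 7 clusters by design.
- The evolution-model rule depends on `presence_threshold`; calls for main
  clones hovering near 0.10 post-treatment are sensitive to it.
- Gene identity is a normalized symbol string; no alias resolution.
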