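---
title: "Profiling a bacterial gene family across gut metagenomes: methods and design"
author: "bshprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a bacterial gene family across gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bshprof)
```

## The problem

Bile salt hydrolase (BSH, EC 3.5.1.24) deconjugates glycine- and
taurine-conjugated bile salts in the gut and is encoded, often in several
paralogous copies, across a phylogenetically wide range of intestinal
bacteria. Profiling the family across strain proteomes and per-individual
metagenomes raises a chain of methodological questions that this package
answers as one pipeline:

1. **Curation** — which proteins in a strain-proteome collection belong to
   the family? (length window, pairwise identity, identity-threshold
   homology screen, and the within/between-genus identity densities that
   justify the threshold);
2. **Census** — how are copies distributed over strains, genera and phyla?
   (taxonomy parsed from strain names, the NP = number-of-paralogs
   distribution, encoding fractions);
3. **Abundance** — how abundant is each family member in each individual?
   (non-redundant catalog, read mapping, length-normalized relative
   abundance, per-individual detection at a stricter identity rule,
   cumulative RA per group and population);
4. **Phylotyping** — what are the family's functional units? (alignment
   distances, a neighbor-joining tree, an average-linkage cut into k
   phylotypes with an unclassifiable outlier group);
5. **Association** — how does family abundance relate to host covariates,
   country-level phenotypes, and disease status? (Mann-Whitney + FDR,
   Spearman, chi-squared presence tests, multivariable-adjusted linear
   models with per-factor variance explained).

A synthetic-data module generates all inputs with planted truth, so every
stage is testable without downloads.

## Statistical and algorithmic choices

### Pairwise identity and the screening contract

All identities are computed from affine-gap dynamic-programming alignments
(BLOSUM62 with gap open 11 / extend 1, or BLOSUM45 with open 15 / extend 2)
with the BLAST convention for percent identity: identical aligned pairs
divided by alignment length, gap columns included. Screening uses local
(Smith-Waterman) alignments by default, mirroring BLASTP semantics.

A BLAST e-value cutoff is a function of database size and is not
reproducible outside BLAST's statistics; the screen instead pairs the
identity cutoff with a raw alignment-score floor (default 100). On family
-length proteins this floor is far above the best random local HSP
(observed ≤ ~65 in score units on simulated decoys) and far below genuine
family alignments (≥ ~2000), so within its operating range it acts as the
e-value did: it removes short spurious HSPs and leaves the identity cutoff
as the operative filter.

The optional shared-k-mer prefilter is off by default. With k = 5 the
guarantee "never skip a pair that would pass 40% identity" does not hold:
at 40% scattered identity the probability of no shared 5-mer is
non-negligible. The prefilter is safe (and useful) for high-identity
screens such as the 62% detection rule; this tension between the two
stated requirements was resolved in favor of correctness.

### Catalog clustering

The non-redundant catalog clusters greedily in decreasing length order:
each protein joins the first representative it matches at ≥ 95% identity
over ≥ 90% of the shorter sequence, else founds a cluster. Identity here is
measured on an *overlap* (free end-gap) alignment: a local alignment can
trim a 94%-identical pair down to a ≥ 95% conserved core and wrongly merge
it, while an overlap alignment of near-full-length homologs cannot discard
both sequences' ends.

### Relative abundance

For gene g and individual i with mapped count c(g,i) and protein length
L(g):

RA(g,i) = (c(g,i) / L(g)) / Σ_g' (c(g',i) / L(g'))

Rows sum to 1 and RA is invariant to per-sample count scaling. "Length" is
amino-acid length: nucleotide length would multiply every density by 3 and
cancel in the normalization. Samples with zero (or sub-floor) total counts
are excluded and listed, never silently zero-filled. Per-population
cumulative RA is the **mean** over samples of within-sample group sums: a
plain sum would scale with cohort size and the per-population scalars are
compared across unequal cohorts; `agg = "sum"` remains selectable.

### Phylotyping

Trees are built by neighbor-joining on global-alignment distances
(p-distance or Poisson-corrected −ln(1−p), with p = 1 capped at a
documented maximum). NJ replaces the original maximum-likelihood tree
because phylotype membership depends on clustering structure, not on ML
branch-length estimates; NJ is exact on additive matrices, which the test
suite verifies against the path-length oracle. The phylotype cut is
average-linkage hierarchical clustering at k clusters (k = 8 by default),
with two outlier rules reproducing the "unclassifiable small group"
phenomenon: clusters below `min_cluster_size` and sequences whose mean
within-cluster distance exceeds the `outlier_quantile` (default 0.95) of
all pairwise distances are routed to the outlier label T0. Regular labels
are T1..Tk′ by decreasing size with ties broken by smallest member id, and
ids are sorted before clustering so labels are permutation-stable. Mapping
these size-ordered labels onto any published labeling is a user-supplied
alias table, since published orderings follow tree layout.

### Association statistics

*Mann-Whitney*: exact two-sided p by full enumeration of group assignments
whenever `choose(n, n1)` ≤ 20 000 (this covers both groups ≤ 8 and handles
ties exactly); otherwise the normal approximation with tie and continuity
corrections. *FDR*: Benjamini-Hochberg step-up, implemented directly.
*Spearman*: mid-ranked ties, exact null when n ≤ 9 without ties, otherwise
the t-approximation. *Chi-squared*: Pearson without continuity correction
by default; zero marginals are an error because expected counts are
undefined. *Multivariable adjustment*: OLS of per-individual family
cumulative RA on gender, age, BMI and population; each factor's p is the
partial F test against the model holding the remaining three, and variance
explained is the partial R², (SSE_reduced − SSE_full)/SSE_reduced × 100,
clamped to [0, 100] only against floating-point dust in degenerate
zero-noise fits. Complete-case analysis per model with the used n reported.
In case-control contrasts, phylotypes absent in more than half of all
individuals are zero-inflated and tested by presence/absence chi-squared;
the rest form one Mann-Whitney family under BH.

Healthy-individual screening uses strict bounds (18.5 < BMI < 29.9,
12 < age < 75); records missing a covariate pass that criterion, matching
how cohorts without metadata are retained in population-level panels.

## The synthetic world

The original analysis used real data and specifies no generative model;
every distributional choice below is a stand-in, stated once.

* **Sequences.** One family ancestor (length uniform in 300–400 aa), two
  subfamily ancestors, one ancestor per genus, leaves per strain — all by
  substitution-only evolution with mutation fractions calibrated so
  within-genus pairs land at ≈ 82% identity and between-genus pairs near
  the 35%/50% modes (the (1−d)² composition of independent substitution
  fractions). No indels are simulated, so global alignments of family
  members are gapless and identity targets are controllable; real families
  contain indels, hence a green identity test does not establish gap
  handling beyond what the alignment unit tests cover.
* **Paralogs.** Counts per strain follow the NP distribution
  {1: 72.48%, 2: 23.49%, 3: 3.36%, 4: 0.67%} by largest-remainder quota,
  which reproduces the 324/105/15/3 split exactly at 447 strains. Each
  paralog is an independent draw from the genus ancestor (duplication at
  the ancestor): deriving paralogs from their sibling with extra divergence
  would place sibling pairs ≈ 94% identity, off the within-genus target
  band that the generator is contracted to hit.
* **Reads.** Error-free (optionally fixed-rate-error) substrings of
  deterministic back-translations. Expected reads per gene are
  proportional to abundance × gene length — the sampling process the RA
  formula's length division undoes. Each gene uses its own synonymous-codon
  variant so that identical amino-acid windows in near-identical paralogs
  do not produce ambiguous reads; real metagenomes do have ambiguous reads,
  so exact-count recovery is a property of this stated world, not of real
  mappers.
* **Covariates and effects.** Gender/age/BMI are independent of abundance
  unless an effect is planted. The planted population effect is exact by
  construction: population means are standardized to between-population
  variance r²/(1−r²) and the noise is residualized against the population
  factor, so the planted partial R² is the realized one (up to the few
  degrees of freedom the other covariates absorb). Phenotype tables draw
  indicators from plausible national ranges; a monotone link to population
  abundance can be planted at Spearman ±1 (deterministic transform) or an
  intermediate target (rank blending).
* **Randomness.** A single master seed; every stage derives its own stream
  as `(seed * 97 + stage_index * 1009) mod (2^31 − 1)`.

## Numerical conventions

Inclusive length bounds; strict covariate bounds; best-hit ties broken by
(identity, alignment length, lexicographic query id); read-mapping ties by
lexicographic gene id; phylotype-assignment ties toward the smaller
phylotype index, flagged; suggested identity threshold by 1-point grid
search minimizing within/between misassignment, ties to the median
minimizer; Poisson distance cap 10 with a warning; RA row-sum tolerance
1e-9.

## Known limitations

* No indel evolution, codon-usage model, sequencing-error realism or
  assembly simulation (out of scope by design).
* The score floor replaces, but does not reproduce, BLAST e-values.
* NJ + average linkage is a clustering surrogate for an ML tree; only
  clustering structure, not branch support, is contracted.
* The published real-data headline numbers that depend on external
  database snapshots (counts of database records, per-population RA
  values, WHO-indicator correlations) are not recomputable offline; the
  package covers their arithmetic and the recovery of planted analogues.
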