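# bshprof

Census and abundance profiling of the bile salt hydrolase (BSH, EC
3.5.1.24) gene family — or any protein family with the same shape of
evidence — across bacterial strain proteomes and per-individual gut
metagenomes.

BSH deconjugates glycine-/taurine-conjugated bile salts and is encoded by
many gut bacteria, frequently in paralogous copies. Asking "how much BSH
does this cohort carry, from which lineages, and does it track host
phenotype?" requires a chain of steps that this package implements end to
end, for microbiome researchers who have strain proteomes (FASTA),
metagenome read sets, and sample metadata:

1. **Reference curation** — length filter (300–400 aa), pairwise protein
   identity under BLOSUM45/62 with BLAST's gap-inclusive identity
   denominator, homology screening at an identity cutoff (45% for family
   curation), and within/between-genus identity densities with a suggested
   separating threshold.
2. **Taxonomy & paralog census** — taxonomy parsed from strain names, the
   NP (number of paralogs per strain) distribution, encoding fractions,
   genus/phylum rollups.
3. **Abundance** — non-redundant catalog (95% identity / 90% overlap),
   read mapping, and the length-normalized relative abundance

   RA(g, i) = (c(g,i)/L(g)) / Σ_g′ (c(g′,i)/L(g′))

   plus per-individual family detection at the stricter 62% rule and
   cumulative RA by genus/phylotype and population.
4. **Phylotyping** — alignment distances (p or Poisson-corrected),
   neighbor-joining tree, average-linkage cut into k phylotypes with an
   unclassifiable outlier group (T0), nearest-reference assignment of new
   sequences.
5. **Association** — Mann-Whitney U with Benjamini-Hochberg FDR, Spearman
   correlation against country-level phenotype tables, chi-squared
   presence tests for zero-inflated phylotypes, and multivariable-adjusted
   linear models reporting each factor's partial-F p and partial R²
   ("variance explained").

A first-class synthetic-data module (`sim_config()`,
`generate_reference_set()`, `generate_metagenomes()`,
`generate_phenotype_table()`) generates all of these inputs with planted
truth — genus-structured families at ~82% within-genus and ~35%/50%
between-genus identity, the observed NP distribution, planted gene
abundances and a plantable population effect — so the full pipeline runs
and is tested entirely offline.

## Worked example

```r
library(bshprof)

## the published NP strain counts, through the census
paralog_census(c("1" = 324, "2" = 105, "3" = 15, "4" = 3))
#> Paralog census: 591 sequences in 447 strains
#>   NP=1: 324 strains (72.48%)
#>   NP=2: 105 strains (23.49%)
#>   NP=3: 15 strains (3.36%)
#>   NP=4: 3 strains (0.67%)
#>   multi-copy strains: 27.52%

## a synthetic reference: 8 genera x 5 strains, screen + phylotype
cfg <- sim_config(seed = 1, n_genera = 8, strains_per_genus = 5)
ref <- generate_reference_set(cfg)
hits <- homology_screen(ref$ancestors, filter_by_length(ref$records),
                        min_identity = 45, matrix_name = "BLOSUM45")
nrow(hits)        # 52 -- every planted family member, no decoys
fam <- ref$records[ref$records$id %in% hits$subject_id, ]
asg <- cut_phylotypes(distance_matrix(fam), k = 8)
asg
#> Phylotype assignment: 52 sequences, 8 regular phylotypes
#> T1 T2 T3 T4 T5 T6 T7 T8
#>  8  8  7  6  6  6  6  5
adjusted_rand_index(asg$labels[fam$id],
                    ref$truth$clade[match(fam$id, ref$truth$id)])
#> [1] 1
```

The census print is the published Fig-2d arithmetic recomputed; the
phylotype cut recovers the eight planted clades exactly (adjusted Rand
index 1).

An end-to-end run (simulate → curate → census → profile → phylotype →
associate) with a checksummed manifest:

```r
man <- run_pipeline(pipeline_config(seed = 1), "out/")
```

or from the shell: `exec/bshprof run --out out/ --seed 1`.

## Documentation

The methods vignette (`vignettes/bsh-profiling.Rmd`) describes the model
and its assumptions, every tunable threshold with its default and
rationale, what the synthetic world does and does not emulate, numerical
conventions and tie rules, and known limitations.
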