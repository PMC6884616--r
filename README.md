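# orthodelta

Comparative-genomics toolkit for linking lineage-specific **gene
duplication** to **transcriptome divergence** across species — the
analysis pattern used when contrasting a focal lineage (e.g. Antarctic
hemoglobinless icefish) against related and outgroup species whose
genomes and RNA-seq are only comparable through ortholog groups (OGs).

The package covers five connected analyses, all operating on OGs:

1. **Copy-number divergence.** After filtering fragmented gene models by
   protein alignment coverage (≥ 60% of the reference ortholog), each OG
   is summarised by the mean copy difference between a focal group *A*
   and a comparator group *B*:

   *M*Δ = mean copies in *A* − mean copies in *B*

   OGs with *M*Δ ≥ 1 are classified *duplicated*, *M*Δ ≤ 0 *background*.

2. **Cross-species differential expression.** Per-species gene counts
   are converted to cpm, summed over OG members, filtered (cpm < 1 in
   more than half of every species' samples), TMM-normalised, and tested
   per OG with a negative-binomial GLM likelihood-ratio test (common +
   tagwise Cox–Reid dispersions); significance at |log2FC| ≥ 1 and
   BH FDR ≤ 0.05.

3. **Preranked gene-set enrichment.** OGs ranked by
   sign(logFC)·(1 − p); classic (unweighted) enrichment statistic;
   NES by "meandiv" normalisation against a label-permutation null
   (1000 permutations); pooled-null FDR q-values.

4. **Tissue specificity.** The τ index, τ = Σ(1 − x\_i)/(N − 1) on
   max-normalised TMM log2 cpm over a multi-tissue panel, compared
   between duplicated, not-duplicated, and strict 1-to-1 gene categories
   with Wilcoxon rank-sum tests.

5. **Promoter motif divergence.** 5-kb upstream regions scanned with a
   JASPAR-style PWM at exact dynamic-programming p-value thresholds;
   per-gene binding-site count difference Δ between the focal species
   and the median of comparison species; Fisher exact association of
   Δ ≥ k with upregulation.

A seeded synthetic-data generator (`simulate_study()`) produces
orthology tables, count matrices, tissue panels, promoters, and gene
sets with planted duplications, dosage effects, DE, tissue-specific
genes and motif insertions — plus a ground-truth manifest — so every
stage is testable by parameter recovery.

## Worked example

```r
library(orthodelta)

cfg   <- sim_config(seed = 1)          # 2000 OGs, 5/4/5-replicate design
study <- simulate_study(cfg)

## 1. copy-number divergence
copies <- copy_number_matrix(study$orthology)
md  <- mean_delta(copies, cfg$focal_species, cfg$comparator_species)
dup <- classify_duplication(md)
table(dup$class)
#> background duplicated
#>       1700        300

## 2. OG-level differential expression, focal vs pooled outgroup
de <- og_de_pipeline(study$counts, study$metadata, study$orthology,
                     group_a = "focal", group_b = "outgroup")
table(de$de$class)
#> down   ns   up
#>   83 1665  252

## 3. duplication x upregulation association
assoc <- duplication_expression_association(dup, de$de)
assoc$table                            # Fisher p = 7.8e-101, OR = 26.4
#>             up not_up
#> duplicated 172    128
#> background  82   1618

## 4. gene-set enrichment of the planted mitochondrial-like set
gsea <- permutation_nes(rank_scores(de$de), study$sets,
                        n_perm = 1000, seed = 1)
gsea[, c("set", "size", "nes", "p_value", "fdr_q")]
#>         set size      nes  p_value  fdr_q
#> 1 mito_like  313  3.76248 0.001000 0.0010
#> 2   control  300 -1.23943 0.177551 0.1966

## 5. tissue specificity by duplication category
tt   <- tau_table(study$panel$counts, study$panel$tissues)
cats <- categorize_genes(study$orthology, dup, cfg$focal_species[1])
tau_by_category(tt, cats)$medians
#> duplicated not_duplicated one_to_one
#>       0.32           0.10       0.08

## 6. promoter binding-site divergence vs upregulation
pwm    <- pfm_to_pwm(study$pfm)
dist   <- score_distribution(pwm)
counts <- tfbs_count_table(study$promoters, pwm, dist, p_threshold = 1e-4)
delta  <- tfbs_delta(counts, cfg$focal_species[1], cfg$outgroup_species)
tfbs_expression_association(delta, de$de, k = 1)$table  # Fisher p = 2.1e-61
#>             up not_de
#> extra_sites 72     95
#> no_extra     5    998
```

Reading the output: the planted duplications are recovered exactly from
the copy table; the duplicated class is strongly over-represented among
upregulated OGs (the dosage effect); the duplication-enriched gene set
scores NES 3.8 with the control set null; duplicated-OG genes show the
highest median τ; and genes with extra planted binding sites in the
focal promoters are overwhelmingly the upregulated ones. The
`study$truth` manifest holds every planted quantity for comparison.

The methods vignette (`vignettes/orthodelta-methods.Rmd`) documents the
models, parameter defaults, generator design, and numerical choices.

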