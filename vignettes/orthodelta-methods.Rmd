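---
title: "Linking gene duplication to transcriptome divergence with orthodelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking gene duplication to transcriptome divergence with orthodelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orthodelta implements a comparative framework for asking whether
lineage-specific gene duplication drives transcriptome divergence — the
kind of question posed by Antarctic icefish genomics, where a focal
white-blooded lineage is contrasted against red-blooded relatives and
temperate outgroup fish. The unit of comparison throughout is the
ortholog group (OG): a cluster of genes across species descended from one
ancestral gene, as produced by standard orthology inference. This
vignette explains each stage's model and assumptions, the tunable
parameters, the synthetic-data generator that stands in for real genomes
in the test suite, and the package's numerical choices.

## Copy-number divergence

Fragmented genome assemblies inflate apparent gene counts because partial
gene models are counted as separate copies. `apply_coverage_filter()`
therefore removes genes whose protein alignment covers less than 60%
(`min_cov`, inclusive boundary) of the reference-species ortholog before
any copy counting; genes without a coverage record are treated as
unalignable and removed with a warning.

Copy-number divergence between a focal species group $A$ and a comparator
group $B$ is summarised per OG by the mean copy difference

$$M\Delta = \frac{1}{|A|}\sum_{s \in A} c_s \;-\; \frac{1}{|B|}\sum_{s \in B} c_s,$$

where $c_s$ is the gene count of species $s$ in the OG
(`mean_delta()`). Species of a group entirely absent from an OG
contribute zero copies — the mean is always over all group members, which
keeps the statistic antisymmetric under group swap.
`classify_duplication()` calls an OG *duplicated* when
$M\Delta \ge 1$ (at least one extra average copy in the focal group) and
*background* when $M\Delta \le 0$; the band in between is reported as
*intermediate* and excluded from two-class association tests. A
"anything above zero is duplicated" rule, which some analyses prefer, is
available by setting `dup_threshold` just above zero.

## Cross-species expression over OGs

Gene-level RNA-seq counts cannot be compared directly across species
(different gene models, different lengths), so `og_de_pipeline()`
aggregates each species' counts-per-million over OG members:
per species, cpm are computed on that species' own library sizes, OG
expression is the *sum* of member-gene cpm, and the per-sample OG
matrices are assembled into one cross-species matrix. OGs with cpm < 1
in more than half of every species' samples are removed
(`filter_low_expression()`); an OG adequately expressed in a single
species is kept, because species-restricted expression is part of the
biology under study (a stricter any-species rule is available via
`mode = "any"`).

The filtered summed-cpm matrix is rounded to integers and treated as
counts on a nominal library of $10^6$. This is deliberately documented
rather than hidden: feeding summed cpm to a count model is an
unconventional but practical choice when cross-species library sizes are
not commensurable, and rounding isolates it in one place. TMM
normalization factors (`tmm_factors()`, the standard doubly-trimmed
precision-weighted mean of log ratios against an automatically chosen
reference, rescaled to geometric mean one) enter the model as offsets
$\log(10^6 f_j)$.

Dispersion is estimated by maximising the Cox–Reid adjusted profile
likelihood (APL) of the two-group negative-binomial GLM: the *common*
dispersion maximises the APL summed over OGs (golden-section search on
the log-dispersion scale, tolerance $10^{-4}$); *tagwise* dispersions
maximise each OG's APL plus `prior_df` (default 10) residual degrees of
freedom worth of the shared APL, evaluated on a 25-point grid spanning
$2^{\pm 6}$ around the common value with quadratic refinement. As
`prior_df` grows the tagwise values collapse onto the common one. No
abundance trend is fitted — common plus tagwise is the model.

`fit_nb_glm_lrt()` compares, per OG, the NB GLM with a two-level group
factor against the intercept-only null via the likelihood-ratio
statistic ($\chi^2_1$). Group means are fitted by Fisher scoring (at most
50 iterations, step tolerance $10^{-8}$); non-convergent OGs are flagged
and their p-value set missing. The log2 fold change contrasts
offset-adjusted fitted group means; when one group has zero counts, both
group rates receive 0.125 pseudo-counts per observation (scaled by the
relative offsets), which bounds the fold change instead of returning
$\pm\infty$ — empirically this yields values around $-15$ for an OG
expressed at a few hundred cpm in one group and silent in the other.
`call_de()` applies Benjamini–Hochberg and the inclusive significance
rule $|\log_2 FC| \ge 1$ and FDR $\le 0.05$.

The intended study design runs this twice: focal group versus the pooled
outgroup (5 vs 15 samples) and focal versus the comparator group (5 vs
4). The pooled comparison treats the outgroup as one plain two-group
contrast without a species blocking factor; pooling distinct species
inflates within-group variance and is therefore conservative.

## Preranked gene-set enrichment

`rank_scores()` converts a DE table to the signed confidence score
$\mathrm{sign}(\log FC)\,(1 - p)$ (zero fold change scores 0), with ties
broken by OG identifier so permutation analyses are reproducible.
`enrichment_score()` implements the classic (unweighted) statistic: walk
the ranked list adding $1/N_h$ at members and $-1/(N - N_h)$ at
non-members; the enrichment score is the maximum-magnitude deviation of
the running sum (exact magnitude ties resolve to the positive extreme).
`permutation_nes()` builds the null by placing each set's labels
uniformly at random in the list, normalises by the mean magnitude of
same-sign null scores ("meandiv"), takes nominal p-values from the
same-sign tail (floored at $1/n_{perm}$ — never zero), and computes FDR
q-values against the pooled normalised null with the usual
monotonisation from the most extreme score inward. These are the only
knobs the recipe fixes; everything else follows the canonical preranked
procedure. Note that under this null roughly 10% of random sets exceed
$|NES| = 1.5$; the meandiv construction guarantees a mean of 1, not a
particular tail mass.

Two Fisher-exact associations connect duplication to function and
expression: `duplication_set_enrichment()` (duplicated vs background ×
in-set vs out) and `duplication_expression_association()` (duplicated vs
background × upregulated at $\log FC \ge 1$ vs not). Both default to the
one-sided "greater" alternative because the hypotheses are directional;
the sidedness is recorded in every result and two-sided tests are one
argument away. Published analyses of this kind rarely state sidedness;
the default here is a declared choice of this package.

## Tissue specificity

Expression breadth uses the $\tau$ index over $N \ge 2$ tissues:
components are divided by the maximal component and
$\tau = \sum_i (1 - x_i)/(N - 1)$, so single-tissue expression gives 1
and uniform expression 0. `tau_table()` computes per-gene $\tau$ on
TMM-normalised log2 cpm with negative values clipped to zero (a
`log2(cpm + 1)` offset is available instead); replicates are averaged per
tissue before $\tau$. All-zero profiles are undefined and reported, not
silently scored. Note that on the log scale a planted boost of $\Delta$
in one tissue over a baseline of $x_0$ log2 cpm yields
$\tau \approx \Delta/(x_0 + \Delta)$: even strongly tissue-specific genes
of well-expressed families do not reach $\tau = 1$.

`categorize_genes()` attaches each focal-species gene to exactly one of
three categories via its OG: *duplicated* ($M\Delta \ge 1$), strict
*one-to-one* (single copy in every species), and *not duplicated*
($M\Delta \le 0$, excluding one-to-one). Intermediate OGs fall in no
category and are reported. $\tau$ is computed per gene (matching how
such results are usually reported as gene counts); an OG-level variant
is a matter of summing profiles before `tau()` and is not the default.
`tau_by_category()` compares the category distributions with pairwise
two-sided Wilcoxon rank-sum tests (exact for small untied samples).

## Promoter motif divergence

`extract_promoters()` takes the `length` bases (default 5000) upstream
of the annotated transcription start — for forward-strand genes the
window ending just before the gene start, for reverse-strand genes the
reverse complement of the window following the gene end — truncating at
contig edges with a flag. Windows overlapping neighbouring genes are not
masked; with 5-kb windows in compact fish genomes some overlap is
unavoidable and the counts should be read accordingly.

JASPAR PFMs (`read_jaspar()`) are converted to log2-odds PWMs with a
per-column pseudocount of 0.1 distributed by the background
(`pfm_to_pwm()`). `score_distribution()` rounds scores to an integer
grid (scale 1000 by default) and convolves the per-column distributions
under the background model, giving the exact probability of every
attainable window score — the standard dynamic-programming route to
exact p-value thresholds. `scan_promoter()` reports every window on
either strand whose exact p-value is at most `p_threshold` (default
$10^{-4}$, the scanning convention); windows containing N are skipped
and overlapping hits all count (a greedy collapse would be a different
statistic; none is applied). The background defaults to uniform; pass
the promoter set's own composition where that matters.

Cross-species divergence in binding-site counts uses strict 1-to-1
orthologs only: `tfbs_delta()` computes per gene
$\Delta = \text{focal count} - \mathrm{median}(\text{comparison counts})$
(a plain difference for a single comparison species), and
`tfbs_expression_association()` tests whether genes with $\Delta \ge k$
(run $k = 1$ and $k = 2$) are more often upregulated
($\log FC > 0$, $p \le 0.05$) than *not differentially expressed* —
significantly downregulated genes are excluded from the table entirely,
since they belong to neither column of that contrast.

## The synthetic study generator

Real analyses of this kind start from assembled genomes and SRA runs;
the package's tests instead use `simulate_study()`, which generates data
with the same statistical structure and a ground-truth manifest for
parameter-recovery checks. The default `sim_config()` mirrors the
motivating study design: two focal (icefish-like) species, two
comparator (red-blooded-like) species, three outgroup species; five
expression replicates for the focal representative, four comparator
samples pooled across its two species, five replicates per outgroup
species; 2000 OGs; a five-tissue panel; 5-kb promoters.

Planted signal, all recorded in the manifest:

* **Duplications** — 15% of OGs (`dup_fraction`) gain 1–3 extra copies in
  every focal species. A further 20% of the remaining OGs
  (`bg_multi_fraction`) carry a shared copy number above one in all
  species, so the background class is not exclusively one-to-one — real
  orthology tables always contain ancestral duplicates, and without them
  the three gene categories of the breadth analysis would collapse to
  two.
* **Dosage** — duplicated OGs express `dosage_logfc` (default 1.0) log2
  units per extra copy, applied to the OG total and divided evenly over
  the copies. The dosage magnitude is a free parameter of the generator,
  not an estimate from any dataset: total-expression scaling is the
  hypothesis the association tests are designed to detect, and 1.0 per
  copy is the natural "proportional dosage" point.
* **Differential expression** — 10% of non-duplicated OGs get a signed
  log2 effect drawn from $[1, 3]$ in the focal lineage.
* **Counts** — negative binomial with dispersion 0.1 (a typical
  bulk-RNA-seq replicate dispersion) around lognormal baselines
  (meanlog 4, sdlog 1.5 on the count scale) scaled by per-sample library
  sizes drawn from $[8 \times 10^5, 1.2 \times 10^6]$.
* **Tissue specificity** — 20% of focal genes are boosted
  $2^{\Delta}$ (default $\Delta = 4$) in one tissue, with planting biased
  toward duplicated-OG genes at odds ratio `tissue_dup_or` (default 6) so
  breadth divergence tracks copy-number divergence, which is the
  coupling the category comparison is meant to detect. Two replicates
  per tissue are generated.
* **Promoters** — i.i.d. uniform background bases for every strict
  1-to-1 OG in the focal, first-comparator and outgroup species; one
  motif occurrence planted per promoter (sampled column-wise from the
  PFM at non-overlapping positions) plus `planted_extra_sites`
  (default 2) additional occurrences in focal promoters of upregulated
  OGs. The bundled 11-column PFM (`default_pfm()`, consensus
  `ACCGGAAGTGG`) is a synthetic information-rich ETS-like profile
  constructed for the package, sharp enough that a sampled occurrence
  with at most one off-consensus base still clears a $10^{-5}$ exact-p
  threshold.
* **Gene sets** — one "mito-like" set in which duplicated OGs are
  over-represented at odds ratio 3, plus a random control set.

Each artifact draws from its own RNG stream derived from the master
seed, so generating an extra artifact never perturbs the others, and
identical configurations produce byte-identical outputs.

What the generator does *not* emulate: sequence evolution, assembly
fragmentation (beyond the coverage-table interface), read-level noise,
GC or length biases, correlated expression programs, and inter-tissue
baseline variation. Passing recovery tests on these data therefore
demonstrates the correctness of the statistical machinery under its own
model, not performance on real genomes.

## Numerical choices and problem sizes

* Dispersion search interval $[10^{-6}, 4]$ on the log scale; APL
  Cox–Reid adjustment dropped for groups with zero totals (boundary
  fits).
* Fisher scoring steps are damped to $\pm 5$ on the log scale to survive
  wild first iterations at extreme starting values.
* PWM scores are rounded at scale 1000 (configurable); every scan
  decision — including the brute-force test oracle — operates on the
  integer grid, so rounding cannot cause disagreement between routes.
* Wilcoxon tests switch from the exact null to the tie-corrected normal
  approximation above 20 pooled observations or at any tie, matching
  standard practice.
* The test suite's simulation sizes are chosen to keep the full run in
  a few minutes: calibration and recovery checks use the full default
  configuration (2000 OGs), while the 100-seed power replicates of the
  duplication–expression and binding-site–expression associations run at
  800 OGs per replicate with default effect sizes — at these effects the
  single-replicate p-values are many orders of magnitude below 0.05, so
  the reduced replicate size does not alter the power conclusion.

## Known limitations

* The summed-cpm-as-counts convention inherits the original design's
  approximation; with per-species library sizes available, a
  length-aware cross-species offset model would be preferable.
* The pooled multi-species contrast has no blocking factor for species.
* Promoter windows are not masked for overlapping genes.
* The generator plants effects multiplicatively and independently per
  OG; it cannot expose the pipeline to correlated pathway-level
  regulation.
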