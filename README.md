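# magniche

Genome-centric analysis of host-associated microbiome niches.

`magniche` is an R package for the downstream half of a
metagenome-assembled-genome (MAG) study of a host-associated microbiome
sampled alongside its surrounding environment — the analyses that start
once bins, per-sample coverage tables and functional annotations exist.
It is written for microbial ecologists working with paired
host/environment metagenomes (the motivating system is a coral holobiont
and the adjacent seawater across reef sites on a water-quality gradient),
in tidyverse style: every function takes a data frame and returns a
tibble, results have `tidy()`/`glance()` methods and `autoplot()`s.

## What it computes

- **MAG quality control** — quality score *Q = completeness − 3 ×
  contamination*; retain MAGs with *Q ≥ 50* and completeness ≥ 75%.
- **Dereplication** — greedy centroid grouping of strain-level duplicates
  at ANI ≥ 99%, per site (replicate redundancy) or overall (cross-site
  strains), with provable representative-separation guarantees.
- **Abundance** — detection at covered fraction ≥ 0.10, scaling of mean
  coverage to the smallest library (Gbp), within-sample relative
  abundance in percent.
- **Habitat specificity** — a MAG is *host-specific* iff it satisfies all
  three criteria: coral : seawater mean relative-abundance ratio > 1,
  seawater prevalence < 50%, and < 0.1% relative abundance in every
  seawater sample.
- **Comparative statistics** — tie-corrected Kruskal-Wallis tests on
  genomic features; two-sided Fisher's exact tests on presence/absence of
  KO/Pfam/CAZy annotations with Benjamini-Hochberg FDR per namespace;
  abundance-weighted Mann-Whitney U tests on orthologous-cluster
  frequencies between water-quality categories.
- **Pathway completeness** — a parser for KEGG-module definition
  expressions (serial steps, alternatives, complexes, optional
  components) and per-genome completeness `100 × satisfied / total
  steps`, flagged at > 75%.
- **Community ecology** — Hellinger transform, Bray-Curtis dissimilarity
  *d(i,j) = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ)*, PCoA, distance-based redundancy
  analysis, one-factor PERMANOVA (pseudo-F on the distance partition,
  seeded permutations, exact enumeration on small designs), envfit-style
  environmental vector fitting with permutation p-values, pairwise
  post-hoc factor fits, Z-scoring and |r| > 0.7 collinearity pruning.
- **A seeded synthetic-study generator** with planted ground truth
  (specificity labels, enriched features, strain groups, an environmental
  driver), so the whole pipeline is testable without sequencing data.

## Worked example

Simulate a study at its default design (22 coral + 6 seawater samples,
six sites, 40 planted host-specific and 30 seawater-specific MAGs) and
run the full pipeline:

```r
library(magniche)
report <- run_demo(seed = 1)
report
#> <magniche_report>
#>   MAGs: 70 total, 70 retained, 70 per-site reps, 66 overall reps
#>   specificity: 40 host-specific, 30 seawater-specific, 0 undetected
#>   enriched features (adj. p <= 0.05): KO=35, Pfam=37, CAZy=8
#>   modules flagged >75%: 85; selected env variables: 1
#>   PERMANOVA sample type: F = 26.3, p = 0.001
```

All 70 synthetic MAGs pass quality filtering, the overall dereplication
collapses the four planted strain pairs (70 → 66 representatives), and
the classifier recovers every planted label. The coral and seawater
communities separate at the permutation floor (p = 0.001 with 999
permutations). The water-quality model on coral samples only:

```r
glance(report$permanova_wq)
#> # A tibble: 1 × 6
#>   statistic R_squared p_value     n n_permutations method
#>       <dbl>     <dbl>   <dbl> <int>          <int> <chr>
#> 1      3.89     0.478   0.003    22            999 sampled
```

Water-quality categories explain about half the distance variance among
coral samples (pseudo-F = 3.89, p = 0.003). Fitting the standardized,
collinearity-pruned environmental variables to that ordination recovers
the planted driver:

```r
dplyr::arrange(report$envfit, dplyr::desc(r_squared))
#> # A tibble: 4 × 7  (top rows)
#>   variable      axis1  axis2 r_squared raw_p n_used adjusted_p
#> 1 temperature  0.979  -0.205    0.866  0.001     22      0.006
#> 2 NH4          0.0861  0.996    0.342  0.018     22      0.054
#> 3 POC         -0.852   0.524    0.296  0.042     22      0.084
```

`temperature` — the variable the generator tied to the compositional
gradient — attains R² = 0.87 and is the only variable passing the
R² > 0.65 selection rule, so it alone builds the final constrained
ordination. Individual pieces work standalone on plain tibbles, e.g.
`quality_score(91.2, 2.03)` returns `85.11`, and
`autoplot(report$ordination_wq, envfit = report$envfit)` draws the
ordination with fitted vectors.

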