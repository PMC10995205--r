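---
title: "Methods: genome-centric analysis of host-associated microbiome niches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-centric analysis of host-associated microbiome niches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magniche)
```

magniche implements the downstream, genome-centric half of a
metagenome-assembled-genome (MAG) survey of a host-associated microbiome —
the part that starts once bins, coverage profiles and annotations exist.
The motivating setting is a coral holobiont sampled alongside the
surrounding seawater across reef sites spanning a water-quality gradient,
but every stage is written against plain tabular contracts, so any paired
host/environment survey fits.

## The analysis model, stage by stage

**Quality filtering.** Each MAG carries CheckM-style completeness and
contamination estimates. The quality score is
`completeness − 3 × contamination`; a MAG is retained when the score is at
least 50 *and* completeness is at least 75%. Both thresholds are inclusive
because the conventions they come from are printed as "≥"; both are
settable in `run_config()`.

**Dereplication.** Strain-level duplicates are grouped at ANI ≥ 99%.
`dereplicate_mags()` uses greedy centroid clustering: MAGs are visited in
descending quality order (ties broken lexicographically by id, for
determinism); each unassigned MAG becomes a representative and absorbs all
unassigned MAGs within threshold of it. We chose the greedy centroid over
single-linkage deliberately: single linkage can chain two genomes that are
*below* threshold to each other into one cluster, whereas the greedy rule
guarantees two testable properties — representatives are pairwise below
threshold, and every absorbed MAG is within threshold of its
representative. External dereplication tools implement secondary
clustering differently in detail, so exact cluster membership on real data
is not expected to be reproduced; the guarantees above are. The ANI matrix
is max-symmetrized (the conservative merge direction) and asymmetries
beyond one ANI point raise a warning. `per_site` mode removes redundancy
between biological replicates within a site; `overall` mode removes
strains recovered independently from different sites before biogeography.

**Abundance.** A MAG counts as detected in a sample when its covered
fraction is at least 0.10 (the read-mapper's default detection rule; the
boundary is treated as detected and the threshold is configurable).
Detected mean coverages are scaled to the smallest library (in Gbp) and
converted to within-sample relative abundance in percent. Because a
uniform per-sample scaling cancels inside within-sample proportions, the
library-size step only matters for cross-sample comparison of
*normalized coverage*; both layers are therefore kept and written, and
relative abundance is the default input to every downstream stage. The
denominator is the sum over the MAG set under analysis, i.e. percentages
are "of mapped MAG reads", not of the total metagenome. A sample in which
nothing is detected is flagged and given `NA`, never silently zeroed.

**Specificity.** The classifier applies three a posteriori criteria; a MAG
is host-specific only if it passes all three, each strict as printed:
mean coral : seawater relative-abundance ratio > 1, seawater prevalence
< 50%, and < 0.1% relative abundance in *every* seawater sample. Means are
taken over all samples of a type with undetected entries contributing
zero; restricting to detected samples would make criterion 1 inconsistent
with criterion 3. A MAG absent from seawater but present in coral gets
ratio +Inf and passes criterion 1 — absence from the free-living pool is
the strongest possible evidence, not an error. MAGs detected nowhere are
labelled `undetected` and excluded from enrichment. Failing *any* one
criterion yields `seawater_specific`; no single criterion is privileged.

**Comparative statistics.** Genomic features (genome size, GC, gene count,
coding density) are compared between specificity groups with the
tie-corrected Kruskal-Wallis test; a zero-variance feature is reported
with H = 0 and p = 1 rather than NaN. Functional enrichment binarizes
annotation counts at ≥ 1 (the question is presence/absence of a function,
not copy number) and uses the two-sided Fisher exact test, BH-adjusted
*within* each namespace — CAZy, KO and Pfam are separate families of
hypotheses reported separately, so adjusting jointly would couple them.
Significance is called at adjusted p ≤ 0.05, inclusive. Cluster
enrichment weights per-MAG cluster copy numbers by the relative abundance
of the carrying MAGs and compares weights between water-quality categories
with a two-sided Mann-Whitney U: exact by complete enumeration of group
assignments while `n1*n2 ≤ 400` (enumeration is correct under ties, which
abundance-weighted data always has), tie-corrected normal approximation
with continuity correction beyond. The raw p at 0.05 is the conventional
decision value for this screen; BH-adjusted values are provided alongside.

**Pathway completeness.** KEGG-module definitions are parsed with the
standard grammar: space-separated serial steps, commas for alternatives,
`+` for complex subunits, `-` for non-essential components, parentheses
for grouping. Completeness is the percentage of satisfied top-level steps.
Nested parenthesized sequences count as one outer step — the dominant
convention among annotation tools, and the one that keeps
satisfied/total well defined. Minus-prefixed components are excluded from
the requirement entirely (not counted, not required), matching the KEGG
meaning of non-essential subunits. Internal `--` gap tokens are ignored
with a warning since their semantics are undocumented. Modules are flagged
in reports when completeness is strictly above 75%.

**Community ecology.** Relative abundances are Hellinger transformed
(square-root proportions), turned into Bray-Curtis distances, and
ordinated by principal coordinates (Gower double-centering +
eigendecomposition). Negative eigenvalues are dropped without correction
— mirroring the uncorrected default of the standard ordination routine —
and reported so the user can judge the departure from Euclidean geometry.
Constrained ordination (`dbrda()`) regresses the PCoA axes on the centered
constraint design; constrained + unconstrained inertia equals total
positive inertia to 1e-8 by construction, and that identity is tested.
PERMANOVA is the one-factor distance partition (`SS_total = Σd²/n`,
within-group sums from within-group distances) with free label
permutation; the models in this analysis are single-factor, so no
multi-factor machinery is included. Environmental vectors are fitted to
the first two ordination axes by least squares (figures are 2-D, and the
upstream convention fits vectors in the plane shown), with permutation
p-values and BH adjustment; variables with R² > 0.65 and adjusted
p ≤ 0.05 feed the final constrained model. Post-hoc pairwise contrasts
use a between-centroid goodness statistic, r² = 1 − SS_within/SS_total on
the pair's 2-D scores with label permutation: the referenced pairwise
factor-fit routine's internals are not specified upstream, so this
package defines the statistic explicitly and does not claim equivalence
on real data. Environmental preprocessing Z-scores each variable (sample
sd, n−1; missing values pairwise) and removes a column whose |Pearson r|
with an already-retained column strictly exceeds 0.7; columns are walked
in input order because the upstream description does not say which member
of a collinear pair was dropped, and determinism requires a rule.

**Permutation conventions.** Every permutation test is seeded and uses
`p = (1 + #{stat* ≥ stat}) / (1 + n_perm)`, so 999 permutations give the
attainable minimum p = 0.001. When the number of distinct label
arrangements is at most `n_perm` (e.g. 3 + 3 samples: 20 arrangements),
`permanova()` switches to complete enumeration and the p-value is exact,
with the observed arrangement included in the reference set. Ties between
a permuted and the observed statistic are counted as at-least-as-extreme
(a 1e-12 slack guards floating-point equality).

## The synthetic-study generator

Sequencing data for a study like this runs to ~10^2 Gbp and cannot ship
with a package, so `simulate_study()` generates a full synthetic study
with planted ground truth. Its defaults are the study-scale conditions: 22
coral and 6 seawater samples across 6 sites in 5 water-quality categories;
40 host-specific and 30 seawater-specific MAGs; completeness with mean
91.2% and sd 7.12 drawn as 75 + 25·Beta (a Beta matched by moments keeps
the mean exact on the bounded support, where a truncated normal would
shift it); contamination as a moment-matched Gamma (mean 2.03, sd 2.16);
library sizes log-uniform on 2–100 Gbp; host-specific MAGs from a
larger-genome (≈4 Mb vs ≈2.5 Mb), lower-GC (≈42% vs ≈52%) regime.

Coverage is log-normal with MAG-level means (`meanlog ~ N(log 5, 1)`) —
a heavy-tailed model chosen because observed MAG relative abundances span
four orders of magnitude; no dispersion model is given upstream, so the
log-normal is a modeling decision of this package. The detection model is
`covered_fraction = 1 − exp(−coverage/κ)` with κ = 1, i.e. the
Lander-Waterman expectation for the fraction of a genome covered at a
given mean depth; it has a closed form, which makes planting
sub-threshold MAGs trivial. At `noise_sd = 0` host-specific MAGs are
absent from seawater and seawater-specific MAGs are detected in every
seawater sample, so label recovery is exact by construction. At the
default `noise_sd = 0.7`, host MAGs additionally spill into seawater
samples with probability 0.15 per sample at a median coverage of 0.08 —
around the detection boundary, chosen to emulate low-level horizontal
acquisition from the water column and to give the classifier genuinely
ambiguous cases rather than a free pass.

Coral-sample composition carries a latent gradient
`z = ρ·g_site + sqrt(1−ρ²)·ε` with per-MAG loadings; the planted driver
variable (`temperature`) follows the site gradient `g` with small noise,
so the correlation between the driver and the dominant compositional axis
is ρ = `env_gradient_strength` (default 0.8) by construction. Other
environmental variables are random site-level means plus within-site
noise, including two deliberately collinear pairs (NO3 tracking NH4, TDN
tracking POC, r > 0.9) to exercise pruning. Functional enrichment is
planted by shifting presence log-odds by ±2.5/2 for 40 of 300 KOs, 40 of
300 Pfams and 8 of 60 CAZy families (three quarters toward the host
group); background features share identical probabilities, so at log-odds
0 the Fisher screen is an exact null. Cluster copy numbers are sparse
Poisson counts without planted structure; the weighted enrichment stage is
validated against hand-constructed fixtures instead.

What the generator does *not* emulate: phylogenetic correlation between
MAGs (features are exchangeable given the group), compositional coupling
between taxa beyond the shared denominator, spatial autocorrelation
between sites, read-level artifacts (mapping bias, contamination of bins),
or taxonomy beyond random phylum labels. Passing tests therefore
demonstrate the correctness of the statistical machinery under a
controlled truth, not robustness to those real-data pathologies.

## Problem sizes and numerical choices

The test suite runs the classifier-recovery property over 20 generator
seeds at the default design, PERMANOVA calibration over 500 null
replicates (n = 20, 199 permutations), envfit driver recovery over 50
seeds, the Fisher oracle over all 2×2 tables with group sizes up to 15,
the BH oracle over 1000 random vectors (lengths 1–500), and the module
oracle over all 64 subsets of a 6-KO universe — sizes chosen so the whole
suite completes in minutes while keeping Monte-Carlo intervals tight
enough to be informative. Identity checks use 1e-9 (distance
reconstruction, abundance sums) or 1e-8 (inertia conservation);
permutation-tie slack is 1e-12.

Degenerate inputs are contracts, not crashes: empty MAG tables filter to
empty results; configurations retaining zero MAGs run the pipeline to
empty-but-valid outputs; all-zero samples are flagged by name; constant
environmental variables are removed with a log entry; constant features
get H = 0, p = 1.

## Known limitations

- The greedy dereplication and the post-hoc pairwise statistic are
  explicit re-definitions of procedures whose upstream internals are
  unspecified; numerical agreement with those tools on real data is not
  claimed (ordination, PERMANOVA and envfit *are* cross-checked against
  vegan in the tests).
- PERMANOVA is single-factor; nested or stratified designs are out of
  scope.
- envfit uses the first two axes only.
- The generator's independence assumptions (above) mean synthetic power
  estimates should not be read as field power estimates.
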