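---
title: "Methods: drought indices, diversity statistics and mixed-model GEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought indices, diversity statistics and mixed-model GEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drygene)
```

`drygene` analyses candidate-gene resequencing panels of geo-referenced
germplasm: it quantifies how drought-stressed each accession's collection
site is, and asks whether allelic variation at a handful of a-priori drought
genes tracks that stress. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data tests do and
do not demonstrate.

## 1. Habitat drought indices

### Model

Thornthwaite's classic potential-evapotranspiration model needs only monthly
mean temperature and latitude. For month $j$:

$$
PET_j = \begin{cases} 1.6\, L_j\, (10\,T_j/I)^a & T_j > 0\\ 0 & T_j \le 0,\end{cases}
\qquad
I = \sum_{j:\,T_j>0} (T_j/5)^{1.514},
$$

with $a = 6.75\times10^{-7}I^3 - 7.71\times10^{-5}I^2 + 1.792\times10^{-2}I
+ 0.49239$ and $L_j = D_j/12$, where $D_j$ is the day length (hours) on the
15th of the month. $D_j$ uses the Forsythe-style declination with the
0.8333° sun-altitude correction; the arccos argument is clamped to
$[-1, 1]$ so polar day/night degrade gracefully to 24 h / 0 h (the clamping
never fires for the subtropical study region the package was built around).
The 15th-of-month ordinal days use a fixed non-leap calendar (15, 46, …,
349).

The monthly drought index compares demand with supply:
$DI_j = 100\,(PET_j - P_j)/PET_j$, positive when demand exceeds rainfall and
bounded above by 100. Two conventions are worth stating explicitly:

* **Units.** The classic formula yields cm/month; WorldClim-style
  precipitation is mm/month. PET is multiplied by 10 before the DI ratio so
  both sides share units. Since DI is a ratio of a difference to PET, only
  consistency matters.
* **Frozen months.** When $PET_j = 0$ the ratio is undefined; the package
  defines $DI_j = 0$ — no evaporative demand, no drought stress. This keeps
  annual aggregates finite for montane sites.

### Timeframes

Seven aggregates are reported per accession: means of $DI_j$ over 3-, 6- and
12-month accumulated windows and over the four calendar trimesters. The
literature this design follows contrasts "accumulated" and trimester
windows without stating which months the 3- and 6-month windows cover; the
package anchors them at January by default and exposes `anchor_month`, so a
user matching a specific phenology can slide them. The 12-month window and
the trimesters are anchor-independent.

Indices are emitted raw and z-scaled (sample, $n-1$, standard deviation);
a zero-variance column scales to zeros with a warning rather than NaNs.
Association scans use the raw indices by default (scaling is a monotone
per-index transform, so single-index test statistics are unchanged; the flag
exists for cross-index comparability of effect sizes).

### Group comparisons

`compare_groups()` screens each taxon's index values with Shapiro–Wilk at
$\alpha = 0.05$ — the conventional screen where the source methodology says
only "indices with normal behavior". All-normal routes to one-way ANOVA +
Tukey HSD; anything else to Kruskal–Wallis + pairwise Wilcoxon with
Bonferroni correction. Groups under 2 members are excluded with a warning;
groups under 3 cannot be screened and force the non-parametric route. Exact
Wilcoxon p-values are used whenever `wilcox.test` supports them (no ties,
small n) — this is what lets the test suite check the route against an
exhaustive permutation oracle.

## 2. Variants

Alignment columns are genotyped haploid: the panel species is highly
autogamous and each accession contributes one Sanger haplotype, so genotypes
are coded 0 (major) / 1 (minor) per sequence, and $H_e = 1 - \sum p_i^2$ is
the expected heterozygosity under random mating — the usual
polymorphism-information proxy for such tables, not an observed quantity.

A column is a SNP when exactly two of {A,C,G,T} occur among non-missing
calls; gaps, N and ambiguity codes are missing data. Columns with more than
two states, or more than 50% missing (tunable), are excluded and logged.
Sequencing-control taxa (label `"control"`) are excluded from frequency
computations by default. The minor-allele-frequency filter is **inclusive**
(≥ 0.05): published per-site tables in this design print sites at exactly
0.05, so a strict filter would contradict the tables it feeds.

`catalog_fixture()` materialises the published SNP catalog as a
deterministic 100-sequence alignment: with $n = 100$, 2-decimal printed
frequencies are integral counts, so the caller recovers the printed
positions, alleles and frequencies exactly. Allele assignment is per-site
independent — haplotype phase is not recoverable from a frequency table —
so haplotype-level analyses should use the coalescent simulator instead.

## 3. Diversity statistics

Per gene and per taxon the package reports $S$, mean maf, mean $H_e$,
nucleotide diversity $\pi$, Watterson's $\theta_W = S/(a_1 L)$ with
$a_1 = \sum_{i<n} 1/i$, and Tajima's $D$ with the original normalising
constants; $D$ is NA (not 0) when $S = 0$ or $n < 4$.

Missing-data policy for $\pi$ is pairwise deletion with a per-pair effective
length (the convention of the standard desktop tools for such data), with
complete deletion available via a flag. The "All" row applies the maf
filter before counting $S$ and computes $\pi$, $\theta_W$, $D$ on the same
filtered columns; per-taxon rows use the sites segregating within that
taxon, unfiltered — this is the only reading under which published per-taxon
$S$ can exceed the whole-panel $S$, as it does in the tables this design
mirrors. Taxa with fewer than `min_n = 4` sequences are skipped: below four
sequences Tajima's D is undefined and the remaining statistics are
dominated by sampling noise.

## 4. Structure

* **Fst** is Hudson's per-SNP estimator in heterozygosity form,
  $F_{ST} = 1 - H_w/H_b$, with the unbiased ($n/(n-1)$) within-taxon
  heterozygosity. It is transparent, nearly unbiased, and isolated behind
  one function so a Weir–Cockerham variant could be swapped in. The
  sampling correction makes equal-frequency SNPs dip slightly below zero;
  raw values are retained and flooring at 0 is left to reporting, so
  distribution summaries are not censored.
* **PCA** mean-imputes missing genotypes per column, centres, and uses the
  SVD; scores are reported for the first $k$ components (default 2, the
  number used as fixed covariates downstream).
* **Kinship** is plain identity-by-state: the fraction of co-observed SNPs
  with matching alleles. IBS matrices from few SNPs are often not positive
  definite; the mixed-model code bends them by flooring eigenvalues at
  $10^{-6}$ with a warning.
* **NJ trees** use p-distances (pairwise deletion; Jukes–Cantor via flag —
  the distance model is a documented free choice, and at amplicon-scale
  divergences the two are nearly affine). Negative branch lengths are
  floored at 0. Bootstrap resamples alignment columns; support is the
  percentage of replicates containing each internal bipartition.
* **Median-joining networks** iterate minimum-spanning-network construction
  (tolerance $\varepsilon$, default 0 as in standard implementations) with
  majority-consensus median vectors proposed from connected triplets; a
  sweep adds the median that most shortens the spanning length, terminating
  when none helps, then prunes median vectors of degree < 3. On biallelic
  sites the majority median is the exact quasi-median; the all-states-differ
  tie branch keeps the focal node's state and cannot fire on biallelic
  data. The test suite checks the result against brute-force Steiner
  enumeration on small cases.

## 5. Genotype×environment association

The environmental index is the response and the marker a predictor — the
convention of loading the index as the "phenotype" in standard GWAS tools.
The mixed model is

$$ y = g\beta + Q\gamma + u + e,\qquad u \sim N(0, \sigma_g^2 K), $$

with $Q$ the first two genotype PCs by default. The variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ is REML-estimated **once per scan** under
the null model through a single spectral decomposition of $K$
(EMMA-style profiled likelihood, P3D-style reuse across markers: per-marker
re-estimation is much slower and changes little for single-gene panels).
Each marker is then tested by GLS Wald F with $\delta$ fixed; markers with
missing genotypes are handled exactly by subsetting the covariance, not by
imputation. With $K = I$ the model provably collapses to the fixed-effects
scan, which the tests verify to $10^{-6}$.

CMLM clusters individuals on $1 - K$ (average linkage), replaces $K$ by the
between/within-group means expanded back to individuals, and picks the group
count from the grid $\{1, \lceil n/8\rceil, \lceil n/4\rceil, \lceil
n/2\rceil, n\}$ by maximum null REML likelihood — a fixed, deterministic
grid; a full sweep is deliberately not the default. At $g = n$ CMLM equals
MLM; at $g = 1$ the exchangeable random part makes the marker test collapse
to the GLM one (GLS under equicorrelation with an intercept is OLS).

Haplotype association enters the haplotype class as a multi-level fixed
factor (rare classes, < 2 carriers, pooled into `"other"`) and reports the
omnibus F; with two classes it reduces to the marker model.

Significance uses the dual convention of candidate-gene designs: flagged at
p < 0.05 (strict) and at p ≤ 0.01 — the latter a fixed FDR-equivalent cutoff
for a small set of a-priori functional genes, deliberately **not** a
Benjamini–Hochberg procedure.

## 6. The synthetic-data generator

`simulate_alignment()` draws a standard n-coalescent genealogy (sequential
pairwise coalescence, exponential waiting times), drops Poisson($\theta/2$
per unit branch) mutations under infinite sites, and writes them into a
random ancestral sequence — so $E[S] = \theta a_1$ gives an analytic oracle.
Structured mode overwrites a `divergence` fraction of variant sites with
fixed between-taxon differences. The default taxon structure is the panel
the package was designed around (23 + 6 + 4 + 19 accessions in four taxa).
`simulate_climate()` produces seasonal-cosine temperatures and
gamma-distributed precipitation; `simulate_coupled()` adds an environmental
index $\beta \cdot g_{causal} + \text{taxon effect} + N(0,\sigma)$ with a
truth record.

What the simulator deliberately does **not** emulate: recombination within
amplicons, selection, sequencing error, missing-data patterns correlated
with taxon, and real spatial autocorrelation of climate. Passing the
property suites therefore demonstrates correctness of the *statistics* under
their own sampling assumptions — not robustness to every artefact of real
Sanger panels.

## 7. Problem sizes and numerical choices

The test suite's calibration experiments use sizes chosen to make sampling
error small relative to the asserted tolerances while staying desk-scale:
500 neutral coalescent replicates at $n = 20$, $\theta = 5$, $L = 1000$ for
the SFS calibrations (mean Tajima's D in $(-0.3, 0.3)$, $E[S]$ within 5%,
$\hat\theta_W$ and $\hat\pi$ within 15%); 1000 replicates at $n = 50$ for
GLM/MLM type-I error (within two binomial standard errors of 0.05); 200
replicates for MLM power against a marker explaining 30% of variance
(> 80% at p ≤ 0.01). REML optimisation runs on $\log\delta \in [-12, 12]$
via golden-section search of the profiled likelihood — the profile is
unimodal in well-posed problems, and the wide bracket covers effectively
pure-environmental to effectively pure-genetic variance.

## 8. Known limitations

* Coding/non-synonymous status of SNPs is a user-supplied annotation, not
  inferred from an ORF.
* Indels are treated as missing data, never genotyped.
* The Fst estimator is per-SNP Hudson only; multi-SNP ratio-of-averages
  estimators are out of scope.
* The day-length model is the Forsythe approximation; sub-minute agreement
  with ephemerides is not a goal.
* CMLM's group grid is coarse by design; likelihood plateaus can make the
  chosen group count sensitive to near-ties (the choice is deterministic
  given the data).
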