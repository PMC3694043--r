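---
title: "Stratified nonparametric linkage analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified nonparametric linkage analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stratlink)
```

## The problem

Genome scans for phenotypically heterogeneous disorders routinely fail to
replicate: when distinct genetic liabilities are pooled into one "affected"
category, the allele-sharing signal contributed by any one liability class is
diluted by families segregating a different one. `stratlink` implements a
multi-level stratification strategy for multiplex nuclear families (families
with two or more affected siblings) in which each family carries per-affected
sub-phenotype labels from an upstream classification (four clusters `g1`-`g4`
derived from diagnostic-interview severity profiles, taken here as input),
and nonparametric linkage is run separately within each stratified subgroup:

* **G level** — families with at least one affected of subtype `gk`, keeping
  *all* affected siblings regardless of their own subtype (inter-family
  heterogeneity reduced, intra-family heterogeneity retained);
* **Gs level** — the same families with discordant affecteds removed, keeping
  only siblings concordant for `gk`; families left with fewer than two
  concordant affecteds are no longer multiplex and drop out;
* **GM / GFc level** — the Gs families split into male-only versus
  female-containing pedigrees, judged on the retained concordant affecteds.

With four subtypes this yields 16 subgroup analyses; an unstratified `ALL`
scan is kept for comparison, and pairs of subgroups sharing a candidate
region can be pooled with `merge_subgroups()` (a strict set union of
families). Because one subgroup catalogue means 16 opportunities for a
chance maximum, a study-wide significance layer re-runs the entire
stratify-and-scan pipeline on label-randomized cohorts and refers the best
observed peak to the null distribution of the across-subgroup maximum.

Affecteds removed at the Gs level are treated as unknown phenotype (they are
simply excluded from the scoring set; their genotypes still inform the
inheritance distribution). Diagnosis classes support the two-stage design in
which strict diagnoses are analysed first (`n1`) and broad-spectrum subjects
are added afterwards (`n2`); `expand_cohort()` rebuilds any subgroup recipe
at the n2 stage, and the n1 family set is provably a subset of the n2 set.

## The linkage model

### Inheritance-vector HMM

For a nuclear family with $c$ children, the hidden state at a map position is
the inheritance vector $v \in \{0,1\}^{2c}$, one bit per meiosis, recording
which parental haplotype each child received paternally and maternally.
`lander_green_ibd()` runs the standard forward-backward recursion over the
markers of each chromosome:

* the prior is uniform over the $2^{2c}$ vectors;
* the emission is the probability of the observed genotypes given $v$,
  obtained by summing over ordered founder-allele assignments weighted by
  population allele frequencies (founder-allele peeling); missing genotypes
  are summed over, never imputed;
* transitions between adjacent positions flip each bit independently with
  the Haldane recombination fraction
  $\theta = \tfrac12(1 - e^{-2d/100})$ of the inter-marker distance $d$ (cM).

The returned distribution at every position is conditional on all markers of
the chromosome (multipoint). The exact HMM is exponential in sibship size;
the meiosis budget defaults to 16 bits (8 children), far beyond the sibships
the simulator produces, and larger or non-nuclear families are skipped with
a warning rather than approximated.

### Allele-sharing score and Kong-Cox LOD

Within each family, `npl_pairs()` scores the retained affected siblings with
$S_{\text{pairs}}$: the total number of alleles shared identical-by-descent
summed over all affected pairs, in expectation under the multipoint
inheritance distribution. The score is standardized by its exact mean and
standard deviation under the uniform (null) inheritance distribution, giving
$Z_i = (S_i - \mu_0)/\sigma_0$; a lone scoreable affected leaves
$\sigma_0 = 0$ and the family is excluded as uninformative.

Families are combined at each position with the Kong-Cox one-parameter
linear model: maximize

$$\mathrm{LOD}(\delta) = \sum_i \log_{10}(1 + \delta Z_i), \qquad \delta \ge 0,$$

subject to every per-family likelihood ratio $1 + \delta Z_i$ remaining
positive. The bound used is $\min_i(-1/Z_{\min,i})$ where $Z_{\min,i}$ is
family $i$'s *minimum attainable* standardized score (known exactly from the
sharing distribution); for a cohort of affected sib pairs this equals
$1/\sqrt{2} \approx 0.707$. The maximization is a clamped Newton ascent of a
concave scalar function, vectorized across positions; the test suite checks
it against a dense $\delta$-grid search at step $10^{-5}$. The one-sided
constraint truncates the LOD at zero.

The pointwise significance of a LOD score is the standard normal conversion
$p = 1 - \Phi(\sqrt{2\ln 10 \cdot \mathrm{LOD}})$, with LOD $= 0 \mapsto
p = 0.5$. This conversion reproduces, at printed precision, more than thirty
of the LOD/p pairs published for this analysis strategy, which is the basis
for adopting the $S_{\text{pairs}}$/linear-model combination here.

### Study-wide significance

`randomize_cohort()` permutes family-level label vectors (each family's
per-affected subtype and diagnosis-class assignments, moved as one unit)
between families, stratified by affected count so every family receives a
vector of the right length. This preserves the subgroup size spectrum and
each family's internal structure and genotypes while destroying the
label-genotype association. For each of `N` replicates the 16 subgroups are
rebuilt from the permuted table and rescanned — the per-family inheritance
distributions are label-independent and therefore computed once and cached —
and the across-subgroup genome-wide maximum LOD is recorded. The study-wide
p of the best observed peak is $(r+1)/(N+1)$ by default (the raw $r/N$
convention is available for comparison with older reports). `N = 100`
mirrors the published design and bounds resolution at about 0.01.

The maximum is taken over the 16 label-dependent subgroups only. The
unstratified `ALL` scan is invariant under label permutation; folding a
shared constant into both the observed and the null maxima would create an
atom at $p = 1$ and destroy the uniformity that makes the permutation p
interpretable.

### TDT

`count_transmissions()`/`tdt_statistic()` implement the McNemar-form
transmission disequilibrium test $\chi^2 = (b-c)^2/(b+c)$ on trios drawn
from a stratified cohort. By default one affected child per family (the
proband, i.e. the first retained affected in canonical order) is used, so
sibling non-independence cannot inflate the statistic; trios with an untyped
parent are dropped rather than reconstructed. Transmission assignments that
remain ambiguous after phase enumeration are skipped and counted.

## The synthetic cohort generator

Real genotype and interview data for this design are access-restricted, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, and every claim the test suite makes is a claim about this
generator:

* nuclear families (two founders plus a sibship), founder genotypes drawn
  from per-marker allele frequencies, offspring by gene-dropping with
  Haldane recombination — hence zero Mendelian errors and linkage
  equilibrium between markers before `inject_noise()` is applied;
* sub-phenotypes: the proband's subtype is drawn from `subtype_probs`;
  each further affected shares it with probability `concordance`, else
  draws from the renormalized remainder;
* risk loci: at a locus with sibling relative risk $\lambda_s$, affected
  pairs in families concordant for the locus subtype follow the
  no-dominance sharing triple
  $z = (0.25/\lambda_s,\; 0.5,\; 0.5 - 0.25/\lambda_s)$. The generator
  realizes this by letting each affected sibling after the first share the
  first affected's paternal meiosis bit with probability
  $1 - 0.5/\lambda_s$ while the maternal meiosis stays neutral — the unique
  two-Bernoulli factorization of the triple, which loads the excess on one
  parental side; for sibships with more than two affecteds the sharing
  between two non-index affecteds is slightly above the pairwise target,
  a known and accepted approximation.

Default scenario parameters are chosen once to emulate the cohort the
stratification strategy was developed for: 392 multiplex families; sibship
sizes 2-4 (65/25/10%), mostly two affecteds (85% two, 15% three); a 4:1
male-to-female ratio among affecteds (`female_affected_prob = 0.2`);
`concordance = 0.3`, which reproduces the published narrative that roughly
a quarter of G-level families survive concordance filtering (63 of 232 in
the most severely affected subgroup); `subtype_probs` uniform over the four
clusters, since subtype marginals are not directly recoverable from
published family counts; `broad_fraction = 0.15`, consistent with the
reported growth of the cohort from 337 to 392 families when broad-spectrum
diagnoses were added; and a panel of 200 markers per chromosome at 1 cM
spacing with minor allele frequencies uniform on (0.1, 0.5), a desk-scale
stand-in for a filtered genome-wide SNP set.

What the generator deliberately does **not** model: linkage disequilibrium
between markers (the analysis assumes an LD-pruned panel; `scan_genome`
performs no LD correction), population structure and ethnicity, extended or
loop pedigrees, genotyping batch effects, and X-linked inheritance (the
package is autosomal throughout). Passing tests therefore demonstrate
correctness of the machinery and power/calibration under these idealized
conditions, not performance on any real cohort.

## Quality control

`apply_filters()` reproduces conventional array-QC marker exclusion:
founder-only minor allele frequency below `maf_min` (default 0.05),
missingness above `missing_max` (default 0.10 — the source description says
"high rate" without a number), exact Hardy-Weinberg test below `hwe_alpha`
(default 0.001, the conventional array-QC value; the published account does
not state test or threshold, so the two-sided exact test on founders was
chosen), and more than `mendel_max` (default 1) Mendelian errors per marker
summed over families. MAF and HWE use founders only to avoid relatedness
inflation. The filters are logically independent, so the surviving marker
set does not depend on application order.

## Numerical choices and degenerate inputs

* Duplicate genetic positions are jittered upward by $10^{-6}$ cM (stable
  order by marker id): the HMM requires strictly positive inter-marker
  distances.
* Forward-backward vectors are rescaled to sum to one at every marker; a
  zero-sum emission (a genotype configuration impossible under every
  inheritance vector, i.e. an unfixed Mendelian error) raises an error
  naming the family and marker rather than propagating NaN.
* The Kong-Cox Newton ascent is clamped to $[0, (1-10^{-9})\,\delta_{max}]$
  and iterated to $|\Delta\delta| < 10^{-12}$; positions whose score sum is
  non-positive stay at $\delta = 0$, LOD $= 0$.
* Individuals with exactly one recorded parent are rejected at input
  (founder identification assumes both-or-neither), and half-called
  genotypes are rejected rather than half-used.
* Evaluation positions default to the marker grid; an optional uniform grid
  interpolates the multipoint distribution between markers (off-marker
  posteriors combine the forward and backward distributions spread through
  the Haldane kernel of the flanking gaps).
* Monomorphic markers return an exact HWE p of 1 and a MAF of 0, and are
  excluded by the MAF rule, not by a special case.

## Problem sizes used by the test suite

The suite verifies the HMM against exhaustive joint enumeration on 100
random pedigrees of up to 6 meioses and 3 markers (tolerance $10^{-8}$), the
Kong-Cox maximizer against a $10^{-5}$ grid on 1000 random score sets
(tolerance $10^{-4}$ LOD), parameter recovery of a $\lambda_s = 2$
subgroup-private locus on cohorts of 100 families over 50 seeds (21-25
markers at 5 cM), and permutation calibration with 100 outer cohorts of 20
families, each assessed with $N = 100$ randomized replicates on a 16-marker
genome, testing uniformity of the study-wide p by Kolmogorov-Smirnov at
$\alpha = 0.01$. These sizes are the package's chosen desk-scale study
conditions; the published cohort-scale results (LOD scores above 4, the
study-wide $P = 0.02$, the specific family counts) require the restricted
data and are represented in the suite only through these structural and
statistical properties.

## A worked example

```{r example, eval = FALSE}
library(stratlink)

## a cohort with one g1-private risk locus
sc <- simulation_scenario(
  n_families = 100, n_chrom = 2, markers_per_chrom = 21, spacing_cm = 5,
  linked_loci = list(list(chrom = 1, cm = 50, subtype = "g1", lambda_s = 2)))
sim <- simulate_cohort(sc, seed = 1)

qc <- apply_filters(sim$cohort, sim$map)
cache <- linkage_cache(sim$cohort, qc$map)
cat16 <- stratify_catalogue(sim$cohort, sim$subtypes, stage = "n2",
                            include_all = TRUE)

all_curve <- scan_genome(sim$cohort, qc$map, cache = cache)
g1s_curve <- scan_genome(sim$cohort, qc$map, strat = cat16$G1s, cache = cache)
peak_table(list(ALL = all_curve, G1s = g1s_curve), top_k = 2)

sw <- studywide_significance(sim$cohort, qc$map, sim$subtypes,
                             N = 100, seed = 2)
sw$p
```

## Known limitations

* Autosomal, nuclear, two-founder families only; no parametric LOD, no
  X-linked model, no half-typed parent reconstruction.
* $S_{\text{all}}$ scoring and sex-specific maps are not implemented; the
  scoring statistic is $S_{\text{pairs}}$ with a sex-averaged Haldane map.
* The permutation layer randomizes labels; gene-dropping simulation of
  genotypes given pedigrees is an alternative null that is noted but not
  provided.
* With $N = 100$ replicates the smallest attainable study-wide p is
  $1/101 \approx 0.0099$; increase `N` for finer resolution.
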