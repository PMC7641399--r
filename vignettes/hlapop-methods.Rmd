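---
title: "Methods: HLA variation against a neutral background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HLA variation against a neutral background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlapop)
```

## Scope and rationale

`hlapop` analyses variation at the four classical HLA loci (A, B, C,
DRB1) in a set of population samples, using a genome-wide microsatellite
panel typed in the same individuals as a neutral demographic control.
The logic throughout is comparative: demography affects all loci
jointly, so neutral markers predict what HLA "should" look like absent
selection, and departures from that prediction — in diversity,
site-frequency spectra, or differentiation — are the quantities of
interest. This vignette documents the models and estimators, the
parameter choices, the synthetic-data generator, and the numerical
conventions, in enough detail that every number the package produces is
reproducible from first principles.

## Data model

Genotypes are held in a long tibble (population, individual, locus,
unordered allele pair). Allele names are reduced to two-field
(protein-level) resolution on read: deeper fields describe synonymous or
non-coding variation and worldwide reference frequencies are almost
universally reported at two fields. A trailing `G`/`g` marks a g-group
(alleles identical over the typed exons reported under one name); after
reduction these behave as ordinary two-field alleles — the information
lost is minimal and the alternative (carrying ambiguity sets through
every estimator) would complicate all downstream contracts. Allele order
within a genotype is non-semantic and canonicalized by lexicographic
sort, so equality of cohorts is well defined and file round-trips are
exact.

Individuals untyped at a locus are dropped *per locus*, not globally:
per-locus chromosome counts n therefore differ within a population,
which is the rule rather than the exception in real HLA tables. Where a
cross-locus summary needs one value per population (e.g. "mean HLA
heterozygosity"), we average the available loci; the alternative —
restricting to individuals complete at all loci — discards data and
changes n inconsistently across analyses.

## Diversity

Sample heterozygosity uses the unbiased estimator
$H = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$,
the convention of the standard HLA summary-statistics tools; a flag
disables the $n/(n-1)$ correction for comparison with sources that
report plug-in gene diversity. Microsatellite heterozygosity applies the
same estimator per marker and averages markers.

Regional contrasts use one-way ANOVA on per-population heterozygosity
followed by Tukey's HSD, which controls the family-wise level across
region pairs. The Aché population is excluded by default from regional
summaries: it is an extreme diversity outlier whose inclusion makes
every SAL contrast about one population. The exclusion is a per-analysis
flag (`exclude = "Ache"`), on for regional summaries and off for
per-population tables. If all responses are identical the ANOVA F
statistic is undefined; we return adjusted p = 1 for every contrast,
which is the correct inferential statement.

Individual-level association regresses each individual's proportion of
homozygous microsatellite markers on their count of homozygous HLA loci
(0–4), per population, flagging significance under Bonferroni at
`0.05 / populations tested`; a fixed printed threshold can be supplied
for comparison with published analyses. The class-trend analysis groups
individuals into 0 / 1 / 2+ homozygous HLA loci and regresses
microsatellite homozygosity on class scores 0, 1, 2 — a linear-contrast
trend test. The choice of scores is a convention; any monotone scoring
gives the same test up to affine equivalence for three classes.

## Exact test of Hardy–Weinberg proportions

Conditional on the allele counts $m_1 \dots m_k$ of $2n$ gametes, a
genotype array $\{n_{ij}\}$ has probability
$$P = \frac{n!\,2^{H}\,\prod_i m_i!}{(2n)!\,\prod_{i\le j} n_{ij}!},$$
with $H$ the number of heterozygotes. The p-value is the total
probability of arrays no more probable than the observed one (ordering
by conditional probability — the cited exact-test convention — rather
than by heterozygote count; directionality is reported separately
through residuals). Small array spaces are enumerated exhaustively by
depth-first search over margin-consistent arrays; the decision uses a
cheap product upper bound on the space size against `max_arrays`
(default 10^6). Larger spaces are sampled by permuting the observed
gamete vector into random pairings (`mc_steps` draws, default 10^5,
seeded), which samples the conditional distribution exactly; the
Monte-Carlo p-value uses the add-one estimator $(1+\#\{P \le
P_{obs}\})/(B+1)$. Ties on the statistic are compared with a relative
log-probability tolerance of 10^-9.

Per-genotype diagnostics are standardized residuals
$(obs - exp)/\sqrt{exp}$ against HWP expected counts from the sample
allele frequencies, flagged two-sided at |residual| > 1.96. The 1.96
threshold is our diagnostic convention, not a calibrated test; expected
counts of zero yield undefined residuals, reported as `NA`. Whether
published per-genotype findings used residuals or per-genotype exact
tests is generally ambiguous; residuals are transparent and
directional, which is what the diagnostic is for.

## Ewens–Watterson test

Under the infinite-alleles model, the distribution of the allele
configuration (the partition of n into k part sizes) conditional on
observing k alleles is free of θ:
$P(\text{config}) \propto 1 / \bigl(\prod_i n_i \prod_j a_j!\bigr)$,
where $a_j$ counts parts of size j. We enumerate all partitions of n
into exactly k parts when there are at most 10^5 of them (always the
case for the sample sizes of HLA population surveys; partitions of 50
chromosomes into any k number in the low tens of thousands) and compute
$F_{exp} = E[\sum p_i^2 \mid n,k]$ and the lower-tail
$p = \Pr(F \le F_{obs} \mid n, k)$ exactly. Beyond the threshold, the
fallback samples configurations by the sequential (Chinese-restaurant)
construction at a θ matched to $E[k\,|\,n,\theta] = k$ and rejects draws
with the wrong k — conditional on k the accepted draws follow the exact
conditional distribution regardless of θ, so the estimator is unbiased.
The lower-tail convention means small p indicates balancing selection
(frequencies too even) and p near 1 directional selection; two-tailed
significance at 0.05 is p < 0.025 or p > 0.975. The k = 1 case is
degenerate (F = 1 by definition) and returns p = `NA`.

## Tajima's D

Allele calls are recoded to aligned DNA sequences (one per chromosome,
multiplicity = copy count) via a per-locus sequence map; loci whose
typing resolution does not map alleles uniquely to sequences cannot be
recoded and raise an explicit error listing the absent alleles.
Alignment columns containing any gap are excluded entirely (complete
deletion, the common default). π is the mean pairwise difference over
all $\binom{n}{2}$ pairs, counting identical sequences with
multiplicity, computed columnwise as $\sum_c (n^2 - \sum_a c_{a}^2) / 2
/ \binom{n}{2}$. D uses the standard constants $a_1, a_2, b_1, b_2,
c_1, c_2, e_1, e_2$; S = 0 is an error (the statistic is undefined),
not a zero.

The p-value is $\Pr(D_{sim} \ge D_{obs})$ under a neutral coalescent
null: each replicate draws a Kingman genealogy (exponential coalescence
times, uniform pair merges), and mutations are placed on branches with
probability proportional to branch length. By default exactly S
mutations are placed (conditioning on the observed number of segregating
sites); a θ̂-parameterized Poisson option (`fixed_s = FALSE`) is
provided because published tool chains differ on this point and the two
conventions give slightly different nulls. With this orientation the
p-value matches the Ewens–Watterson convention: strongly positive D
(balancing selection) gives small p, strongly negative D gives p near
1. The default is 10^4 replicates; `n_sims = 0` skips the p-value when
only D is needed.

## AMOVA F_ST, R_ST and Z_ST

Pairwise differentiation is a two-level AMOVA at the haplotype
(chromosome) level: the 2n typed chromosomes are the units (the diploid
packaging of alleles into individuals is ignored — published tool chains
are silent on this, and at HWP the two choices agree in expectation).
The squared distance between chromosomes is allele identity (0/1) for
F_ST and squared allele-size difference for R_ST (meaningful under
stepwise mutation). All sums of squares reduce to allele-count
arithmetic, so the 678-marker × all-pairs sweep never forms a distance
matrix. Negative estimates are retained as computed — they are the
estimator's behavior for undifferentiated pairs and truncation would
bias background means. A pair monomorphic for the same allele has no
variance to partition and is returned as F_ST = 0 with a `degenerate`
flag; microsatellite markers monomorphic within a pair likewise
contribute 0 to the background vector rather than being dropped, keeping
the panel denominator stable across pairs.

Z_ST standardizes each HLA pairwise F_ST against the microsatellite
background *of the same population pair*:
$Z_{ST} = (F_{ST}^{HLA} - \overline{F_{ST}^{msat}}) / SD(F_{ST}^{msat})$,
with the mean and SD computed per pair (our reading of the per-pair
formulation; a pooled alternative would mix pairs with very different
backgrounds). The empirical p-value is the proportion of markers with
F_ST *strictly* greater than the HLA value, so its resolution is one
over the panel size; the `mean_HLA` row standardizes the mean of the
four per-locus F_ST values (the regional "mean HLA" is likewise the mean
of locus-level values, not an F_ST on concatenated data). Regional
aggregation averages $-\log p$ (natural log) over the pairs of a region
pair; $-\log p = 3$ corresponds to p ≈ 0.05. Zero empirical p-values are
floored at half the panel resolution before taking logs, only for this
aggregation.

## Endemic / LFD classification

Each allele's unweighted mean frequency across the Native American
populations (zeros included for populations lacking it) is compared
with its unweighted mean across the unflagged populations of a
worldwide reference panel; migrant and uncertain-origin populations are
excluded from the reference mean because they can carry American
alleles back across the classification boundary. Categories: *endemic*
(reference mean exactly 0), *LFD* (ratio ≥ 3, inclusive — "at least
3-fold" is read as a closed bound), *other*. Calls supported by ≤ 3
allele copies in the Americas (copies summed over all Native
populations) are flagged *poorly supported*: small samples produce
large ratios by chance. When an independent secondary native/non-native
comparison is available, an LFD allele poorly supported in both
datasets is removed from the final list (alleles absent from the
secondary data count as unsupported there); without a secondary
dataset, removal degrades to the primary flag with a warning, so the
filter can only ever shrink the LFD list.

Per-population category sums (which partition each locus's allele mass:
endemic + LFD + other = 1) are averaged unweighted within regions, with
the Aché excluded by default from every cell (applying the exclusion
everywhere, not just at single loci, is the internally consistent
choice and matches the published all-regions class II mean). The
"burden" correlate is the Pearson correlation, per locus, between each
population's endemic+LFD total and its mean microsatellite
heterozygosity — negative when drift, not selection, concentrates
restricted alleles.

## EM haplotypes and ASH

Two-locus haplotype frequencies are estimated by gene-counting EM on
unphased genotypes: only double heterozygotes have ambiguous phase, and
their two resolutions are weighted by the current haplotype
frequencies. The log-likelihood is asserted non-decreasing at every
iteration; convergence is a log-likelihood change below `tol = 1e-8`,
with `max_iter = 10^4` and a warning (best estimate returned) on
non-convergence. Because the likelihood can be multimodal for small
samples, the best of one linkage-equilibrium initialization plus
`restarts` random Dirichlet initializations (default 10; seeded) is
returned. Estimated haplotype margins reproduce the sample allele
frequencies to numerical precision — a fixed point of the M step.

Allele-specific heterozygosity conditions on allele a at one locus:
$ASH(a) = 1 - \sum_b (h_{ab}/p_a)^2$, the plug-in heterozygosity of the
conditional partner distribution (no small-sample correction — none is
established for this statistic, and category comparisons are within the
same sample sizes). ASH is 0 exactly when the allele rides one
haplotype, the signature of a young or recently selected allele.
Category summaries run the EM in every population and locus pair and
average allele-level ASH values with equal weight per allele (our
reading of "averaged over all alleles of that type for each pair of
loci"; population-first pooling is the noted alternative and would
weight populations equally instead). Frequency strata follow the
conventional bounds (0.05, 0.10] and > 0.10, with the conditioned
allele's frequency measured in the population where ASH is computed;
alleles at or below 0.05 are excluded from the per-locus rows as well —
the stratification exists precisely because low-frequency alleles have
mechanically low ASH, and the lower bound is where the published
stratification starts.

## The synthetic cohort generator

`sim_cohort()` emulates the study design the package exists for, with
known ground truth:

- **Allele pools.** Each locus's source frequencies come from a single
  large Chinese-restaurant draw with locus-specific θ (defaults A = 6,
  B = 14, C = 6, DRB1 = 7, making B the most polymorphic locus as in
  real data, with pooled allele counts in the tens).
- **Demography.** A founder chain (defaults: SIB → NAM → MEA → SAA →
  SAL with bottleneck sizes 400, 150, 90, 60, 35 diploids and 4–8
  generations each; 1/3/6/4/10 populations per region; 20 diploids
  sampled per population, matching the survey's scale of 24 populations
  and ~420 individuals) evolves frequencies by Wright–Fisher binomial
  resampling; populations within a region are founded serially from one
  another with `g_pop = 3` extra generations. Drift on frequencies
  (rather than genealogies) is deliberate: it is orders of magnitude
  cheaper and is sufficient for the heterozygosity-cline,
  differentiation and endemic-allele behavior the tests target. The
  global founding order is recorded as the route ordering — the
  generator's analogue of a least-cost-path rank, which the package
  consumes but never computes.
- **Microsatellites.** 678 markers (the study panel size) on an integer
  size grid, with a deterministic stepwise-mutation flow (rate
  `mu_msat = 10^-3` per copy-generation, half up/half down, reflected
  at the grid edge) plus the same binomial drift, so R_ST is meaningful
  and heterozygosity clines appear at neutral markers too.
- **Planted truth.** Endemic alleles are created after the split from
  the reference world at region-level target frequencies and are absent
  from every unflagged reference population (a few *flagged* migrant
  reference populations do carry them, exercising the flag-exclusion
  logic). LFD alleles are planted continent-wide at native frequencies
  5–7× their reference frequencies. The truth record lists every
  planted allele with its category, so classification recall and
  precision are scoreable.
- **Reference panel.** 50 populations (a configurable, scaled-down
  stand-in for a worldwide meta-analysis of hundreds) drawn as
  Dirichlet perturbations of the source frequencies.
- **LD.** Haplotypes at the first two loci are coupled with weight
  `ld_dprime` (exactly Lewontin's D′ in the biallelic case; a mixture
  of the independence and comonotone couplings otherwise). Planted
  alleles at the second locus are locked onto as few partner haplotypes
  as the margins allow — margins at both loci are preserved — so young
  planted alleles have low ASH, as real young alleles do.
- **Sequences.** Per-locus allele sequences in two regimes:
  `balanced_clades` (two deep clades separated by ~24 substitutions —
  the positive-Tajima's-D regime of long-term balancing selection) and
  `star` (private substitutions only — the negative-D regime).

What the generator does **not** emulate: real American demographic
history (dates, a Beringia standstill, post-contact collapse),
selection itself (no fitness differences — planted alleles mimic the
*pattern* drift produces), allele-name ambiguity across typing eras,
missing-data structure, and recombination within loci. Passing tests on
synthetic cohorts therefore demonstrate that the estimators recover
known truth under the stated demographic model — not that any
biological conclusion about real populations is correct.

Identical `sim_params()` (including seed) give byte-identical output;
all randomness in the package flows through explicit seeds, and
derived per-stage seeds keep every stochastic stage independently
reproducible.

## Problem sizes and calibration checks

The test-suite and acceptance-script sizes are chosen so the full
calibration battery runs in minutes on one core while keeping binomial
error well inside the tolerances checked: Ewens–Watterson uniformity
and two-tailed rejection over 2,000 neutral replicates at n = 50, θ = 3
(θ large enough that the discrete conditional null is dense and the
Kolmogorov–Smirnov comparison against the uniform is meaningful); HWP
calibration over 400 replicates with 1,000 Monte-Carlo permutations
each; Tajima's D sign behavior over 100 replicates per regime;
classification recall over five full cohorts with a 50-population
reference panel; the founder-chain cline over 100 replicates of a
4-population chain at bottleneck 25. Enumeration-vs-Monte-Carlo
agreement is checked at 3 Monte-Carlo standard errors on instances
small enough for both paths.

## Known limitations

- The exact-HWP enumeration bound is a loose product bound; some
  enumerable instances fall back to Monte-Carlo (with a seeded,
  calibrated estimator), never the reverse.
- The EW Monte-Carlo fallback rejects on k and is slow when the matched
  θ makes the observed k improbable; for survey-sized samples the exact
  path always applies.
- The multiallelic D′ construction is an association device, not a
  full parameterization of multiallelic LD; truth for EM/ASH tests is
  always recorded as the haplotype matrix itself.
- Tajima's D p-values use a constant-size coalescent null; under real
  population growth the genome-wide D distribution shifts negative, so
  these p-values are conservative for detecting balancing selection in
  grown populations.
- The Z_ST empirical p-value inherits the background panel's resolution
  (1/678 at the study scale) and is undefined where the microsatellite
  F_ST vector has zero variance.
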