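# hlapop

Population-genetic analysis of HLA class I and II variation against a
genome-wide neutral-marker background.

## The problem

The HLA loci (class I: *HLA-A*, *-B*, *-C*; class II: *HLA-DRB1*) are the
most polymorphic genes in the human genome and are shaped by long-term
balancing selection. In populations with strong recent drift — such as
Native American populations founded through a chain of bottlenecks along
a colonization route — it is hard to tell how much of the observed HLA
variation reflects selection and how much simply reflects demographic
history. The standard way to disentangle the two is to compare HLA
variation with a panel of putatively neutral markers (genome-wide
microsatellites) typed in the *same* individuals: the neutral markers
document the demography, and systematic departures of HLA from that
background are candidate signatures of selection.

`hlapop` implements that comparison end to end, for anyone analysing
multiallelic immune-gene variation against a neutral panel:

- **Data model** — two-field HLA allele names (`B*39:06`, g-groups),
  genotype tables with per-locus sample sizes, reference
  allele-frequency panels, aligned allele sequences, microsatellite
  panels.
- **Diversity** — unbiased sample heterozygosity
  `H = n/(n-1) * (1 - Σ p_i²)`, allele counts, population- and
  individual-level HLA-vs-microsatellite comparisons, regional contrasts
  (ANOVA + Tukey HSD).
- **Hardy–Weinberg proportions** — the exact conditional test for
  multiallelic loci (exhaustive enumeration of genotype arrays where
  feasible, seeded gamete-permutation Monte-Carlo otherwise), with
  per-genotype standardized residuals.
- **Neutrality tests** — the Ewens–Watterson homozygosity test, with the
  null distribution of `F = Σ p_i²` computed *exactly* from the Ewens
  sampling distribution conditional on (n, k); and Tajima's
  `D = (π − S/a₁) / √(e₁S + e₂S(S−1))` on sequence-recoded samples, with
  a coalescent-simulation p-value (`Pr(D_sim ≥ D_obs)`, conditioned on
  the observed S).
- **Differentiation** — haplotype-level AMOVA pairwise F_ST (allele
  identity distance) and R_ST (squared allele-size distance), regional
  aggregation, and the empirical standardization
  `Z_ST = (F_ST^HLA − mean(F_ST^msat)) / SD(F_ST^msat)`
  with an empirical p-value = proportion of microsatellite loci with
  higher F_ST than HLA.
- **Allele geography** — classification of alleles as *endemic* (absent
  from a worldwide reference panel), *LFD* (large frequency difference:
  at least 3-fold more common in the Americas), or *other*, with
  poorly-supported (≤ 3 copies) flags and a two-dataset removal filter;
  per-population category sums and regional means.
- **Haplotypes** — gene-counting EM estimation of two-locus haplotype
  frequencies (monotone log-likelihood, restarts) and allele-specific
  heterozygosity `ASH(a) = 1 − Σ_b (h_ab/p_a)²`, summarized by allele
  category and frequency stratum.
- **Synthetic cohorts** — a serial-founder simulator (Wright–Fisher
  drift through a chain of bottlenecks, stepwise-mutating
  microsatellites, planted endemic/LFD alleles with recorded ground
  truth, clade-structured allele sequences, controlled two-locus LD) so
  the entire pipeline runs and is testable with no external data.

Everything is tidyverse-native: functions take data frames and return
tibbles, the EM fit has `tidy()`/`glance()`/`autoplot()` methods, and
`run_all()` orchestrates the full analysis from one (optionally YAML)
configuration.

## Worked example

Regional means of endemic and LFD allele frequencies, recomputed from
the bundled published per-population sums (the Aché population, an
extreme diversity outlier, is excluded from regional averages):

```r
library(hlapop)
library(dplyr)

sums    <- published_category_sums()
regions <- published_region_map()
means   <- region_category_means(sums, regions, exclude = "Ache")
filter(means, locus == "B")
#> # A tibble: 5 × 5
#>   region locus endemic_mean lfd_mean n_pops
#>   <chr>  <chr>        <dbl>    <dbl>  <int>
#> 1 All    B           0.0830    0.402     22
#> 2 MEA    B           0.0683    0.430      6
#> 3 NAM    B           0         0.106      3
#> 4 SAA    B           0.0665    0.39       4
#> 5 SAL    B           0.128     0.487      9
```

Endemic *HLA-B* alleles carry ~8% of the allele mass continent-wide and
~13% in the South American lowlands, while LFD alleles — present
elsewhere but at least 3-fold more common in the Americas — approach
half the allele pool outside North America.

An Ewens–Watterson test on a simulated neutral sample (n = 50
chromosomes; the exact conditional null given n and k is enumerated over
partitions):

```r
g <- sim_neutral_population(theta = 3, n = 50, seed = 7, locus = "B")
ewens_watterson(allele_frequencies(g)$count)
#> # A tibble: 1 × 6
#>       n     k F_obs F_exp p.value method
#>   <int> <int> <dbl> <dbl>   <dbl> <chr>
#> 1    50     7 0.521 0.325   0.940 enumeration
```

`F_obs > F_exp` with p = 0.94 points (non-significantly) toward
homozygosity excess; under the two-tailed convention, p < 0.025 would
indicate balancing selection and p > 0.975 directional selection.

A full synthetic cohort reproduces the qualitative signature that
motivates the method — per-population HLA heterozygosity tracks the
neutral microsatellite background almost perfectly, because both record
the same founder-chain demography:

```r
sim  <- sim_cohort(sim_params(seed = 42))
h    <- heterozygosity(allele_frequencies(sim$cohort))
hp   <- summarise(group_by(h, population), H = mean(H))
both <- inner_join(hp, msat_heterozygosity(sim$msat), by = "population")
population_level_correlation(both$H, both$H_msat)
#> # A tibble: 1 × 4
#>   estimate statistic  p.value     n
#>      <dbl>     <dbl>    <dbl> <int>
#> 1    0.963      16.7 5.45e-14    24
```

The one-call pipeline writes the full report bundle (heterozygosity,
HWP, both neutrality tests, classification, F_ST/Z_ST, ASH) as TSVs plus
a run log:

```r
run_all(list(simulate = TRUE, seed = 1), out_dir = "report")
```

## Package layout

- `R/` — implementation (data model and IO, simulator, diversity, HWP,
  neutrality, differentiation, classification, haplotypes/ASH, pipeline,
  plots)
- `inst/extdata/` — bundled published summary tables (plain text)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/hlapop-methods.Rmd` — the methods vignette: models,
  assumptions, parameter choices, numerical details, limitations
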