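---
title: "Measuring diversity and differentiation with highly variable markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring diversity and differentiation with highly variable markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jostdiv)
```

## The problem

Comparative population genetics of host–parasite systems (the motivating
case is a slavemaking ant and its two host species, genotyped at
microsatellite loci and a ~1.3 kb mtDNA fragment) asks two questions per
species: how much genetic diversity does each subpopulation hold, and how
strongly are subpopulations differentiated? With highly variable markers
both questions are distorted by the classical statistics.

**Diversity.** Heterozygosity `H` compresses differences at the top of its
range: a population going from 4 to 2 to 1 equally frequent alleles has
`H` = 0.75, 0.5, 0 — the first halving of diversity looks like a 33% drop,
the second like a 100% drop. The effective number of alleles

$$ n_e = \frac{1}{J} = \frac{1}{\sum_i p_i^2} $$

(the reciprocal of homozygosity) goes 4, 2, 1 and scales linearly with
diversity, so `jostdiv` uses `n_e` as the comparison currency
(`effective_alleles()`, `heterozygosity_equal_alleles()` documents the
worked example).

**Differentiation.** The classical ratio

$$ G_{ST} = \frac{H_T - H_S}{H_T} $$

is bounded above by `1 - H_S`: when within-population heterozygosity is
high, `G_ST` is near zero *no matter how differentiated the populations
are*. Jost's D,

$$ D = \frac{N}{N-1}\,\frac{H_T - H_S}{1 - H_S}
     = \frac{N}{N-1}\left(1 - \frac{n_{eS}}{n_{eT}}\right), $$

removes that ceiling; it depends only on the ratio of within- to
total-sample effective allele numbers. The two formulations are
algebraically identical (`jost_d()`, `jost_d_from_ne()`; the identity is
asserted to 1e-12 in the tests). The package reports both `D` and `G_ST`
everywhere, because their divergence *is* the scientific signal: on
island-model simulations with high mutation (mean `H_S` > 0.85) and
`Nm` = 0.5 the acceptance checks find mean `G_ST` < 0.1 while mean
`D` > 0.4.

## Estimators and their assumptions

`hs_ht()` computes `H_S` (mean within-population expected heterozygosity)
and `H_T` (total expected heterozygosity with allele frequencies averaged
*unweighted* across populations) in two modes:

* `"plain"` — the direct frequency formulas. Exact for the textbook
  examples and the only mode in which identities like "two populations
  fixed for distinct alleles give D = 1" hold without estimator noise.
* `"nei_chesser"` (default) — the Nei & Chesser small-sample corrections,
  using the harmonic mean sample size and (for diploid data) the observed
  heterozygosity. This is the mode for real-data-shaped analyses.

The unweighted average across populations follows the Nei–Chesser
convention; sample sizes enter only through the correction terms.

Numerical edge cases are handled explicitly rather than silently:

* `G_ST` with `H_T = 0` (no variation) is an `NA` marker, not an error.
* Corrected `H_S` reaches exactly 1 when every individual in every sample
  carries a unique allele — `D` is then 0/0. Such loci/windows are
  reported as missing with the note `"within-population diversity
  saturated"`. This happens routinely for long sequence windows at high
  mutation rates and mirrors the power collapse expected when almost
  every individual is unique.
* Small negative `D`/`G_ST` (estimator noise) are reported as computed,
  not clamped.
* A genotype is missing only as a whole two-allele pair; per-locus
  analyses drop missing individuals locus-wise. (The source study does not
  state its missing-data rule; locus-wise deletion is standard practice
  and is this package's choice.)
* In the precomputed permutation statistic (`make_d_gst_statistic()`),
  populations that a permutation leaves with no usable data at a locus
  (or a single individual in `nei_chesser` mode, where the correction is
  undefined) are dropped from that locus for that permutation.

## Sequence data

An alignment is treated as one haploid locus by collapsing identical
full-length sequences to haplotype alleles (`as_haplotype_dataset()`);
`N` and `-` count as ordinary, distinct characters for the identity rule —
a conservative, reproducible choice. Sites with `N`/`-` are excluded
pairwise only where sites are actually compared:

* `nucleotide_diversity()` — mean pairwise differences per *compared*
  site;
* `gamma_st()` — per-site `H_S`/`H_T` over character frequencies, averaged
  over **all** sites including monomorphic ones (the denominators stay per
  site, so a sequence with `N` at a site is excluded at that site only).
  Because a site has at most four states, per-site heterozygosity never
  saturates, which is exactly why `gamma_ST` incorporates genetic distance
  without the `G_ST` ceiling.

`fragment_length_analysis()` emulates having sequenced a shorter fragment:
windows of each length are drawn at uniformly random start positions
(contiguous, sampled with replacement — the replication scheme of the
original design is unstated, and with-replacement is the simplest
faithful reading of "a random location"), and power at a length is the
fraction of windows with permutation `p < alpha`.

## Significance testing

`permutation_test()` randomizes *individuals* over populations (sample
sizes preserved exactly, a full multilocus genotype moves as one unit —
the conservative unit when samples deviate from Hardy–Weinberg), and
evaluates every statistic on the same randomized datasets, so D and G_ST
p-values are directly comparable (identical for haploid data).

The p-value is `count(stat_perm >= stat_obs) / n_perm` and can be 0, as in
the source tables; an optional `(count+1)/(n_perm+1)` convention is
available behind `add_one = TRUE`, default off. `exact_permutation_pvalue()`
enumerates all assignments for up to 12 individuals and is the oracle the
Monte-Carlo path is tested against (the `{a,a} | {b,b}` toy has exact
p = 1/3).

`mantel_test()` (isolation by distance) correlates lower-triangle entries
and permutes row/column labels of the second matrix. Significance is
two-sided on `|r|`: negative and positive correlations are both findings
of interest, so sign-agnostic testing is required. Geographic distances
are WGS84 geodesics from decimal coordinates (`geographic_distances()`);
the original analysis used web software without stating its metric, so the
geodesic is this package's choice. Whether the original Mantel p-values
were one- or two-sided is likewise unstated; two-sided is the
conservative default here.

All stochastic analyses take one master seed; per-analysis child streams
are derived with `derive_seed()`, so adding an analysis never shifts the
random numbers of earlier ones.

## Other components

* **Null alleles.** `null_allele_proportion()` implements the Chakraborty
  heterozygote-deficit estimator `r = (H_e - H_o)/(H_e + H_o)`, floored at
  0 (whether the original analysis floored negative estimates is
  unstated; flooring is the conservative reading of "proportion").
  Averaged over populations it is an upper bound per locus, assuming the
  whole deficit is due to null alleles.
* **Expansion sign test.** The per-locus expansion statistic `k` is
  deliberately pluggable — its published formula is not reproduced here —
  and the package ships the aggregation: the count of negative values
  against Binomial(n, 1/2) with an exact two-sided p
  (`expansion_sign_test()`; 8/8 negative gives p = 0.0078125, printed
  0.008). Zeros count as non-negative, conservative toward the expansion
  hypothesis.
* **Trees.** `nj_tree()` delegates the agglomeration to `ape::nj` and
  post-processes negative branch lengths: the most negative edge is zeroed
  and its deficit moved to a sister branch (first sister in edge order as
  the deterministic tie-break), preserving path lengths.
* **Aggregation.** Across-locus summaries are unweighted arithmetic means
  of per-locus statistics (`multilocus_mean()`), not statistics recomputed
  from averaged heterozygosities — this reproduces the printed per-species
  means (0.25, 0.58) from the printed per-locus values. Whether those
  printed means were computed before or after rounding is unknowable; the
  package aggregates unrounded values and comparisons are made at two
  decimals. In `pairwise_d()` every pair uses `N = 2` by definition.

## The synthetic testbed

The study's raw genotypes are not deposited, so the pipeline is exercised
end-to-end on a forward-time Wright–Fisher finite-island simulator
(`simulate_microsats()`, `simulate_sequences()`): `K` demes of equal size,
migration at rate `m` with a uniformly chosen destination deme, stepwise
(±1 repeat, unbounded — size ceilings are out of scope) or
infinite-alleles mutation for microsatellites, and uniform base
substitution on `L` finite sites for sequences. A forward simulator was
chosen over a coalescent because it realizes the island-model assumptions
directly and is fast enough at desk scale (the hot loop is compiled;
`K <= 10`, `N_deme <= 500`). Sequences use `N_deme / 2` haploid copies per
deme, the standard 4-fold reduction of mitochondrial effective size
relative to nuclear markers in a two-sex diploid population (the factor is
hard-coded; sex is not modelled). Burn-in defaults to `10 * N_deme * K`
generations from a monomorphic start, which reaches
mutation–migration–drift quasi-equilibrium at these parameter ranges.

`make_paperlike_fixture()` presets three species-shaped bundles (6–8
demes, per-site sample sizes 10–50, 8 loci for the hosts, 6 for the
parasite whose two extra markers "fail to amplify", a 1305 bp alignment,
coordinates in a northeastern-North-America-like box). Per-locus mutation
rates are spread over 5e-4 to 1e-1 so the per-locus effective allele
numbers span roughly 2–22, the range of the motivating data.

`inject_null_alleles()` marks each allele copy unamplifiable independently
with probability `null_freq`: one null copy makes an apparent homozygote,
two make a missing genotype. Under Hardy–Weinberg proportions the
Chakraborty estimator is then exactly consistent for `null_freq` (the
algebra reduces `(H_e - H_o)/(H_e + H_o)` to `r`), and the acceptance
checks recover an injected rate of 0.2 within ±0.05 at 200 individuals.

What the simulator does *not* emulate: selection, recombination,
population-size change, unequal deme sizes or asymmetric migration,
genotyping artefacts other than null alleles, and allele-size homoplasy
constraints. Passing tests therefore demonstrate estimator correctness and
calibration under the island model, not robustness to every feature of
field data.

## Problem sizes and calibration conditions

The test suite and the acceptance script use desk-scale study conditions,
chosen once: type-I calibration uses 200 panmictic datasets (one deme of
60, 40 individuals sampled and split into four pseudo-demes, 3
infinite-alleles loci, 200 permutations each), and its rejection rate is
required to fall inside the exact binomial 99% envelope of alpha = 0.05.
The D-vs-G_ST contrast uses 10 replicates of `K = 6`, `N_deme = 100`,
`m = 0.005` (`Nm = 0.5`), `mu = 0.02` (infinite alleles), which puts mean
`H_S` ≈ 0.91 — inside the prescribed high-diversity regime. The
fragment-length scan uses `K = 4`, `N_deme = 50`, `m = 0.01`,
`mu = 3e-6`/site on 1305 bp — a regime with moderate haplotype sharing, so
short windows are often uninformative and power climbs with length; 20
windows per length and 200 permutations per window keep the scan fast
while leaving the trend unambiguous.

## Known limitations

* `H_T` computed from unweighted mean frequencies is permutation-invariant
  only when sample sizes are equal; with unequal samples the permutation
  null distribution of D absorbs a small amount of `H_T` variation.
* The Nei–Chesser haploid correction makes `D` undefined exactly at full
  haplotype saturation (see above); `"plain"` mode remains available when
  saturation is expected.
* The exact enumeration oracle is limited to 12 individuals by design;
  beyond that the Monte-Carlo path with a seed is the supported route.
* Mitochondrial inheritance is emulated only through the 4-fold size
  reduction; heteroplasmy and paternal leakage are ignored.
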