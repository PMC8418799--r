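---
title: "Screening microsatellite loci and testing isolation by distance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening microsatellite loci and testing isolation by distance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatIBD)
```

## The problem this package addresses

A microsatellite survey that finds no spatial-genetic structure is hard to
interpret: the blank can reflect genuine high connectivity, or it can be
manufactured by technical noise — non-amplifying (null) alleles that inflate
apparent homozygosity, size homoplasy that makes unrelated alleles look
identical, or a distance metric poorly matched to the signal present. The
workflow implemented here takes a genotype matrix (diploid allele sizes in
bp, individuals annotated with site, sex and coordinates) and systematically
separates these possibilities: it quantifies per-locus noise, builds
locus subsets with better signal-to-noise ratio, partitions by sex, and runs
a battery of isolation-by-distance (IBD) tests whose metrics lean on
different parts of the signal. A forward-time simulator generates data with
the same statistical structure, so the whole chain can be power-checked.

## Noise metrics

**Null alleles.** At a locus carrying a null allele at frequency $r$,
null/visible heterozygotes type as homozygotes and null/null individuals
drop out, producing a homozygote excess spread across *all* homozygote
classes (unlike, say, allelic dropout of large alleles). `detect_null()`
tests exactly that pattern: for each allele class the observed homozygote
count is compared with its distribution under Hardy–Weinberg proportions
(randomizations of the allele vector; 1,000 by default), and the one-sided
per-class p-values are combined with Fisher's method. When the combined test
is significant, the frequency is estimated with the Brookfield moment
estimator
$$\hat r = \frac{H_E - H_O}{1 + H_E},$$
floored at zero. This estimator assumes missing genotypes are technical
failures rather than null homozygotes — the right choice when missingness is
low and not locus-concentrated. Two caveats matter for interpretation: the
estimate is attenuated toward zero at larger $r$ when null/null individuals
are in fact excluded as missing (at $r = 0.25$ and $H_E \approx 0.9$ the
expectation is near 0.19), and it is an upper-bound-style signal, not an
unbiased measurement. The recovery tests therefore check that injected null
frequencies of 0.1 and 0.25 are recovered within ±0.08 on average at
$n = 200$, which the estimator meets.

Because inbreeding also produces homozygote excess — but across *many loci
at once* rather than locus by locus — populations are screened first:
`screen_inbred_pops()` drops any population in which at least 20 % of loci
(7 of 33 in the reference survey) show significantly positive $F_{IS}$ by a
one-sided U-test of heterozygote deficiency. Per locus, the burden over the
retained populations is summarised as $r_\mathrm{cumulative}$, the sum of
$\hat r$ over populations with a significant excess, which captures both
prevalence and severity in one number; loci are ranked worst (1st) to best,
ties sharing their block's first rank position.

**Homoplasy.** Slipped-strand mispairing rates rise with the number of
contiguous repeat units, so loci with long repeat tracts accumulate alleles
identical in state but not by descent. Only one allele per locus is ever
sequenced during marker development, so its repeat count is rescaled to the
median-sized allele of the pooled gene pool proportionally:
$$\text{median repeats} = \text{seq\_repeats} \times
  \frac{\text{median allele length}}{\text{seq allele length}}.$$
Proportional scaling (rather than differencing by motif length) is used
because it reproduces every value of the bundled reference survey's
annotation table to two decimals, including the half-integer medians that
arise from even allele-copy counts. Loci are ranked most-repeats-first.

## The omission stopping rule

On each noise axis, `iterative_omit()` removes the worst-ranked locus one at
a time and, after each removal, compares the full metric vector against the
reduced one with a one-tailed Welch $t$-test (unequal variances,
Welch–Satterthwaite df; direction "the reduced mean is lower"). The first
removal count with $p < 0.05$ stops the search. Welch rather than a
pooled-variance $t$ is used because only the Welch degrees of freedom
reproduce the reference survey's printed statistics (df ≈ 40 for the
33-vs-28 comparison, 42 for 33-vs-24). Two properties of this rule are worth
knowing:

* removing a *single* locus can never stop the rule — the mean shifts by at
  most about one standard error of the full sample, bounding $t$ near 1 — so
  stopping indices of 2+ are the norm;
* on the reference survey the null-allele axis stops at $k = 5$
  ($t = 1.720$, $p = 0.047$), while the repeat-count axis first reaches
  significance at $k = 6$ ($t = 1.819$, $p = 0.037$); the survey's published
  low-noise set was nonetheless built from five loci per axis, so
  `build_lnds()` exposes the omission counts (`n_omit_null`,
  `n_omit_homoplasy`) with the stopping indices as defaults, and the
  package's study-reconstruction tests pass five explicitly. With five per
  axis the two sets share one locus and the low-noise dataset keeps
  $33 - 9 = 24$ loci.

`build_lnds()` finishes by re-running both Welch comparisons on the final
set and applying a probability-of-identity guard: per-locus
$PI = 2(\sum_i p_i^2)^2 - \sum_i p_i^4$, compared full-vs-reduced with the
same one-tailed test, to confirm the discarded loci did not carry
disproportionate information content.

## High-signal retention

`per_locus_global_fst()` computes Weir–Cockerham $\theta$ per locus from the
two-level variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals, from observed
heterozygosity), summing components over alleles before taking the ratio
$\theta = \sum a / \sum(a+b+c)$. Loci are ranked descending with the gap to
the next rank ($\Delta F_{ST}$) reported. The retention threshold $k$ is
deliberately *not* automated: natural breaks in a rank-ordered $F_{ST}$
distribution are a judgement call, so `build_hsds()` takes $k$ as a
parameter and the $\Delta F_{ST}$ table is the evidence the user inspects.

## Distances and the Mantel battery

Population-based dissimilarities: the Cavalli-Sforza & Edwards chord
distance $D_c = \frac{2}{\pi L}\sum_l \sqrt{2(1-\sum_i \sqrt{x_{li}y_{li}})}$
(robust to null alleles, since it uses frequency geometry rather than
heterozygosity); Nei's standard distance with gene identities averaged over
loci before the log (the classic multi-locus form, chosen over per-locus
logs because fixed loci would otherwise contribute infinities); and pairwise
$\theta/(1-\theta)$, with negative $\theta$ floored at zero so Mantel inputs
stay finite and monotone.

Individual-based similarities: the kinship coefficient $D_{kf}$ is
implemented directly from its verbal definition — the probability that a
randomly drawn allele from one individual is identical in state to one from
the other, i.e. the mean of the four cross-individual identity indicators
per locus (method tag `dkf_iis`); $D_{ps}$ counts multiset-shared alleles
over $2\times$ loci compared (A/A vs A/B shares one); and the Lynch–Ritland
relatedness estimator uses reference (pooled) allele frequencies, weights
loci by the inverse-sampling-variance term
$w = \frac{(1+S_{ab})(p_a+p_b) - 4p_ap_b}{2p_ap_b}$, skips degenerate loci
(zero denominator), and averages the two directions since the estimator is
asymmetric in reference and proband. Pooled rather than per-site reference
frequencies are used because a shared rare allele should count as evidence
of kinship relative to the whole study's gene pool.

`mantel_ibd()` correlates off-diagonal entries, permutes one matrix's label
order (999 permutations by default, add-one smoothing), and tests one-tailed
in the direction IBD predicts — positive for dissimilarities, negative for
similarities. Geographic distances are plain Haversine great-circle
distances at the mean Earth radius 6371.0088 km; all members of a site share
the trap coordinate, so individual-level matrices contain legitimate zero
within-site distances (no jitter is applied). The OLS slope of genetic on
km is reported alongside $r$ because weak-but-significant IBD is the
expected regime: with tens of thousands of individual pairs, correlations of
0.02–0.04 are detectable at $p = 0.001$.

## The simulator: what it emulates and what it does not

`simulate_dataset()` runs a 1-D stepping-stone: demes of constant diploid
census on a constant-latitude line 150 km apart (so Haversine distances are
near-linear in deme index), non-overlapping generations, random monogamous
pairing within demes, multinomial offspring allocation to constant census,
strict stepwise mutation (±1 repeat, equal probability, reflecting at a
floor of 5 repeats), and sex-specific natal dispersal. Two design choices
are central:

* **Census timing.** Each cohort is born, mutates, then disperses; the final
  census is sampled *after* dispersal and *before* reproduction. Field
  samples from flight traps are exactly such individuals — dispersed but not
  yet reproduced — and this timing is what allows sex-biased dispersal to
  blur the dispersing sex's spatial signal while the philopatric sex retains
  it. Sampling before dispersal would make the sexes statistically
  exchangeable and the phenomenon unobservable.
* **Dispersal kernel.** A mover draws a shifted-geometric step count with
  mean `disp_steps_*` (default 1, i.e. strictly adjacent-deme migration).
  Values above 1 model occasional long-range, wind-assisted dispersal. This
  matters for the sex-bias experiment: a strictly adjacent move displaces an
  individual by one deme, which cannot erase a ten-deme gradient, so
  complete masking of the female signal requires the long-range kernel that
  the species' biology (pioneering females, above-canopy wind transport over
  tens of km) motivates.

**Default scenario.** The defaults were calibrated once to the weak
differentiation regime the workflow targets and then frozen: 9 demes,
census 400 per deme with a field sample of 28 (survey-sized samples are
samples, not demes), 33 loci, founder alleles drawn uniformly from 15–25
repeat units (standing variation: ~11 alleles per locus, $H_E \approx 0.89$),
stepwise mutation at $5\times10^{-4}$, both sexes dispersing at $m = 0.2$ to
adjacent demes, 100 generations. Under these conditions measured global
$F_{ST} \approx 0.011$. The sex-bias power experiment used in the test suite
overrides this with 10 demes, $m_\mathrm{female} = 0.5$ and a mean-5-step
female kernel, $m_\mathrm{male} = 0$; across 20 replicates the male-partition
Lynch–Ritland Mantel test is significant in a large majority while the
female partition stays near the nominal rate.

**Not modeled:** overlapping generations (the beetle completes up to nine a
year in the south), outbreak/irruption demography, selection, coalescent
shortcuts, within-deme spatial structure, genotyping error other than null
alleles, and allele-size constraints beyond a floor. Passing tests on
simulated data therefore demonstrate the statistical machinery under the
stated model, not robustness to all features of real trap samples —
in particular, real surveys' uneven sex ratios and collection years are not
emulated.

## Numerical choices and degenerate inputs

* Monte-Carlo p-values everywhere use add-one smoothing
  $(x+1)/(B+1)$, so the attainable floor is $1/(B+1)$ and p-values never
  reach 0. Exact-test sampling permutes the allele vector — an i.i.d. draw
  from the Levene conditional distribution — rather than a Markov chain;
  two-allele tables are enumerated exactly.
* Monomorphic loci: HWE and U-tests return $p = 1$ (with a warning for the
  exact test); $F_{IS}$ is `NA`; $PI = 1$; $\theta$ is `NA` and such loci
  rank last with a flag.
* Half-missing genotype calls are promoted to fully missing with a warning
  (the GenePop `000` convention knows only whole-genotype missingness);
  allele pairs are stored sorted, so no statistic depends on call order.
* Rank ties share their block's first position (`ties.method = "min"`),
  matching the reference survey's "equal 14th" convention; $F_{ST}$ rank
  ties break by unrounded $\theta$, then locus name, so ordering is
  deterministic.
* GenePop output uses the 3-digit dialect with raw bp sizes as codes
  (alleles ≤ 999 bp); larger alleles are refused with advice to recode. An
  optional sidecar TSV records the code→bp mapping.
* Seeds: every stochastic entry point takes a `seed` argument applied via a
  local RNG scope, so calls are reproducible without disturbing the
  caller's RNG state; the simulator consumes a single seed for all draws.

## Problem sizes used in the test suite

The suite exercises the full pipeline at reduced scale: the shared simulated
dataset uses 5 demes × 20 sampled individuals × 12 loci; the Mantel
size check runs 500 null simulations on 12 labels with 99 permutations;
estimator-recovery runs use single-locus datasets of 200 individuals; the
sex-bias experiment runs 20 replicates of the 10-deme scenario with 199
Mantel permutations per partition. These sizes give each stochastic check
comfortable margins (binomial or multiplicity-aware bounds are stated next
to each test) while keeping the default run short.

## Known limitations

The null-allele scan reconstructs the classic homozygote-excess procedure
from its published description (per-class randomization p-values, Fisher
combination; method tag `mc_like`); other implementations differ in how
they bin allele classes, so per-population significance calls near the
threshold can differ between tools. The Brookfield estimator's attenuation
at high $r$ is inherent to excluding null homozygotes as missing. The
$\Delta F_{ST}$ break choice is interactive by design. And the simulator's
stepping-stone geometry means geographic distance and deme index are
interchangeable — conclusions about irregular sampling geometries require
the user's own coordinates.
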