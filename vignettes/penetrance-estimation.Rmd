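---
title: "Family-based penetrance estimation with a two-locus EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based penetrance estimation with a two-locus EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedpen)
```

## The estimation problem

Rare loss-of-function variants in a risk gene (the motivating case is
*SORL1* in Alzheimer disease) are too rare for prospective cohorts to
estimate their age-related penetrance: a cohort holding a handful of carriers
yields no usable survival curve. Families ascertained through an affected
carrier proband are rich in carriers, but two obstacles follow:

1. **Ascertainment bias** — families enter the study *because* someone
   developed the disease early, so naive estimates overstate the risk.
2. **Missing genotypes** — most relatives are never sequenced; their carrier
   status must be inferred from the pedigree and from their phenotypes.

A further complication is that the main common risk factor, the *APOE*-ε4
allele, co-occurs with the rare variant and strongly modifies onset age, so
the two loci must be modelled jointly.

## Model

`pedpen` models the instantaneous risk (hazard) of disease at age $t$ for an
individual with APOE genotype $a$ and rare-variant status $s$ as

$$\lambda(t \mid a, s) \;=\; \lambda_{nc}(t \mid a)\,
  \exp\!\big(\beta(t)\, \mathbf{1}_{\{s = \text{carrier}\}}\big),$$

where

* $\lambda_{nc}(t \mid a)$ is a **non-carrier baseline**, piecewise constant
  on an age grid, with one stratum per APOE-ε4 dose (0, 1, 2 alleles). It is
  an *input*, typically derived from published cohort incidence, supplied as
  a CSV of hazards or cumulative incidences (`read_baseline()`,
  `baseline_from_incidence()`). The rationale for treating the population
  baseline as the non-carrier baseline is the extreme rarity of the variant.
* $\beta(t)$ is the **log hazard ratio of carriers**, piecewise constant on
  $J$ age intervals with cutoffs $\tau_1 < \dots < \tau_{J-1}$. It is shared
  across APOE strata (proportional hazards on the baseline of each stratum).

Penetrance is $F(t \mid a, s) = 1 - \exp(-\Lambda(t \mid a, s))$ with
$\Lambda$ the cumulative hazard; with three ε4 strata and two carrier states
the model yields six penetrance curves.

## Genotype space and the E-step

Genotypes are represented phase-ordered: an APOE ordered allele pair (3
alleles, 9 pairs) times an ordered variant pair (2 alleles, 4 pairs), i.e. 36
states. Phase ordering makes Mendelian transmission a uniform draw of one
allele per parent per locus, with the two loci unlinked (chromosomes 19 and
11). For reporting, states project onto the six effect classes (ε4 dose ×
carrier).

Missing genotypes are handled by an EM algorithm. The E-step computes, for
every individual, the exact posterior probability $w_i(a,s)$ of each of the
36 states given *all* evidence in the family: founder priors (Hardy–Weinberg
at each locus, linkage equilibrium across loci), transmission, observed
genotypes (a hard 0/1 compatibility mask), and phenotype likelihoods
$S(T_i)$ for a member censored at $T_i$ or $S(T_i)\lambda(T_i)$ for onset at
$T_i$. The computation is exact sum-product message passing on the pedigree's
nuclear-family factor graph — equivalent to Elston–Stewart peeling — with
per-message rescaling so that families whose evidence values are far below 1
do not underflow; the accumulated log constants give the family
log-likelihood. Pedigrees with marriage or inbreeding loops are rejected at
parse time: exact peeling on loop-free pedigrees matches the intended data,
and no approximate fallback is provided. An independent enumeration oracle
(`brute_force_marginals()`) exists purely so that the engine can be verified
against direct summation on small families; the test suite checks equality to
10⁻¹⁰ on a thousand random pedigrees.

## M-step and ascertainment correction

Given weights $w_i$, the maximizer of the expected complete log-likelihood
is closed-form per interval:

$$\hat\beta_j = \log \frac{\sum_i \mathbf{1}_{\{T_i \in [\tau_{j-1},
\tau_j)\}}\, \delta_i \sum_{(a,s)\,\text{carrier}} w_i(a,s)}
{\sum_i \sum_{(a,s)\,\text{carrier}} w_i(a,s)\,
\big[\Lambda_{nc}(\min(T_i,\tau_j) \mid a) - \Lambda_{nc}(\tau_{j-1} \mid a)\big]},$$

a posterior-weighted occurrence/exposure ratio. An interval with no carrier
events returns a flagged $-\infty$ sentinel ("no information"), not a number;
an interval with no carrier exposure is an error suggesting coarser cutoffs.

Ascertainment is corrected by omitting proband phenotypes. The default mode
removes the proband's phenotype from both the E-step evidence and the M-step
sums while keeping their *genotype* as hard evidence (it anchors which side
of the family carries the variant). This is the strongest reading of
"proband phenotypes omitted"; because the E-step usage is genuinely ambiguous
in the source methodology, an `mstep_only` mode (phenotype used as E-step
evidence only) and an uncorrected `include` mode are provided behind
`em_config(proband_mode = )`. Note that when the proband's two-locus genotype
is fully observed, their phenotype evidence cannot change any other member's
posterior, so `exclude` and `mstep_only` coincide in the common case.

Cutoff vectors are compared by $\mathrm{BIC} = -2\ell + J\log N$ with $N$ the
number of phenotype-contributing (informative, non-proband) members — the
units entering the M-step. This convention for $N$ is a package choice (the
source convention is not published) and is deliberately explicit in
`select_cutoffs_bic()`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_age` | 40 years | informativeness floor; onset/censoring below it contributes structure only (the baseline is undefined there) |
| `cap_age` | 85 years | censoring cap; older members (and later onsets) are censored at the cap |
| `apoe_freqs` | (0.08, 0.78, 0.14) | founder ε2/ε3/ε4 frequencies — field-typical European values, **not** estimated from any dataset; configurable |
| `sorl1_freq` | 1e-4 | founder variant allele frequency; posteriors of ungenotyped relatives are sensitive to it, so report it alongside results |
| `tolerance` | 1e-6 | EM stop on max $|\Delta\beta_j|$ |
| `max_iterations` | 500 | EM cap; non-convergence is a warning flag, not an error |

Age conventions: intervals are half-open $[\tau_{j-1}, \tau_j)$; an event at
a cutoff belongs to the right interval; ages are real-valued years.
β initialises at 0 (neutral); because the M-step is a global closed form
given posteriors, initialisation only affects the E-step path, and the
observed-data log-likelihood is nondecreasing by construction.

## Uncertainty

`bootstrap_ci()` resamples families with replacement (to the original family
count), refits with the cutoffs held fixed, and reports 2.5/97.5 percentiles
of every $\beta_j$ and of the penetrance at requested ages, for all six
classes. Holding cutoffs fixed matches the single selected cutoff set being
reported; per-replicate reselection would mix model-selection noise into the
intervals and is deliberately not done. Baseline uncertainty can be
propagated by perturbing each log-hazard piece with an independent normal
draw of user-supplied standard error; without standard errors the option is
forced off with a warning rather than inventing a scale. When every member
entering the M-step is fully genotyped, posteriors are data-determined and
each replicate reduces *exactly* to recombining per-family event/exposure
sums, which makes large bootstrap runs cheap; the general path refits the EM.

## What the simulator emulates — and what it does not

`simulate_families()` generates three-generation families: two grandparental
couples, the two parental sibships, and the proband's sibship, with sibship
sizes truncated-Poisson (mean 3, minimum 1) — matching clinic families with a
median of about 11 informative members over 3 generations. Genotypes are
gene-dropped from Hardy–Weinberg founders after seeding one heterozygous
carrier grandparent on a uniformly chosen parental side (an importance device
making carrier families reachable at a realistic variant frequency; inference
never uses the seeding distribution). Onsets are drawn by inverse-transform
sampling of the piecewise-exponential onset law; censoring ages are uniform
on [45, 85] (the empirical censoring-age distribution of the source families
is not published; uniform over the adult support is a neutral choice).

Ascertainment is **single**: one member of the youngest generation is drawn
at random and the family enters only if that member is an affected carrier
with onset at or below the recruitment limit; that member is the proband.
Under single ascertainment, removing the proband's phenotype from the
likelihood is an exact correction, which is precisely the regime in which the
proband-exclusion strategy is justified. (Choosing the proband among all
qualifying members instead would emulate complete ascertainment, under which
exclusion over-corrects — an instructive failure mode, but not the recruitment
design being emulated.) The `baseline_mimic` scenario uses a recruitment
onset limit of 75 years, the later clinical criterion, consistent with
observed proband onsets up to age 70.

The default synthetic baseline (`synthetic_baseline()`, also shipped as
`inst/extdata/baseline_synthetic.csv`) is Gompertz-shaped — log-hazard slope
0.17/year, hazards at age 60 of 1e-4, 3e-4 and 8e-4 per year for ε4 dose
0/1/2 — giving non-carrier cumulative incidence by 85 of about 4%, 11% and
27%, in the range of published ε4-stratified Alzheimer risks and calibrated
once so that simulated carrier onset ages populate all four default effect
intervals the way clinic-family data do. It is labelled synthetic everywhere:
it is **not** a cohort-derived table, and headline numbers obtained with it
are properties of the simulation design, not of any real population.

Missingness patterns: `baseline_mimic` observes genotypes for ~15% of
relatives (both loci together, as Sanger confirmation would) and removes ~10%
of relative phenotypes; `genotypes_all_missing` hides every relative's
genotype; `unbalanced_phenotype` blanks the phenotypes of the unaffected
parent's branch when exactly one parent is affected; `heterogeneous` adds a
per-family normal shift (sd 1) to all β values.

What the simulator does *not* emulate: the exact structures of any real
families, non-uniform censoring, genotyping error, de-novo variants, age
dependent genotyping availability, competing mortality, or linkage between
the loci. Passing simulation tests therefore demonstrates correctness of the
estimator under the stated generative model — not robustness to every feature
of real clinic data.

## Numerical and design choices

* Cumulative hazards are exact rectangle sums on a refined grid merging
  baseline breaks and β cutoffs; no quadrature error anywhere.
* Message normalization constants are accumulated on the log scale; the
  log-likelihood is exact, not a proxy.
* Contradictory evidence (an observation compatible with no state, or a
  family whose total evidence is zero) raises an error naming the family
  rather than returning NaNs.
* Problem sizes in the test suite (200-family recovery with 50 replicates,
  27-family bias study with 50 replicates, 30×200 bootstrap coverage) were
  chosen as the smallest designs at which the Monte-Carlo error is clearly
  below the assertion margins.
* BIC ties break toward fewer intervals, then lexicographically smaller
  cutoffs.
* Case-control carriers older than the support cap are censored at the cap
  (the alternative — truncation or exclusion — is not distinguishable from
  the source description; censoring is conservative).

## Known limitations

* No competing-risk mortality: penetrance is interpreted as risk in the
  absence of death from other causes and will overstate lifetime risk at old
  ages.
* Heterogeneous variant effects are *simulated* but not *fitted* (no frailty
  term); under heterogeneity the homogeneous-effect estimate overstates the
  average effect, which is why analyses should restrict to variant sets with
  homogeneous functional impact.
* Loop-free pedigrees only; no X-linked loci; no genotyping-error model.
* The β estimate below age 60 rests on sparse events and on a baseline
  segment where cohort data are weakest; treat the left end of the curves
  with caution.

## A worked run

```{r, eval = FALSE}
baseline <- read_baseline(system.file("extdata", "baseline_synthetic.csv",
                                      package = "pedpen"))
set.seed(1)
sim <- simulate_families(sim_scenario("baseline_mimic", n_families = 27,
                                      baseline = baseline))
fit <- fit_penetrance(sim$peds, baseline, cutoffs = c(60, 65, 70))
fit
penetrance_table(fit, c(65, 70, 75, 80, 85))
bootstrap_ci(fit, n_iterations = 100, seed = 2)
```
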