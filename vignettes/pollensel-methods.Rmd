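---
title: "Measuring pollinator-mediated selection from single-pollen genotypes"
author: "pollensel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pollinator-mediated selection from single-pollen genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Floral traits -- colour, scent, morphology -- are thought to evolve under
selection exerted by pollinators, but measuring that selection requires both
fitness components of a hermaphroditic flower: pollen *received* (maternal
success) and pollen *donated* to other plants (paternal success). Genotyping
individual pollen grains on stigmas makes both measurable within a single
pollinator visit sequence: each grain on a stigma can be traced to the plant
that donated it.

`pollensel` implements the full analysis chain for a mixed-array experiment
of this kind, modelled on a daylily/nightlily system: an array of 24
butterfly-syndrome parental plants (*Hemerocallis fulva*-like: reddish,
unscented, diurnal) plus 12 F2 hybrids with a nocturnal, yellowish, scented
species, arranged in a 6x6 grid. F2 hybrids segregate for tepal colour
(colour-chart score 3--23), scent intensity, corolla direction, stem height
and anther--stigma distance (ASD), providing the phenotypic variation that
selection is measured on. The unit of replication is the *trip bout*: one
pollinator's foraging sequence from arrival at the array to departure.
Stigmas are collected after every bout and all plants visited during the
bout are replaced with fresh-stigma spares, so pollen never accumulates
across bouts.

The package has five analysis stages -- simulation, grain QC, paternity,
success tallies, Bayesian selection inference -- wired together by
`run_pipeline()`. Each stage is usable on its own, and user data can enter
through `read_experiment()` in place of the simulator.

## The synthetic experiment generator

No raw data from the original experiment were ever deposited, so the
generator is a first-class component: it produces complete experiments with
known ground truth, which is what every downstream guarantee is tested
against.

* **Plants.** Parental plants draw traits from tight distributions around
  the butterfly-syndrome phenotype; F2 traits come from wide segregation
  distributions truncated to realistic ranges (tepal colour truncated to
  the full 3--23 chart range, mean ~12). Genotypes use a 10-locus
  microsatellite panel with 4--8 alleles per locus; the two parental
  species carry disjoint allele pools, and each F2 locus is an independent
  draw of two gametes through an F1 pair, giving exact Mendelian ratios.
* **Visits.** A bout's length is Poisson (mean 9, minimum 1); each visit is
  a softmax draw over open flowers with log-weight
  $\sum_k b_k x_k + g_k x_k^2$ on standardized traits. This mirrors the
  inference model's linear+quadratic form on purpose: the generator is the
  null and alternative hypothesis machine for the inference tests. Flowers
  accept at most two visits per bout, matching the observed 0--2 visit
  counts.
* **Pollen transport.** The pollinator carries pollen cohorts; at each
  visit it deposits a binomial fraction $d$ of every carried cohort, adds
  self pollen (fraction $s$ of a pickup), and picks up $P$ grains from the
  current flower. Carryover is therefore geometric -- the simplest model
  that produces multi-step transfer, which is observed in real arrays.
  Defaults ($P = 30$, $d = 0.07$, $s = 0.5$) were chosen once so that
  roughly 35% of deposited grains are outcross and the rest self, the
  proportions seen in the motivating experiment; they were not revisited
  afterwards.
* **Genotyping noise.** Each grain is a haploid gamete of its donor; a
  typing error replaces an allele with a random panel allele (1% default);
  allelic dropout masks loci (10% butterfly preset, 25% hawkmoth -- those
  samples amplify less well); contamination merges a grain's observation
  with another grain from the same stigma, producing the 2--3-allele loci
  that flag multi-grain PCR wells.

What the generator does **not** emulate: spatial flight paths and
distance-dependent movement, nectar depletion and pollinator learning,
within-day flower senescence, and linkage between trait loci and marker
loci (traits and genotypes segregate independently). Passing tests
therefore demonstrate that the analysis machinery is correct under the
stated transport and noise models, not that those models capture every
property of real arrays.

## Grain-level quality control

Three rules, applied in this order by `filter_grains()`:

1. **Stigma cap.** When a stigma carries more than 72 grains
   (about twice the number of array plants), exactly 72 are kept by uniform
   subsampling; smaller loads are analysed completely.
2. **Contamination.** Any record with two or more alleles at any locus is
   discarded whole -- a haploid grain cannot show two alleles, so the well
   contained multiple grains.
3. **Typed-locus thresholds.** Butterfly-bout grains need >= 7 typed loci,
   hawkmoth-bout grains >= 5 (their PCR efficiency is lower). The
   "more than seven" phrasing of the motivating protocol is read
   inclusively (>= 7); both readings are configurable.

Discarded grains stay visible in the QC report but never enter the success
tallies.

## Paternity of a haploid grain

A grain is **self** if at every locus typed in both grain and mother its
allele occurs in the maternal genotype. The species are self-incompatible,
so self grains are dead ends for siring but still occupy the stigma; they
terminate the pipeline with category `self`. A grain with no comparable
locus is self by this rule and flagged via the comparable-locus count.

Outcross grains are assigned among **candidate donors**: the distinct
genets of flowers visited *strictly before* the grain's deposition visit in
the same bout (the first visit to the stigma flower, unless a deposition
visit index is supplied). Candidates failing simple exclusion -- a locus
typed in both where the candidate carries no copy of the grain's allele --
are dropped (zero mismatch tolerance by default). Surviving candidates are
scored by a LOD adapted to haploid offspring:

$$\mathrm{LOD} = \sum_{\ell} \ln \frac{(1-e)\,T(a_\ell \mid G_\ell) + e\,p_{a_\ell}}{p_{a_\ell}}$$

where $T$ is the gamete transmission probability (1 for a homozygote
carrying the allele, 0.5 for a heterozygote, 0 otherwise), $p_a$ the
population allele frequency estimated by copy counting over the array
plants, and $e$ the typing-error rate. The error mixture $(1-e)T + e\,p_a$
keeps the score finite under mismatches at $e > 0$ and is the one deliberate
simplification relative to the classical parentage likelihood, chosen so
every per-locus term is hand-checkable; it is isolated in `lod_score()`.

Confidence comes from the $\Delta$ statistic (LOD of the most likely minus
the second most likely candidate; the sole candidate's LOD when there is
only one). `calibrate_delta()` reproduces the classical Monte-Carlo
calibration: 10,000 cycles by default, 473 candidate parents, 90% of
candidates sampled, 1% typing error; thresholds are the smallest $\Delta^*$
whose exceeders are correct at the 80% (relaxed) and 95% (strict) level.
The 473 reflects all plant individuals used across the experiment's days,
not the 36 positions of the array, and is configurable.

## Pollination success and the combined statistic

Per flower per bout, four indicators: `visits` (attraction), `X` outcross
grains acquired (maternal success), `Y` grains donated to other stigmas in
the same bout (paternal success), and the combined success

$$W = X + Y \cdot \frac{\overline{X}}{\overline{Y}},$$

with the ratio computed per pollinator across all records, or set to 1
("no competition": every deposited outcross grain could sire an ovule). By
default `X` counts *all* outcross grains including donor-unassigned ones
(they are outcross pollen acquired regardless of whether the donor is
identifiable), while `Y` requires an assigned donor; an `assigned_only`
mode for `X` is available. The identity
$\overline{W} = 2\overline{X}$ in observed-ratio mode is used as a test
oracle.

## The Bayesian selection models

For each pollinator, four Poisson log-link models with crossed random
intercepts:

* **attraction** -- visits per flower per bout, all available flowers;
* **acquisition** and **donation** -- efficiency per visit: visited
  flowers only, with the visit count as an extra fixed effect;
* **combined** -- $W$, all available flowers.

$$y_i \sim \mathrm{Poisson}(\lambda_i), \quad
\log \lambda_i = \alpha + \sum_k \beta_k x_{ki} + \gamma_k x_{ki}^2
  \;[+ \beta_6 v_i] + r_{\mathrm{bout}(i)} + rp_{\mathrm{genet}(i)}$$

Traits are standardized to mean 0, SD 1 on the analysed subset; squares are
taken after standardization. Non-visit responses are scaled to SD 1 (then
rounded to the nearest nonnegative integer so the Poisson likelihood
remains valid -- the scaling is part of the procedure being reproduced, and
an unscaled-count mode is available via `scale_response = FALSE`). Random
intercepts for trip bout and genet are Gaussian with SDs
$\tau \sim \mathrm{Uniform}(0, 10^4)$; fixed effects get vague Gaussian
priors (SD 100).

**Sampling.** The posterior is sampled with JAGS. These designs are
strongly collinear -- two-thirds of the rows belong to near-identical
parental plants, so each squared column is nearly an affine function of its
linear column -- and the raw parameterization mixes poorly under any of
JAGS's samplers. `fit_selection_model()` therefore rescales the
fixed-effect block by the inverse Cholesky factor of its Poisson-weighted
cross-product (weights from a maximum-likelihood fit without random
effects), places the vague priors on the rescaled coefficients, and maps
every draw back to the trait scale. The likelihood is untouched and the
implied prior is still essentially flat over the identified region; the
gain is that univariate slice updates traverse the posterior efficiently.
The posterior mean of every coefficient agrees with the collapsed
maximum-likelihood fit within Monte-Carlo error when the random-effect
variances are driven to zero (tested), which pins down the correctness of
the transform.

The reference schedule is 3 chains, 10,000 burn-in, 3000 draws per chain at
thinning 20. The package default (`reduced_schedule()`: 2500 burn-in, 1250
draws at thinning 4) is sufficient for interactive use; the convergence
check in the test-suite and acceptance script uses 3 chains with 3000
burn-in and thinning 8--16, which holds the split-chain $\hat R$ of every
parameter below 1.1 across seeds. The slowest-mixing parameters are
consistently the hierarchical SDs $\tau$ with their uniform priors, not the
selection gradients.

Convergence is judged by split-chain $\hat R < 1.1$ for every parameter
(`compute_rhat()`; each chain is halved, and between/within-half variances
are pooled).

## Classifying selection

For each trait: the 95% central credible interval classifies $\beta$ and
$\gamma$ as negative / none / positive (median sign as tie-guard). When
$\gamma$ is classified, the fitness optimum $z^* = -\beta/(2\gamma)$ is
estimated -- the point from the posterior-*mean* coefficients (so published
coefficient means reproduce published optima exactly), the interval from
the 2.5/97.5% quantiles of the per-draw ratio $-\beta^{(s)}/(2\gamma^{(s)})$.
The ratio distribution is heavy-tailed, so the point estimate is not forced
inside the interval; a flag records containment instead. Modes follow the
published decision rules:

* $\gamma$ negative and the $z^*$ interval inside the standardized
  phenotypic range: **stabilizing**;
* $\gamma$ positive, interval inside the range: **disruptive**;
* $\gamma$ classified but the interval exceeds the range:
  **stabilizing-or-directional**, direction from the sign of $\beta$'s
  posterior median (even when $\beta$'s own interval spans zero -- the
  quadratic is the evidence, the linear sign only orients it);
* only $\beta$ classified: **directional**;
* neither: none.

No multiplicity correction is applied (none was applied in the analysis
being reproduced); forty intervals are examined per full experiment, so a
couple of spurious classifications per null run are expected and observed.

## Numerical and design choices

* Allele codes are positive integers (fragment sizes); frequency tables are
  plain copy counts over the array plants, which *are* the candidate
  population.
* Flowers are identified as genet x bout instances (plants are replaced
  between bouts); the genet is the selection unit and random-effect key.
* Ties in $\Delta$ resolve to 0 (never assigned); a sole candidate's
  $\Delta$ is its LOD, matching the calibration's handling.
* Degenerate inputs fail loudly: zero-variance traits, loci typed in no
  plant, alleles missing from a frequency table, non-integer responses.
* Confidence levels can be genuinely unreachable in weak-information
  settings (few loci, many candidates); the threshold is then $+\infty$
  with a warning, and no grain reaches that confidence.
* Test problem sizes: the simulated acceptance dataset uses the default
  array (36 plants, 8 butterfly bouts, ~290 flower-bout rows); coverage is
  checked over 50 replicate fits of a 2-trait design at short chain
  lengths, pooling coefficients for the binomial check.

## Limitations

Selection is measured through pollination success only -- no fertilization,
seed set or offspring fitness. Candidate donors are restricted to flowers
visited earlier in the same bout, which is exact under the experimental
replacement protocol but would undercount carryover across bouts in designs
without replacement. The LOD error model is the mixture simplification
described above. And the simulator's preference model shares its functional
form with the inference model; recovery results say nothing about model
misspecification on real data.
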