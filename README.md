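# pollensel

Pollinator-mediated selection on floral traits, measured by genotyping
individual pollen grains on stigmas.

In a mixed experimental array (24 butterfly-syndrome parental daylilies +
12 F2 hybrids segregating for tepal colour, scent, corolla direction, stem
height and anther–stigma distance), every pollinator *trip bout* leaves a
record: which flowers were visited, and which pollen grains ended up on
which stigma. Genotyping single grains at 10 microsatellite loci turns that
record into both fitness components of a flower —

* **X**, outcross pollen grains acquired (maternal success),
* **Y**, pollen grains donated to other plants (paternal success),

plus visits (attraction) and the combined success
**W = X + Y · (Ave.X / Ave.Y)**.

`pollensel` implements the whole chain as composable stages:

1. **Synthetic experiments** (`simulate_experiment`) — array plants with
   segregating traits and Mendelian genotypes, preference-driven visit
   sequences, geometric pollen carryover, self deposition, and single-pollen
   genotyping noise (dropout, typing error, multi-grain contamination), with
   ground truth for every deposited grain.
2. **Grain QC** (`filter_grains`) — 72-grain stigma cap, exclusion of
   multi-allele (contaminated) records, ≥7 / ≥5 typed-locus thresholds for
   butterfly / hawkmoth samples.
3. **Paternity** (`assign_paternity`) — self vs outcross against the
   maternal genotype; candidates restricted to flowers visited earlier in
   the bout; simple exclusion plus a haploid-adapted LOD,
   `ln[((1−e)·T + e·p)/p]` summed over loci; confidence from the Δ statistic
   with thresholds calibrated by Monte-Carlo simulation
   (`calibrate_delta`, 10,000 cycles, 473 candidates, 80%/95% levels).
4. **Success tallies** (`tally_success`, `combined_success`).
5. **Selection inference** (`fit_selection_model`) — hierarchical Bayesian
   Poisson models with crossed random intercepts (trip bout, genet), linear
   (β) and quadratic (γ) gradients on standardized traits, τ ~ U(0, 10⁴)
   hyperpriors, sampled via JAGS; split-chain R̂ convergence checks
   (`compute_rhat`); optimum estimation **z\* = −β/(2γ)** and classification
   into directional / stabilizing / disruptive selection
   (`classify_selection`, `summarize_selection`).

`run_pipeline()` wires the stages together with one master seed and writes
every stage output as TSV.

## Worked example

```r
library(pollensel)

run <- run_pipeline(seed = 11,
                    calib = calibration_config(cycles = 1000),
                    schedule = reduced_schedule())
print(run)
```

```
Pollination selection analysis
==============================
Grains: 1836 raw, 1731 kept after QC (0 capped, 90 multi-allele, 15 under-typed)
Assignment: assigned_relaxed=13, assigned_strict=492, self=1082, unassigned=144
Success ratio Ave.X/Ave.Y (butterfly): 1.285
Convergence: max R-hat 1.063 (all parameters < 1.1)

Selection modes (trait x measure):
 pollinator             trait                                  visits acquisition donation                                combined
  butterfly       tepal_color                                      ns          ns       ns                                      ns
  butterfly   scent_intensity stabilizing_or_directional (decreasing)          ns       ns stabilizing_or_directional (decreasing)
  butterfly corolla_direction                                      ns          ns       ns                                      ns
  butterfly       stem_height                                      ns          ns       ns                             stabilizing
  butterfly               asd                                      ns          ns       ns                                      ns
```

Reading this: of ~1800 simulated grains, QC removed contaminated and
under-typed records; 505 outcross grains were assigned a donor at the
calibrated 80%/95% confidence levels and 1082 were self pollen. The fitted
models recovered the selection programmed into the generator's butterfly
preference — a negative quadratic on scent whose optimum interval spills
past the phenotypic range (hence "stabilizing or directional towards
weaker scent") and stabilizing selection on stem height in the combined
measure — and, correctly, no signal on the neutral traits; every parameter
converged (R̂ < 1.1).

Individual stages work standalone, e.g. an optimum from posterior means:

```r
estimate_optimum(-1.665, -3.842)
#> Fitness maximum at z* = -0.217
```

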