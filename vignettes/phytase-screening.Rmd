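---
title: "Models and methods behind the phytase screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the phytase screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytscreen)
```

This vignette is the package's own account of the science it implements: the
stereochemical bookkeeping, the kinetic model, the chromatographic forward and
inverse models, the classification rules, and the synthetic scenarios — with
the assumptions, defaults and numerical choices a user should know before
trusting an inference.

## 1. Stereochemistry: what the column can and cannot distinguish

A phosphorylation state of the *myo*-inositol ring is a subset of the carbons
{1,...,6} bearing phosphate: 64 species from InsP6 (phytate) down to free
inositol. The ring has a mirror plane through carbons 2 and 5, so the map
σ: 1↔3, 4↔6 (2, 5 fixed) sends every species to its enantiomer.
Anion-exchange chromatography cannot separate enantiomers: two species
co-elute exactly when one is the σ-image of the other. The package therefore
works with σ-orbits ("chromatographic classes"): species fixed by σ are
*meso* (no enantiomer), orbits of size two are d/l pairs. At the InsP5 level
this gives the familiar quartet — the meso isomers InsP5 [2-OH] and
InsP5 [5-OH] and the pairs InsP5 [1/3-OH] and InsP5 [4/6-OH] — which is the
entire basis of positional classification: a method that resolves these four
classes can tell a 3-phytase from a 4/6-phytase from a 5-phytase, but can
never tell d-3 from l-3 (i.e. 1d-3 from 1d-1) attack. Orbit counts per level
6..0 are 1/4/9/12/9/4/1, 40 in total, which equals the Burnside average
(64 fixed-free + 16 σ-fixed)/2 and is verified exhaustively in the tests.

Naming: InsP5 classes are named by their free hydroxyl ("InsP5 [4/6-OH]");
every other orbit is named `Ins(p1,p2,...)Pn` by the member with the
lexicographically smallest locant sequence, with a `d/l-` prefix for pairs.
So the orbit {Ins(2,3,4,5)P4, Ins(1,2,5,6)P4} is canonically
`d/l-Ins(1,2,5,6)P4`; users coming from the chromatography literature should
read class listings through `enumerate_classes()`, which records both members.

By default the profile universe lumps levels 3 and below into single classes
(`InsP3`, `InsP2`): the gradient resolves only one InsP3 region, and InsP1
co-elutes with inorganic phosphate, so those two are pooled into one
`Pi/InsP1` class. Free inositol carries no phosphate, gives no detector
response, and is excluded from chromatographic profiles (it is still tracked
by the simulator). Lumping is a flag; the full 40-orbit enumeration remains
available.

## 2. Kinetics: a linear master equation over the degradation DAG

Dephosphorylation is modelled as sequential single-phosphate removals on the
64-node DAG (192 edges, each labelled by the removed position). An enzyme is
a weight vector w over positions and a first-order rate constant k (per day):
removal of position p from species S proceeds at rate k·w(p), independent of
which other positions are occupied. This memoryless, distributive model is
the minimal one that generates positional pathway biases; it assumes
substrate well below Km (no saturation) and no processivity. A hook for
species-conditional weights exists internally but no preset uses it — nothing
in the screen's readout constrains processivity.

Communities add: mixing weights over enzymes; first-order sorption of InsP6
(and only InsP6, the most strongly bound species) to an inert pool;
first-order scavenging of free Pi; and a logistic activation
a(t) = 1/(1 + exp(−(t − t_lag)/τ)) scaling all enzymatic rates, representing
the growth lag of the degrading cohort. Defaults: no lag (t_lag = 0),
τ = 0.25 day where a lag is used. Each removal event releases one Pi into the
free pool, so the simulator tracks species abundances, the Pi pool, the
sorbed pool, and cumulative scavenged Pi; inositol and phosphate totals are
conserved exactly (property-tested at 1e-6 relative over random communities).

Integration: the system is linear, so the time-homogeneous case (no lag) is
propagated exactly with the matrix exponential; with a lag the generator is
time-dependent and a fixed-step classical Runge–Kutta integrator is used
(default step 0.001 day; the scenario tests use 0.005 day, which is already
at machine-precision agreement for these rate scales because linear invariants
are preserved exactly by Runge–Kutta schemes and the stiffest preset rate is
~10/day). Abundances are ensemble concentrations; nothing in the kinetics is
stochastic — randomness enters only through the chromatographic noise model.

The *pathway flux* of an enzyme — the probability a degrading molecule visits
a given intermediate — is computed by dynamic programming: flux 1 at InsP6,
split at each species proportionally to the positive weights of its remaining
positions. Species whose remaining positions all have zero weight are
terminal and retain their flux (β-propeller phytases, for instance, typically
stall at lower levels). The simulator's cumulative throughput per species
converges to this DP distribution as t → ∞, and the tests assert agreement to
1e-4 — a genuine two-route consistency check, since the DP never touches the
ODE code.

## 3. Chromatograms: forward model and recovery pipeline

**Forward.** A class profile renders as a sum of Gaussians: class c with
amount A contributes A·r_c·N(t; rt_c, σ_c), so peak area equals amount times
response. The default response model is equal molar response for every class
(the detection chemistry is not part of the model, and the screen's
percentage statements are mole-fraction statements); a per-phosphate
proportional model is available. Baseline is flat; noise is seeded white
Gaussian.

**Retention table.** Defaults (min): Pi/InsP1 2.8 (solvent front), InsP2 8.0,
InsP3 14.0, the seven InsP4 standards at 18.0–24.0 in ladder order, InsP5
classes at 27.0 (2-OH), 28.0 (1/3-OH), 29.5 (4/6-OH), 31.0 (5-OH), InsP6 at
37.0; σ = 0.25 min everywhere. Only 2.8, 28 and 37 are anchored to published
chromatography of this gradient family; the rest are invented, monotone with
phosphate number, and flagged as such in the table. Two InsP4 orbits —
Ins(1,2,3,5)P4 and Ins(1,3,4,6)P4 — do not appear in the acid-reflux
standards ladder; whether they fail to form or co-elute is unknown, so the
default table omits them and `retention_table(include_extra_insp4 = TRUE)`
adds configurable slots at 25.0 and 26.0 min (uniform 1-min spacing, keeping
every pair of classes baseline-resolved at σ = 0.25). Simulated experiments
render with the extended table because promiscuous (MINPP-type) communities
do populate those orbits and the forward model must place every species
somewhere. The elution order of InsP5 [2-OH] vs [1/3-OH] is likewise
unanchored; the default puts 2-OH first.

**Inverse.** Peak detection smooths with a 5-point moving average, estimates
the baseline as the median of the smoothed trace and the noise SD as
mad(diff(signal))/√2, and keeps local maxima that clear both a height
threshold (5 × noise SD above baseline) and a *topographic prominence*
threshold (the larger of 5 × noise SD and 0.5% of the tallest peak's height).
Prominence — height above the higher of the two saddles towards taller
terrain — is what rejects noise bumps riding on the flanks of real peaks,
which a pure height test cannot do. Apexes are refined by parabolic
interpolation; peaks closer than 0.3 min merge, keeping the taller. Areas are
trapezoidal over apex ± 3σ of the assigned class, bounded by the valleys
towards neighbouring peaks; assignment takes the nearest retention entry
within 0.35 min (safely under half the minimum 1.0-min inter-class gap), at
most one peak per class (tallest wins), and unassigned peaks are always
reported, never dropped. The ±3σ window clips 0.27% of a Gaussian's area
symmetrically in every class, so mole-fraction normalization cancels the
truncation; the round-trip suite verifies recovery within 1% noise-free and
5% with noise at a signal-to-noise ratio of 20 over 50 seeds.

## 4. The classifier

Thresholds (all exposed via `classifier_params()`; the qualitative logic is
standard, the numeric gates are this package's operationalization):

| parameter | default | meaning |
|---|---|---|
| activity_threshold | 0.05 | minimum fractional InsP6 loss to call activity |
| dominance_share | 0.5 | minimum InsP5 share for a dominant class |
| dominance_ratio | 2 | dominant class must double the runner-up |
| minpp_gate | 0.05 | 5-OH presence / 1/3-OH absence gate (InsP5 share) |
| theta_report | 0.01 | mole fraction above which an intermediate "is identified" |

Two conventions matter and are deliberate design choices. First, InsP5 shares
are computed on the *baseline-corrected increase* max(t_n − t_0, 0): the
clean substrate itself carries ~5% InsP5 [1/3-OH], which would otherwise leak
into the 1/3-OH share and misread a genuine MINPP isolate as mixed — the
screen's own logic is "peaks not present in the reference". Second, all
fractions are taken over total *inositol phosphate*: the Pi/InsP1 pool is
excluded from the denominator, which makes every label invariant to Pi
accumulation, Pi scavenging, and overall profile scaling.

The cascade: (1) InsP6 loss below the activity threshold → `NO_ACTIVITY`;
(2) find the dominant InsP5 class if any; (3) dominant 1/3-OH → `PHYTASE_3`;
dominant 4/6-OH with 5-OH share below the gate → `PHYTASE_4_6`; dominant
5-OH → `PHYTASE_5`; dominant 2-OH → `UNCLASSIFIED_2POS` (no EC class
corresponds to initial 2-attack); (4) dominant 4/6-OH with a 5-OH share at or
above the gate and 1/3-OH below it → `MINPP_LIKE`; (5) everything else →
`MIXED_COMMUNITY`, including the case of a dominant 4/6-OH flanked by *both*
5-OH and 1/3-OH above the gate, which no single positional class explains.
Because a single promiscuous MINPP and a multi-enzyme community produce the
same qualitative multi-peak pattern, a mixed call always carries an evidence
note that MINPP alone is compatible; resolving that ambiguity needs isolation
or sequencing, not chromatography. The MINPP gate value (5%) is a free choice
— the source observations are qualitative ("a smaller 5-OH peak", "little to
no detectable degradation at the 1/3-position") — and is flagged as such.

## 5. Synthetic scenarios and their calibration

`make_substrate("clean")` is 95% InsP6 + 5% InsP5 [1/3-OH] — the residual
impurity of a purified phytate preparation; `"commercial"` adds lower
inositol phosphates and Pi totalling 25% impurity and fails QC at the default
10% threshold, emulating unpurified commercial phytate.

Enzyme presets (weights w1..w6; k per day):

| preset | weights | k | pattern |
|---|---|---|---|
| bsubtilis_bpp | 0.01, 0.01, 1.0, 0.01, 0.01, 0.01 | 0.12 | 3-position attack, dominant 1/3-OH |
| buttiauxella_appa | 0.20, 0.001, 0.001, 0.001, 0.05, 10.0 | 0.12 | 6-position attack; InsP5 [4/6-OH] share 0.975; exactly two InsP4 products (d/l-Ins(2,3,4,5)P4 ≫ d/l-Ins(1,2,3,4)P4) |
| ac12_minpp | 0.02, 0.05, 0.02, 0.8, 0.5, 1.6 | 0.2 | promiscuous: dominant 4/6-OH, smaller 5-OH, trace 1/3-OH, four InsP4 intermediates at day 2 |
| btminpp | same weights | 0.6 | the same specificity expressed much more strongly |
| five_phytase | 0.01, 0.01, 0.01, 0.01, 1.0, 0.01 | 0.3 | diagnostic dominant 5-OH |
| pputida_null | uniform | 0 | clearing-zone false positive |

Rates are calibration artifacts, not measurements: the reference experiments
constrain the qualitative pattern at the sampled days (e.g. "much of the
InsP6 remained" after 3 days for the *Bacillus*-type strain; near-complete
degradation by day 2 for the AppA-type isolate with the InsP5 pool still
present), and k values were chosen once to land in those regimes. Note that k
multiplies the raw weight sum, so buttiauxella_appa's InsP6 removal rate is
k·Σw ≈ 1.2/day despite the small k.

The `agricultural_soil` scenario mixes the three positional signatures
(mixing weights 3.0 / 0.3 / 2.0) under a logistic lag with midpoint day 3
(τ = 0.25): degradation becomes visible on day 3 (~29% loss), under 5% of
starting InsP6 remains by day 5, and the mid-course profile (day 4) carries
simultaneous 1/3-OH, 4/6-OH and 5-OH signatures plus ≥4 InsP4 classes and
InsP3 — a `MIXED_COMMUNITY` call. The mixed signature is transient: by day 5
the 3-phytase's 1/3-OH product has been consumed by the other activities and
the snapshot resembles the dominant surviving activity. Reading soil screens
mid-course is therefore part of the documented protocol. Relative enzyme
abundances in real soils are unknown; these mixing weights are calibration
artifacts. The `broadbalk` scenario is sorption (3/day) plus Pi scavenging
(5/day) with no enzymes: phytate leaves the medium within a day with no
intermediates and no Pi accumulation, emulating a high-clay soil. Because
sorption is modelled for InsP6 only, the 5% InsP5 impurity stays in solution;
an enzymatic component would slowly convert it into visible intermediates,
which the reference observation excludes — hence the enzyme-free preset.

Scenario noise defaults to SD 0.002 on traces whose diagnostic peaks have
heights of order 0.1–1.5, i.e. signal-to-noise well above 20 for everything
the classifier relies on; all generators are deterministic given
(name, seed).

**What the generator does not emulate.** Real gradients drift; real baselines
curve; real peak shapes tail; real detector response differs between classes
and instruments; extraction from agar is incomplete and matrix-dependent;
sorption binds lower inositol phosphates too, not only InsP6; and real
communities grow, so rates are not first-order throughout. Passing the
package's tests therefore shows the *interpretive logic* is sound under the
stated forward model, not that any particular instrument will reproduce these
numbers. The anchored facts (the InsP5 quartet, the enantiomer ambiguity, the
Pi/InsP1 co-elution, the three anchored retention times, the 5% substrate
impurity) are the parts that transfer.

## 6. Problem sizes and numerical notes

The test suite and acceptance script run entirely from code-generated data:
traces of 4001 points (0–40 min at 0.01 min), 64-state kinetics propagated by
matrix exponential or RK4 (step 0.005 day in scenario tests), 100 random
communities in the conservation suite, 50 seeds in the noisy round-trip
suite, 100 seeded replicates in the label-stability suite, 20 random rate
constants per preset in the classifier identity suite. Degenerate inputs are
handled explicitly: all-zero weight vectors are rejected; zero-InsP6
references make `degradation_extent()` error rather than divide by zero;
profiles that do not cover the InsP5 quartet are rejected by the classifier;
non-uniform time grids and malformed CSV rows fail with the offending line
identified. Ties in peak merging keep the earlier (taller-first) peak;
ties in assignment resolve to the nearest retention entry.

## 7. Known limitations

* Enantiomer-resolved assignment is impossible by construction; a 4/6-OH
  product genuinely cannot distinguish 1d-6 from 1d-4 attack.
* The two InsP4 orbits absent from the standards ladder have invented default
  retention slots only in the extended table; with the default 7-slot table
  their peaks are reported as unassigned.
* Terminal-product behaviour (enzymes stalling at InsP3/InsP2) is supported
  by zero weights but no preset asserts a specific terminal level.
* No Michaelis–Menten saturation, enzyme expression dynamics, or microbial
  growth; the lag term is a phenomenological stand-in for cohort growth.
* InsP7/InsP8 pyrophosphates and the neo-, scyllo- and d-chiro-inositol
  backbones are out of scope: *myo* only.
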