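---
title: "Models and methods behind lactoswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lactoswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactoswitch)
```

`lactoswitch` bundles two connected pieces of machinery: a deterministic
kinetic model of a lambda-phage-derived tri-stable genetic switch coupled to
gut-lumen lactose/lactate/pH chemistry, and a microbiome time-series toolkit
(sqrt-JSD beta diversity, PCoA trajectories, sparse inverse covariance
networks) exercised entirely on seeded synthetic data. This vignette records
the models, the tunable parameters, the numerical choices, and the design
decisions taken where the underlying biology left the formulation open.

## The circuit model

The switch toggles an engineered *E. coli* between two functional states:
accumulation of β-galactosidase (β-GAL, the *lacZ* product, hydrolysing
lactose) and expression of membrane-targeted L-lactate dehydrogenase (L-LDH,
the *ompA-lldD* product, oxidising lactate to pyruvate and thereby raising
pH). Six gene products are tracked at the protein level (cI, cro, cII, cIII,
β-GAL, L-LDH); mRNA is not modelled explicitly because no transcript-level
rates are available — protein-level lumping is the simplest formulation
consistent with the circuit's verbal logic.

All promoter responses are Hill functions:

* **placm** — activated by lactose:
  $v_0 + (v - v_0)\,L^n/(K^n + L^n)$.
* **patp2** — modelled as repression by the proton concentration
  $h = 10^{-\mathrm{pH}}$: $v_0 + (v - v_0)\,K_h^n/(K_h^n + h^n)$, so the
  promoter weakens as the pH drops. With the default $K_h = 10^{-6}$ the
  half-response sits at pH 6, between the permissive neutral colon (pH 7)
  and the acidic mouse colon (pH 5). The quantitative dose–response of this
  promoter is uncharacterised, so the midpoint is a design choice placed
  where the switch must discriminate.
* **pR** — repressed by cI; drives both *cIII* and *ompA-lldD*.
* **pRM** — repressed by cro; drives *lacZ*.
* **pRE** — activated by cII. placm and pRE drive *cro* and *cII* with
  additive rates, since both genes sit in the lactose-activated positive
  feedback loop.

Degradation is first order everywhere except cII, whose effective rate
$\delta_{cII} + \delta_F K_{III}^m/(K_{III}^m + cIII^m)$ encodes
FtsH-mediated proteolysis inhibited by cIII.

**Default parameters.** The supplementary parameter table of the source
study is not available, so the shipped defaults are a documented design set
(maximal rates 10 a.u./h, leaks 0.05–0.1, unit half-saturations, Hill
exponent 2, protein turnover 1/h for regulators and 0.5/h for the two
enzymes, FtsH terms $\delta_F = 9$, $K_{III} = 1$, $m = 2$) chosen — before
any downstream analysis was built on them — so that the circuit realises its
documented regimes:

* at (pH 7, lactose 0) there is exactly one stable state and it is strongly
  β-GAL dominant (β-GAL ≈ 49 × L-LDH);
* at (pH 5, lactose 25 mM) there is exactly one stable state and it is
  strongly L-LDH dominant (≈ 77 ×);
* a coupled lactose pulse at neutral pH drives the system through the L-LDH
  regime and back.

Every value is exposed through `circuitParams()`.

**Numerics.** Trajectories use `deSolve::lsoda` (stiff-capable) at rtol
1e-8 / atol 1e-10; excursions below zero beyond −1e-12 abort, smaller ones
are clipped with a warning. Fixed points come from Levenberg–Marquardt
multi-starts (`minpack.lm::nls.lm`) drawn log-uniformly over
$[10^{-3}, 10^3]$ a.u. from an explicit seed; stability is decided by the
eigenvalues of a central-difference Jacobian (relative step 1e-6), and
duplicates are merged at $L_\infty$ distance 1e-6. The test suite checks the
multi-start roots against an independent oracle: at fixed signals the only
nonlinear balance is the scalar cII equation, whose roots are enumerated on
a dense grid and refined with `uniroot`.

## The lumen model

The extracellular state is (lactose $L$, lactate $A$, pyruvate $P$, biomass
$B$); pH is derived, not stored, through a single saturating depression
$\mathrm{pH} = \mathrm{pH}_{ref} - \eta A/(\kappa + A)$. A full
Henderson–Hasselbalch speciation would need the buffer composition of the
medium, which is unknown; the one-parameter map is monotone, invertible
(initial lactate is recovered from a measured initial pH) and testable.
Fluxes are Michaelis–Menten: hydrolysis ($V_{gal}$ per enzyme × biomass),
community fermentation of lactose to lactate with stoichiometry
$y_{lac} = 4$ (homolactic: lactose → 2 hexoses → 4 lactate), L-LDH oxidation
of lactate, a baseline alkalinization $k_{alk}B$ (growth-linked consumption
of the medium, which lets control cultures show a late pH rise), and
pyruvate uptake treated as a pure sink. Biomass grows logistically with a
Gaussian pH penalty. For the integrator the $A \ge 0$ floor is smoothed: the
alkalinization sink ramps off over the last $10^{-3}$ mM of lactate
(the LDH term already vanishes at $A = 0$ through its Michaelis factor); a
hard floor produced step-size chattering in `lsoda` exactly at acid
exhaustion.

Arms differ only in their effective enzymes: the engineered (test) strain
contributes circuit β-GAL **on top of** the native *lacZ* baseline
$Z_{native}$ and its circuit L-LDH; control/model/untreated arms carry
$Z_{native}$ and no L-LDH.

**Per-setting presets.** The three environments differ biologically, so the
presets differ:

* `in_vitro` — pure BL21 culture in adjusted LB: no community fermentation
  (the lactic acid was pre-added to the medium), reference pH 7.4 (the LB
  consumption plateau, which the cultures approach from below), η = 3.4,
  inoculum OD 2. $V_{ldh} = 0.12$, $k_{alk} = 0.06$, $\mu_{max} = 0.6$ were
  chosen so the simulated 12-h cultures reproduce the documented directions:
  the test culture ends above the control culture at every initial pH
  (4.54, 5.34, 6.25) and the rescue gap is largest in the most acidic set,
  where only the enzymatic route can visibly move the saturated pH map.
* `mouse_colon` — homeostatic reference pH 5 (so an untreated arm is exactly
  stable), fast lactose clearance ($V_{gal} = 25$), modest fermentation; the
  gavage of 12 mg lactose per 20 g body weight maps to 87.6 mM over a
  configurable 0.4 mL lumen volume (the study reports no lumen volume).
* `human_colon` — neutral reference pH 7 with strong community fermentation
  and slow hydrolysis; used by the 48-h `human_pulse` preset that
  demonstrates the full switch cycle.

## Beta-diversity trajectory analysis

Counts are rarefied to 4000 reads per sample by subsampling **without
replacement** (samples below depth are dropped, not scaled); the test suite
checks per-feature means of 1000 seeded draws against the hypergeometric
expectation. Profiles receive a pseudocount of $10^{-6}$ on the proportion
scale (applied to the abundance distributions, not to raw counts) and are
renormalized. The distance is
$D(a,b) = \sqrt{\tfrac12 KLD(p_a, m) + \tfrac12 KLD(p_b, m)}$,
$m = (p_a + p_b)/2$, with the Kullback–Leibler divergence in **natural
log** — the log base is not fixed by the defining equations, so it is a
recorded open choice; with natural log the squared divergence is bounded by
$\ln 2$ and the distance is a metric.

PCoA is classical scaling: Gower double centering $B = -\tfrac12 J D^2 J$,
eigendecomposition, coordinates $v_i\sqrt{\lambda_i}$ for positive
eigenvalues. Negative eigenvalues are reported, never corrected, and axis
signs are fixed deterministically (each axis's largest-magnitude loading is
made positive) so PCo1 trajectories are reproducible run to run.

Per-group PCo1 trajectories use `stats::loess` (degree 2, tricube weights,
span 0.75 by default — common defaults, the choice being otherwise
unconstrained) with 95% pointwise bands. Group differences per collection
day use a two-sided Mann–Whitney test with mid-ranks: the null is exact (by
complete enumeration, conditional on ties) when both sides have ≤ 8
observations, and a tie-corrected normal approximation otherwise.
Benjamini–Hochberg correction is applied jointly across all testable
(day, pair) cells of one analysis run; untestable cells are reported as
missing and excluded from the family.

## Sparse microbial networks

Features with < 20% prevalence across all samples are removed (the
threshold is inclusive). Compositional counts are centred-log-ratio
transformed on pseudocounted proportions. The graphical lasso maximizes
$\log\det\Theta - \mathrm{tr}(S\Theta) - \lambda\sum_{i\ne j}|\Theta_{ij}|$
by block coordinate descent on the covariance with coordinate-descent lasso
subproblems (C++/Armadillo), convergence at maximal parameter change
< 1e-6, at most 500 sweeps, edges declared at $|\Theta_{ij}| > 10^{-8}$.
On problems with up to four features the returned objective agrees with an
independent brute-force coordinate-search maximizer to < 1e-6.

Penalty selection follows StARS: a log-spaced 20-point path from
$\lambda_{max}$ (largest absolute off-diagonal covariance — the sparsest
end) down to $0.01\lambda_{max}$; 50 subsamples without replacement of size
$\min(\lfloor 10\sqrt n\rfloor, \lfloor 0.8 n\rfloor)$; per-penalty edge
instability $\bar D(\lambda) = \mathrm{mean}_e\, 2\xi_e(1 - \xi_e)$
monotonized by a running supremum from the sparse end; the selected penalty
is the smallest (densest graph) whose monotonized instability stays ≤ 0.05,
refit on the full data. When nothing qualifies the densest admissible end is
returned with a warning flag. Note $2\xi(1-\xi)$ is bounded by 0.5.

Condition subsets mirror the 21-day design: `normal_condition` (untreated,
days 7 and 11), `lactose_feeding` (model/control days 5, 7, 11; test days
5, 7), `treatment` (test days 11 and 13). Whether the original analysis fit
one pooled network recoloured per subset or three per-subset networks is
ambiguous; both modes are implemented (`mode = "per_subset"`, the default,
and `mode = "pooled"`), with the prevalence filter always applied over all
samples so the node set is shared. Node sizes are per-subset mean relative
abundances on the full composition; the top 50 nodes by overall mean are
flagged. Genus-level comparisons sum relative abundances over all features
with a matching genus label regardless of classifier confidence
(confidences are reported alongside).

## The synthetic-data generator

`simulateStudy()` emulates the post-denoising product of the 4-group,
21-day murine design: phases I (days 1–3, normal care), II (4–9, lactose
challenge), III (10–15, bacterial treatment), IV (16–21, restoration);
groups untreated/model/control/test with 10 mice each. Mice are sampled on
alternate days in two interleaved 5-mouse cohorts (days 1,5,9,…,21 and
3,7,…,19), giving 55 samples per group — the only sampling scheme we found
consistent with both "every other day" sampling and the study's per-group
totals of 53–59 — and covering the network-subset days 5, 7, 11, 13.

The latent structure is log-additive: a per-feature log-normal baseline
(sd 1.5, which makes the 35 Bacteroidia-tagged members of the top-50
features carry roughly two thirds of the community, a Bacteroidia-dominated
mouse gut); per-mouse heterogeneity (sd 0.15); a shared temporal drift
ramping linearly from day 3 to day 11 that loads on the Bacteroides-like
block (full-ramp magnitude 0.8 log-units — the untreated community drifts,
a documented but unexplained observation that is modelled as a stand-in,
not a mechanism claim); and a lactose effect (block suppression −0.5
log-units, Lactobacillus-like boost +0.7) active for model/control/test in
phase II and model/control in phase III, the test group reverting to the
shared trend under treatment. Counts are Dirichlet-multinomial
(concentration 300) at log-normal depths (mean 8000), chosen over a
log-normal-multinomial because the closed-form Dirichlet mean makes the
marginal expectation testable. Cage effects exist as a random intercept but
default to off.

What the generator does **not** emulate: phylogenetic correlation between
features, read-level error/chimeras, absolute-abundance changes,
compositional zero-inflation beyond the multinomial, or real temporal
autocorrelation within a mouse beyond its static baseline. Passing tests
therefore demonstrate that the analysis code recovers structure of this
simple log-linear kind, not that it would behave identically on real 16S
data.

## Calibration and power checks

Two study-level Monte-Carlo harnesses ship with the package.
`calibrateTypeI()` runs null studies (all effects and drift zero) through
the full JSD/PCoA/Mann-Whitney pipeline and pools per-cell rejections at
the 0.05 level; the scaled design uses two groups of 15 mice on a single
sampling day per replicate, for two analytic reasons: (i) 15-vs-15 cells
exercise the normal-approximation branch, whose exact size at the 0.05
level is 0.0502 by enumeration of the null U distribution, whereas the
discrete exact branch at (say) 5 vs 5 can only attain size 0.032 — no
implementation could sit inside a tight binomial interval around 0.05
there; (ii) one cell per replicate keeps the pooled rejection count
binomial — cells sharing mice and one ordination are positively correlated,
which invalidates the interval. `patternRecoveryRate()` scores, over seeded
default-effect studies, the qualitative PCo1 pattern the design is built to
produce: untreated drift beyond its baseline spread by days 7–11,
separation from the lactose-fed groups over those days, and the test group
closing more than half of the model group's gap in the treatment phase.

Problem sizes used by the shipped checks — 200 profile triples, five
50-node/200-sample network recoveries with 20 subsamples, 500 calibration
replicates, 50 pattern seeds, 1000 rarefaction draws — were set as
reasonable Monte-Carlo sizes for a desk-scale reproduction.

## Known limitations

* The circuit parameters are a designed default set, not fitted values; the
  model reproduces directions and regimes, not measured magnitudes.
* The pH map ignores buffering species and CO2; the in-vivo lumen model has
  no transit, absorption or osmotic effects, so simulated trough depths are
  qualitative.
* "Tri-stability" manifests here as two strongly dominant stable regimes
  plus the transient mixed state; under the shipped defaults no parameter
  region with three simultaneous point attractors is claimed.
* The glasso implementation penalizes off-diagonal entries only and assumes
  a well-conditioned covariance; zero-variance features are guarded but
  effectively dropped from edge formation rather than modelled.
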