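---
title: "Plastic and genetic phenotype changes across environmental shifts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastic and genetic phenotype changes across environmental shifts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastevo)
```

## The question and the three-stage protocol

When an organism meets a new environment, its phenotypes change in two
phases. First, the environment itself moves trait values without any
mutation — the *plastic* change. Then, over generations of adaptation,
mutations move them again — the *genetic* change. Whether the plastic phase
is a stepping stone toward the adapted state (genetic changes *reinforcing*
the plastic ones) or a disturbance that evolution undoes (genetic changes
*reversing* them) is an open and consequential question for how much weight
plasticity should carry in evolutionary theory.

`plastevo` operationalizes the comparison through three stages per trait:

* **o** — the adapted ancestor measured in the original environment
  (`L_o`),
* **p** — the same genotype measured right after the shift, before any
  mutation (`L_p`),
* **a** — the re-adapted organism in the new environment (`L_a`).

From these, the plastic change is `PC = |L_p − L_o|`, the genetic change
`GC = |L_a − L_p|`, and the total change `TC = |L_a − L_o|`. Two kinds of
traits are supported: gene-expression levels from experimental-evolution
compendia (via the `expression_dataset` pipeline) and metabolic fluxes
predicted from constraint-based models (via the `metabolic_model` stack).

## Flux prediction: FBA, MOMA, MOMA-b

For metabolic traits the three stages are predicted from a stoichiometric
model (matrix `S`, bounds `α ≤ v ≤ β`, biomass vector `c`):

* Stage o and stage a use **flux balance analysis**: maximize `cᵀv`
  subject to `S v = 0` and the bounds — the flux state of an organism whose
  growth has been optimized by selection in that environment.
* Stage p uses **minimization of metabolic adjustment**: minimize
  `‖v − v₀‖²` under the same constraints, with `v₀` the stage-o fluxes. The
  cell right after a shift has the old regulatory state; the nearest
  feasible flux distribution is the natural model of its immediate,
  pre-mutation response.
* **MOMA-b** adds the equality `cᵀv = b` with `b` the FBA optimum, so the
  stage-a state can be predicted by the *same* quadratic program as stage
  p. This removes the worry that comparing an LP solution with a QP
  solution manufactures spurious "genetic changes" out of solver
  differences; `run_adaptation(..., stage_a_method = "moma_b")` selects it.

Environments are sets of available carbon sources; applying one sets the
uptake bound of each available carbon exchange to its uptake rate (default
10 mmol gDW⁻¹ h⁻¹, the conventional glucose-limited setting) and closes
uptake — but deliberately not secretion — of every other carbon exchange.
Whether absent sources should also have secretion closed is not decidable
from the published description; leaving secretion open is the weaker
assumption and is the package default.

Relative fitness is biomass production normalized by the stage-o rate:
`f_p` (after the shift, before adaptation) and `f_a` (after re-adaptation).
A new environment counts as *adaptable* when `f_p` exceeds `1e-4`
(`screen_environments()`): below that, the plastic response cannot sustain
the population long enough for adaptation to happen.

### Solvers and numerics

FBA is solved by a package-local dense two-phase simplex with Bland's
anti-cycling rule; MOMA and MOMA-b are strictly convex quadratic programs
solved by the Goldfarb–Idnani dual active-set method (`quadprog`). Both
sit behind one contract (status, flux vector, objective, residual), so a
different backend can be substituted without touching callers. Two
numerical conventions matter:

* the global tolerance `flux_tolerance() = 1e-4`: solutions must satisfy
  `‖S v‖∞ ≤ 1e-4` and the bounds to that tolerance, and flux differences
  below it are treated as zero when classifying;
* FBA optima can be degenerate (the diamond toy splits its two redundant
  paths arbitrarily). The package accepts the vertex the solver returns and
  provides `shuffle_reaction_order()` to quantify the effect; the MOMA
  optimum is unique (strictly convex objective) and is verified to be
  invariant under such shuffles.

The dense simplex is exact and fast on the toy networks the test-suite
uses (problem sizes of 3–5 reactions, and the property suite's largest
instances stay under a few hundred variables); genome-scale
reconstructions (thousands of reactions) are supported by the same code
path but take hours, which is acceptable for the optional one-off
genome-scale reproduction (`analysis/05_genome_scale.R`) and irrelevant
for routine use.

## Trait classification

`classify_traits()` assigns exactly one category per trait at a relative
cutoff `θ` (conventionally 0.05, 0.2 or 0.5; default 0.2):

| category | condition |
|---|---|
| reinforcing | `PC > cut`, `GC > cut`, same direction |
| reversing | `PC > cut`, `GC > cut`, opposite directions |
| plastic_only | only `PC > cut` |
| genetic_only | only `GC > cut` |
| unchanged | neither |

with `cut = max(θ·|L_o|, ε)`. The `|L_o|` guards against negative flux
baselines (expression levels are non-negative, fluxes are not); `ε` is the
absolute floor — `1e-4` for fluxes (the ignored-difference rule), `0` for
expression, where no analogous instrument floor is published. Exceeding is
strict: a change exactly at the cutoff is not appreciable. Reversing
traits subdivide into *restored* (`TC ≤ cut`), *over-restored* (`GC > PC`)
and *under-restored* (ties `GC = PC` count as under-restored, matching the
"otherwise" reading of the definition). Whenever both changes are
appreciable the plastic change is *facilitating* (`GC < TC`) or
*hindering* (`GC > TC`); the measure-zero tie `GC = TC` is left
unassigned.

Per-adaptation summaries (`summarize_adaptation()`) report all category
fractions with **all analyzed traits** in the denominator — that is what
makes a mean reversion fraction of ~30% commensurable across adaptations —
plus `q`, the fraction of traits with `PC > TC`, and an exact binomial
test of reinforcement vs reversion counts. The two-tailed convention is
the doubled smaller tail capped at 1; with a symmetric null (p = 0.5) this
equals the usual minimum-likelihood convention and reproduces the
published worked values (`2·0.5⁵⁰ ≈ 1.8e-15` for a 50-of-50 split,
`1.1e-10` for 42 of 44, `1.0e-7` one-tailed for 43 of 50).

### Why reversion should outnumber reinforcement: the geometric null

If `PC > TC`, the genetic change *must* point back toward `L_o` —
reversion is forced by geometry, not biology. If `PC ≤ TC` and nothing
else biases the direction, reinforcement and reversion are equally
likely. With `q = Pr(PC > TC)`, the expected ratio is

```
C_RI / C_RV = 0.5(1 − q) / (0.5(1 − q) + q) = (1 − q)/(1 + q),
```

implemented in `expected_ratio()`. `drop_pc_gt_tc()` performs the
sufficiency check: removing the forced traits should erase the excess.
`condition_on_tc()` restricts to traits with appreciable total change —
the only traits visible to comparative biology, where stage p cannot be
measured; restored reversions are invisible there by construction.

## Synthetic data: what it emulates and what it does not

All tests run without downloads, on three seeded generators:

* `gen_triplets()` plants category fractions directly: appreciable effects
  are uniform multiples of `L_o` in `[0.3, 1]` (a 0.1 margin above the 0.2
  cutoff), non-appreciable ones stay 0.1 below it, and multiplicative
  log-normal noise (sd 0.02, a typical replicate-to-replicate scale for
  normalized expression) is applied afterwards. Two stacked downward
  moves are jointly capped so expression stays non-negative; single and
  opposing moves need no cap, so both directions carry the full effect
  range and the planted sign structure survives at all three conventional
  cutoffs.
* `gen_mechanism_triplets()` embodies the proposed mechanism: a latent
  fitness drops to `f_p` at stage p and recovers to `f_a`, and each trait
  follows it (log-linearly) with its own random coupling, plus an
  independent adaptive shift at stage a. Deeper drops produce larger
  plastic excursions, a higher `q`, and a stronger reversion excess.
* `gen_planted_q()` realizes the geometric null itself: a planted fraction
  `q` of traits gets `PC > TC`, the rest get a fair-coin genetic
  direction, and every effect is appreciable by construction.

The distinction between the last two matters. In the fitness-coupled
generator, appreciability at the cutoff is *not* symmetric between the
two directions given `PC ≤ TC` (the reversing side has the larger genetic
change and passes the cutoff more often), so its observed `C_RI/C_RV`
systematically undershoots `(1 − q)/(1 + q)`. The exact-law and
null-calibration tests therefore use `gen_planted_q()`, and the
fitness-coupled generator is tested for its qualitative claims (monotone
`q` in the fitness drop, mean PC falling as `f_p → 1`, the excess
vanishing after `drop_pc_gt_tc()`). Neither generator attempts
study-specific artifacts — library-size effects, batch structure, partial
adaptation at the end of an experiment — so passing tests certify the
*method*, not the noise model of any particular dataset.

`gen_case_bundle()` assembles a 44-case compendium (42 cases planted with
a reversion excess, mirroring the scale of the published transcriptome
reanalysis) for the cross-case sign test; `gen_toy_model()` provides the
linear, diamond and two-source networks whose FBA/MOMA solutions are
closed-form (the two-source carbon swap has
`u* = y₁y₂U/(2 + y₂²)` through the new path, giving `f_p = y₂u*/(y₁U)`
and `f_a = y₂/y₁`).

## Random mixed-carbon environments

`random_environments()` draws, for each candidate source, an availability
probability `g` from an exponential with mean 0.1 (truncated to `[0, 1]`;
the truncation only matters with probability `e⁻¹⁰`) and then a Bernoulli
presence. Two draw modes are provided because the published description
and the published summary statistics point in different directions: one
`g` per (environment, source) pair — the literal reading — implies a mean
of `258·E[min(g,1)] ≈ 25.8` sources per environment with little skew,
whereas the reported mean-28/median-21 pattern is right-skewed and
matches one `g` per environment. `per_source` is the default; neither
mode is asserted to be the original implementation. Seeding uses one
master seed with fixed per-environment substreams, so enlarging an
ensemble never reshuffles the environments already drawn.

## Transcriptome ingestion

Expression matrices from heterogeneous studies are harmonized in four
steps, each a separate operation: drop genes with missing values
(`filter_missing()`, with configurable missing markers), rescale each
dataset to a common grand mean (`normalize_mean()` — classification is
provably invariant to this scalar, and the test-suite asserts it, so the
target value is irrelevant), average replicates per line
(`average_replicates()`, arithmetic mean on the provided scale — the
categories are defined on the measurement scale, so no log transform is
taken), and assemble per-case o/p/a triplets from a YAML manifest
(`build_triplets()`; several cases may share ancestral samples). A
synthetic manifest example ships in `inst/extdata/`.

`growth_independent_mask()` supports the growth-rate confound check:
genes whose expression is monotone across ordered chemostat growth rates
may merely track growth. The one-line published definition does not say
whether ties break monotonicity; the default here counts tied, otherwise
monotone profiles as growth-rate-*dependent* (non-strict convention), with
`strict = TRUE` available, and the choice is recorded in the mask's
construction rather than hidden.

## Design choices where the description was open

* **Diffusion/trait exclusion.** Which reactions count as non-mutable
  "diffusion" is published only as a final count. The default predicate —
  gene-less 1:1 transport of one compound between compartments, plus all
  exchanges — is a configurable argument of `read_sbml_model()`, not a
  hard-coded rule.
* **Carbon-source detection.** An exchange is carbon-transporting when its
  metabolite's elemental formula contains carbon (with Cl/Ca/Cu-style
  false positives excluded by parsing) and is not on a small blocklist of
  non-nutritive inorganics (CO2, bicarbonate, carbonate), again
  configurable.
* **Stage-a predictor.** FBA is the default (re-adaptation means
  re-optimized growth); MOMA-b is the robustness alternative.
* **Screen threshold semantics.** `f_p` is compared on the relative scale,
  so the `1e-4` threshold means "one ten-thousandth of ancestral growth".
* **Restoration boundary.** `TC ≤ cut` counts as restored, consistent with
  the strict-exceedance convention used everywhere else.

## Problem sizes used by the checks

The property suite runs entirely on the toy networks, `1e5` random
triplets for the classifier-oracle comparison, `1e4`-trait mechanism and
planted-`q` simulations, `1e4` random environments, 200 null-calibration
replicates of 500 traits, and a 44-case bundle of 1500 genes — sizes at
which Monte-Carlo error is far below every asserted tolerance. The
genome-scale reproduction (258 carbon exchanges, 1811 flux traits, 50
adaptable environments from glucose) additionally needs the iAF1260 SBML
from BiGG, a documented one-time download, and is therefore exercised
only when that file is present.

## Known limitations

* The dense simplex and active-set QP are exact but not engineered for
  genome-scale speed; a sparse barrier backend would be the natural
  extension behind the existing solver contract.
* FBA degeneracy means stage-o and stage-a flux vectors are one optimal
  vertex among possibly many; summary patterns are robust to reaction
  re-ordering, but individual trait categories near the cutoff need not
  be.
* The transcriptome pipeline treats provided expression values as the
  trait scale; it does not model counting noise or batch structure, and
  the growth-rate filter requires an external chemostat series.
* Synthetic generators certify correctness of the statistics and the
  pipeline, not the biological realism of any particular study's noise.
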