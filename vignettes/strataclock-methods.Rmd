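---
title: "Reconciling fossils and molecular clocks: models and methods in strataclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconciling fossils and molecular clocks: models and methods in strataclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strataclock)
```

# The problem

The first appearance of a clade in the fossil record gives a *minimum*
age for its origin; a molecular clock gives an *estimate* of that age,
often older, always with uncertainty. `strataclock` implements both sides
of this comparison for a calibrated phylogeny:

1. **Stratigraphic calibration.** Given a rooted tree whose tips carry
   first appearance data (FADs) — age intervals `[fad_min, fad_max]` in
   Ma — every node is assigned the conservative interval
   `[max descendant fad_min, max descendant fad_max]`. The difference
   between a lineage's origin (its attachment node's age) and its FAD is
   a *ghost lineage*: a span of existence implied by its sister group but
   unrecorded by fossils.
2. **Bayesian relaxed-clock dating.** Given sequence data for the extant
   tips, node ages are estimated under an uncorrelated lognormal clock
   with fossil-derived calibration priors on selected nodes.
3. **Comparison.** Lineage-through-time (LTT) curves from both sources,
   congruence metrics for the fossil side, and a calibration-subset
   sensitivity design for the clock side.

The packaged worked example is the South American rodent clade
Cavioidea *sensu stricto* (cavies, maras, capybaras and their extinct
stem), whose record is binned to South American Land Mammal Ages
(SALMAs, `salma_timescale()`).

# Stratigraphic side

## Calibration and ghost lineages

`strat_calibrate()` is a single postorder pass computing running maxima;
age conventions are Ma before present, "older" always meaning
numerically larger. The minimum ghost duration of a tip is
`max(0, parent age_lo - fad_max)`: the least-commitment reading, using
the *youngest* defensible node age against the *oldest* defensible
FAD. On the packaged cavioid tree this reproduces the canonical
arithmetic: taxa first recorded in the Colhuehuapian (FAD max 20.5 Ma)
attached under Deseadan-constrained nodes (age_lo 24.5 Ma) carry ghost
lineages of at least 4 Myr.

`count_ghost_origins()` counts ghosts originating *within* a named
interval over **all** branches, terminal and internal. The internal
branches matter: a ghost lineage can lead to a whole clade that appears
later in the record (on the cavioid tree, the lineage to
*Luantus propheticus* + more derived cavioids is one of the four
Deseadan ghosts; a tip-only count would find three).

## Congruence metrics

`strat_metrics()` works with one *point* age per tip. Which FAD bound to
use is genuinely open — published scripts differ and rarely say — so the
bound is an argument (`fad_min` by default, `fad_max` and `midpoint`
selectable) and the choice is reported in the result.

* **MIG** (minimum implied gap) is the sum over *tips* of minimum ghost
  durations. Note this is the per-tip variant; the classical literature
  sometimes accumulates gaps over internal branches as well. The
  internal-branch accounting lives in `strat_debt()`: the length of the
  age character optimized on the tree under an irreversible model
  (descendants may be younger than ancestors for free; every Myr of
  implied pre-appearance range costs one step). Its optimum places every
  node at its oldest descendant's age, so debt = total age drop over all
  edges.
* **MSM\*** = (minimum possible debt) / (observed debt). The minimum over
  all trees is the age range of the data, so MSM\* = range/debt, 1 for a
  perfectly congruent tree.
* **GER** = `1 - (MIG - g_min)/(g_max - g_min)`. With ages sorted
  `a1 >= ... >= an`, the extremes have closed forms: `g_min = a[n-1] -
  a[n]` (the youngest tip's sister clade must contain something at least
  as old as the second-youngest tip; the age-sorted pectinate tree
  attains the bound) and `g_max = sum(a1 - a[i])` over `i >= 2` (the
  pectinate tree with the oldest taxon most deeply nested). Both closed
  forms are proven against exhaustive enumeration over all rooted binary
  topologies for n ≤ 5 in the test suite.

Degenerate data — all tip ages equal, so `g_max == g_min` and the debt is
zero — are defined as perfectly congruent (GER = MSM\* = 1). Polytomies
are treated as hard: no resolution search is attempted, for determinism.
Ties anywhere are broken by stable tip-label order.

# Calibration priors

Two published rules convert a fossil-bearing unit's age bracket into a
node prior:

* `normal_prior(age_lo, age_hi, z)` — mean at the midpoint, sd chosen so
  the bounds sit at the `z` quantiles. The default is `z = qnorm(0.95) =
  1.6449`, i.e. **90% central coverage**. Back-solving the published
  parameter table shows this is what its authors actually did (e.g.
  half-width 1.485 / sd 0.9 ≈ 1.65), despite wording that suggests 95%;
  `z = qnorm(0.975)` is available for the stricter reading.
* `gamma_prior(hard_min, soft_max, shape)` — offset (hard minimum) at the
  oldest secure record, fixed shape, and the scale solved so the 95th
  percentile sits at the soft maximum (the age of the youngest
  well-sampled fauna lacking the clade). The solve is exact through the
  gamma scale family. Only the Cavioidea node's soft maximum (45 Ma) is
  printed in the source material; the other three nodes' gamma
  parameters are therefore shipped verbatim in `table1_priors()` rather
  than re-derived (their back-solved soft bounds are mutually
  inconsistent, so no single reconstruction reproduces all of them).

`round_half_up()` reproduces the half-up rounding convention of printed
tables (R's `round()` rounds half to even).

# The dating model

`clock_date()` fits, by Metropolis–Hastings MCMC on a **fixed** rooted
binary topology:

* **Likelihood**: Felsenstein pruning over compressed site patterns, per
  partition, under unlinked GTR models with 4-category discrete-gamma
  rate variation (category conditional means) and an optional
  invariant-sites class (implemented as an extra zero-rate category; the
  gamma classes keep their mean-1 scale). Gaps, `?` and any non-ACGT
  symbol are fully ambiguous. A branch's expected substitutions are
  `rate × (parent age - child age)`. The kernel is compiled (C++), with
  per-node rescaling against underflow, and is verified in the tests
  against brute-force summation over all internal state assignments.
* **Clock**: one independent lognormal rate per branch, parameterized by
  the real-space mean `ucld_mean` and log-space sd `ucld_sd` (log-space
  location `log(ucld_mean) - ucld_sd^2/2`).
* **Tree prior**: Yule density of internal node ages for a pure-birth
  process started with two lineages at the root, jointly with observing
  `n` tips: `log p = (n-2) log λ - λ (2 t_root + Σ non-root ages)`. For
  two tips this is the no-further-split term `-2λt`. The same convention
  is used by the simulator (`sim_yule_tree()`), which stops the clock
  just before the `n+1`-th split — a single shared convention avoids a
  silent mismatch between prior and generator. With `tree_prior =
  "none"` the ages instead get a flat reference: each uncalibrated
  non-root age uniform on `(0, root age)`, *normalized* (the `1/root`
  terms matter — without them the ordering volume tilts calibrated
  marginals away from their priors).
* **Calibrations** are addressed by the MRCA of a named tip set, which
  must be monophyletic on the fixed topology (checked before sampling);
  gamma priors contribute `-Inf` below their hard minimum, which the
  sampler treats as rejection, not error.
* **Hyperpriors** (the source protocol leaves them unstated): uniform
  `ucld_mean` on (0, 100] substitutions/site/Myr, `ucld_sd` on (0, 5],
  Yule birth rate on (0, 10]/Myr. All are sampled by default and can be
  held fixed via `fix=`.

**Fixed topology is a deliberate deviation**: the original protocol
co-estimated topology and dates, but reported its clock results on the
same topology as its other analyses; fixing it keeps the engine at desk
scale and all calibrated clades well-defined.

## Move set and mixing

One move per generation, fixed weights (logged in the trace's
`acceptance` attribute): single node-age redraw uniform in its
parent/children bracket (the bracket does not depend on the current
value, so the proposal is symmetric); root-age window slide; whole-tree
age scale; a compensating ages-up/rates-down scale that exploits
rate–time confounding (likelihood invariant by construction); single
branch-rate scale; hyperparameter scale moves; and an *independence
proposal from the calibration prior* for calibrated nodes, whose
Hastings ratio cancels the prior factor — this mixes calibrated nodes
essentially perfectly wherever the posterior marginal tracks the prior,
and substantially helps elsewhere.

## Runs, summaries, reproducibility

Defaults follow the published protocol scaled to a desk: 200,000
generations sampled every 1000 (the original 10M × 4 runs are one
`mcmc_settings()` call away), 10% burn-in (unstated in the source;
configurable), four independent runs integrated by `combine_runs()` —
pooled mean and 95% HPD, with ESS summed over runs (autocorrelation is a
within-run property; note this makes ESS additive across runs, so the
"four identical runs" idempotence identity applies to mean and HPD, not
ESS). `hpd()` is the shortest sorted-sample window; `ess()` uses the
initial positive sequence rule, with a zero-variance series defined to
have ESS `n`. Each run's RNG stream derives from `(seed, run index)` by
a fixed affine rule, making multi-run results bit-reproducible.

# Sensitivity design and LTT curves

`enumerate_analyses()` generates the full `(2^k - 1) × 2` design —
every non-empty calibration subset under both prior families, largest
subsets first, normal before gamma — which for the four conventional
cavioid nodes is the 30-analysis table shipped in `table1_priors()`.
`run_sensitivity()` runs them all with per-analysis derived seeds.

`ltt_fossil()` counts lineages *from their inferred origins* (node
`age_lo`), not their FADs — that is what makes ghost lineages visible in
the diversification curve (6 cavioid lineages by the end of the
Deseadan: 2 recorded + 4 ghosts). Curves are cumulative origination
counts, non-decreasing toward the present; extinction is not subtracted.
The `age_lo`/`age_hi` pair forms the envelope induced by fossil age
uncertainty. `ltt_clock()` is the same step construction at posterior
mean ages. `gap_report()` floors gaps at zero where interval
uncertainties overlap: an overlap means no *demonstrable* hiatus.

# The synthetic-data generator

`sim_scenario()` states the simulated world once:

* 12 extant tips (matching the number of sequenced taxa in the worked
  example's clade of interest);
* Yule birth rate 0.12/Myr — chosen so expected root ages
  (`Σ 1/(kλ) ≈ 17.5` Ma) sit on the mid-Miocene scale of the example;
* relaxed clock with `ucld_mean` 0.01 substitutions/site/Myr (a typical
  mammalian mixed nuclear/mitochondrial figure) and `ucld_sd` 0.3;
* four partitions with the published aligned lengths (961, 1140, 1099,
  814 bp), GTR+Γ with the cytochrome-b-like partition adding invariant
  sites;
* fossil preservation as per-SALMA-bin Poisson sampling along terminal
  branches (fossil taxa are sampled ancestors simplified to tips at
  their FAD, so internal branches are not sampled), with bin-specific
  rate multipliers to emulate a Lagerstätten effect.

What the generator does **not** emulate: morphological characters,
alignment error, heterotachy, sampling-through-time (fossilized
birth–death) dynamics, and biogeographic structure in preservation. A
green recovery test therefore establishes that the engine is internally
consistent — data generated under the model yield calibrated posterior
coverage — not that any of those real-data complications are handled.

# Numerical choices and degenerate inputs

* Gamma-scale solve: exact via the scale family; tested to 1e-8 across
  shapes 0.5–10.
* Pruning: per-node rescaling below 1e-250; category mixing by
  log-sum-exp; eigendecomposition through the symmetrized GTR form.
* `hpd()` requires ≥ 20 samples; constant samples give a point interval.
* All-equal FADs: GER and MSM\* defined as 1.
* Empty alignment: likelihood 0, the chain samples the joint prior.
* Settings must leave ≥ 100 post-burn-in samples per run (refused
  otherwise).

# Prior-recovery checks: what they can establish

With data removed, the marginal of a calibrated node equals its
calibration prior only when no *other* density couples to it. A Yule (or
any informative) tree prior multiplies in and legitimately tilts
calibrated marginals; similarly, an uncalibrated node squeezed between
calibrated ones contributes an ordering volume. The package's
prior-recovery test therefore runs with `tree_prior = "none"` and every
internal node calibrated by well-separated priors — the one regime where
"marginal = prior" is the mathematically correct expectation — and
checks each marginal by Kolmogorov–Smirnov distance. Failures under a
Yule prior would be a property of the model, not a bug.

# Known limitations

* Topology is fixed; there is no co-estimation and no support for
  sampled-ancestor or tip-dating models.
* The Yule prior convention is one of several in circulation; densities
  are documented up to additive constants and should not be compared
  across packages without checking conventions.
* MIG is the per-tip variant (see above); compare with other software
  accordingly.
* The MCMC is a minimal sound sampler, not an optimized one: very large
  trees or alignments will want longer runs than the desk-scale
  defaults.
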