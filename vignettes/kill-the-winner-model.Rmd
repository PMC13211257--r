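---
title: "Model and methods: kill-the-winner dynamics under immune surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: kill-the-winner dynamics under immune surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the model addresses

A mucosal microbial community is an open competitive system: taxa with
different intrinsic proliferation rates compete for limited space, and
without any stabilizing force the fastest grower is expected to displace the
rest (competitive exclusion). `hexktw` implements a deliberately minimal
mechanism that can prevent this collapse: a *kill-the-winner* surveillance
rule in which the host does not recognize or curate individual taxa at all,
but simply penalizes whichever taxon has become disproportionately abundant,
and only when the community as a whole has grown large. The package exists to
make the community-level consequences of that single rule explicit and
reproducible: diversity collapse when the rule is off, stable maintained
diversity when it is on, and cycles of collapse and recovery when it is
applied intermittently.

Two implementations of the same logic are provided:

* a stochastic, spatially explicit lattice simulator (`ktw_run()`), and
* a deterministic mean-field map (`meanfield_run()`) with the same
  threshold rule, useful for analytic cross-checks.

## The lattice model

### Geometry

Space is a `width x height` rhombus of hexagonal sites in axial coordinates
`(col, row)`, with toroidal (wrap-around) boundaries. Each site holds at most
one cell; a cell belongs to one of `n` species. The six neighbors of a site
are the fixed axial offsets `(+1,0) (-1,0) (0,+1) (0,-1) (+1,-1) (-1,+1)`.
The torus removes edge effects, so every site is statistically equivalent;
the cost is that dimensions below 3 would make wrapped neighbors coincide,
so neighborhood queries and dynamics reject lattices narrower than 3 (state
construction still allows them, which keeps degenerate states testable).

The default lattice is 60 x 60 = 3,600 sites: large enough that all three
regimes express themselves clearly, small enough that a 1,000-step run takes
well under a second.

### Per-step dynamics

Each step applies, in this order:

1. **Mortality.** Every occupied cell is independently vacated with
   probability `mortality` (default d = 0.05).
2. **Replication.** The surviving cells are visited in a uniformly random
   order; each replicates with its species' probability
   (`replication_probs`, default 0.3 / 0.5 / 0.7 / 0.9 for the four-species
   roster) into one empty neighbor chosen uniformly. A cell with no empty
   neighbor cannot replicate, and cells born within the step do not
   replicate until the next step.
3. **Surveillance check** (below), at most one event per step.
4. **Recording** of counts, Hill numbers and the event flag — after the
   check, so a penalization is visible in its own step's row.

Several of these choices deserve justification, since they are genuinely
open design decisions:

* **Why mortality at all?** With replication alone the lattice fills and
  freezes: no further births are possible, so neither collapse nor
  surveillance-maintained diversity can manifest. A small background death
  rate keeps space turning over. `mortality = 0` remains available in the
  configuration for studying the frozen case.
* **Why sequential (not synchronous) replication?** Synchronous updating
  lets two cells claim the same empty site in one sweep, which then needs an
  arbitrary conflict-resolution rule. Visiting survivors in a random order
  is the simplest conflict-free scheme, and the uniformly re-drawn order
  makes it unbiased on average.
* **Why exclude newborns from replicating in their birth step?** It bounds
  per-step growth by the current population and keeps the step semantics
  independent of the visit order's tail.
* **Why this rate gradient?** The four default replication probabilities
  span a strong threefold gradient, so competitive exclusion completes well
  within 1,000 steps when surveillance is off; the maintenance result is
  explicitly *not* sensitive to these values (the test suite re-draws them
  uniformly in (0.2, 0.95)).

### The surveillance rule

The rule has three numbers and one policy:

| parameter             | default | meaning                                        |
|-----------------------|---------|------------------------------------------------|
| `load_threshold`      | 0.70    | community load as a share of *all* sites        |
| `dominance_threshold` | 0.30    | top taxon's share of *occupied* sites           |
| `removal_fraction`    | 0.80    | fraction of the target's cells removed          |
| `target_policy`       | dominant_taxon | who is penalized                         |

An event fires when **both** thresholds are strictly exceeded
("exceeded" reads as a strict inequality, which also makes the boundary
behavior exactly testable: a community sitting at precisely 70% load or a
30% share never fires). When it fires, `round(0.8 * count)` cells of the
dominant taxon — ties broken toward the lowest species id — are removed
uniformly at random, rounding half away from zero so a single-cell target is
removed rather than spared. Load is measured against total capacity
(how full the system is), dominance against the community (how uneven it
is); these are different denominators on purpose, since the two thresholds
sense different things.

The `dominant_taxon` policy is the model's reading of suppression "directed
at" the winner; removing 80% of *all* cells is retained as the
`whole_community` policy for sensitivity analysis, but it is not the
default: indiscriminate removal rescales the community without changing its
composition, which is exactly what a kill-the-winner mechanism is not.

Temporal activation is a `schedule`: `always`, `off`, or `windows` — a list
of half-open `[start, end)` intervals in 0-based step indices. The
intermittent regime uses windows `[200, 400)` and `[600, 800)`; half-open
intervals were chosen so that windows tile without double-counting
boundaries, and "active during steps 200–400" maps to first activation at
step 200 and last at 399.

### Randomness and reproducibility

One master seed drives everything. It is expanded (via one `sample.int()`
draw) into three named substreams — initialization, dynamics, penalization
sampling — and the run loop swaps the corresponding RNG states in and out.
The point of the split is that surveillance sampling never perturbs the
dynamics draws: a run with surveillance on is *bit-identical* to the same
seed with surveillance off up to the first penalization event (the test
suite asserts exactly this). Within the dynamics substream the three phases
(mortality, visit order, target choice) share one stream inside the compiled
kernel; splitting those further would require a hand-rolled splittable
generator and buys nothing at module granularity.

Initialization seeds each species with an equal number of cells (within one
cell for indivisible totals) on sites sampled uniformly without replacement,
at 10% total occupancy by default — an unbiased, symmetric start.

## Diversity: Hill numbers

Community evenness is summarized by Hill numbers, the effective number of
equally abundant species:

$$ ^qD = \Big(\sum_i p_i^q\Big)^{1/(1-q)}, \qquad
   ^1D = \exp\Big(-\sum_i p_i \ln p_i\Big), $$

with $p_i$ the relative abundances over species with nonzero counts. Orders
0, 1 and 2 are species richness, exponential Shannon diversity and inverse
Simpson diversity; effective species counts are reported (rather than the
raw indices) because they share one scale and one unit, and the raw indices
remain available as `shannon_index()` / `simpson_index()`. Conventions that
matter numerically: the $q = 1$ case is computed directly from the entropy
limit, never by evaluating the general formula near 1; zero-count species
are excluded from all sums; the empty community is assigned diversity 0
(not an error) so post-collapse trajectories stay representable; and
$q = 0$ returns the integer richness exactly. The implementation is checked
in the test suite against `vegan::renyi(..., hill = TRUE)` on random
communities and against closed forms.

## The mean-field counterpart

The non-spatial twin tracks real-valued abundances $x_i$ of $n$ taxa with a
shared logistic resource limitation, mortality, and the identical threshold
rule, as a discrete-time map with the same step semantics as the lattice:

$$ x_i \leftarrow x_i + x_i\,\big(r_i\,(1 - S/K) - m\big), \qquad
   S = \sum_j x_j, $$

floored at zero, followed (on active steps) by the threshold check: if
$S/K$ strictly exceeds the load threshold and some share $x_i/S$ strictly
exceeds the dominance threshold, the dominant taxon is multiplied by
$1 - \text{removal fraction}$.

Choices worth recording:

* **Mortality is load-bearing here.** With $m = 0$ the shared-logistic
  system is neutral at capacity — any composition with $S = K$ is a fixed
  point — so exclusion would never complete. With $m > 0$ only the fastest
  grower persists: the surviving equilibrium is $S^* = K(1 - m/r_{\max})$,
  and every other taxon has negative per-capita growth there. This closed
  form is the analytic oracle in the tests (single-taxon equilibrium matched
  to relative error below $10^{-6}$).
* **A discrete Euler map, not an ODE.** The suppression event is an
  instantaneous discrete cull; embedding it in a continuous integrator
  would blur exactly the thing being modeled. An optional smaller Euler
  sub-step (`euler_dt`) is exposed and converges to the same equilibria.
* **Extinction tolerance.** Abundances under a multiplicative map never
  reach exact zero, so survivors are counted above $10^{-6} K$.
* **Shared capacity, not an interaction matrix.** "Competitive
  interactions" is read in its simplest form — one common resource pool. A
  full pairwise interaction matrix is a deliberate non-goal; the shared-K
  form is the minimal instantiation that exhibits the exclusion/coexistence
  dichotomy.

Defaults mirror the lattice roster: $r = (0.3, 0.5, 0.7, 0.9)$, $m = 0.1$,
$K = 1000$, $x_i(0) = 25$, 1,000 steps.

## What the generator emulates — and what it does not

The simulator is a conceptual model of surveillance logic, not a calibrated
model of any real community. It emulates: space-limited growth with distinct
proliferation rates, load- and dominance-triggered suppression, and the
resulting community-level regimes. It does **not** emulate: taxon-specific
immune recognition, graded (non-threshold) suppression, migration or
mutation, resource or chemical gradients, multiple organisms per site, or
measurement noise of real abundance data. Consequently, passing tests show
that the *rule is logically sufficient* for the regime behaviors on this
idealized substrate — they say nothing quantitative about real mucosal
communities, and no parameter here is fitted to data.

## Validation scale and numerical conventions

The regime properties are stochastic, so the package verifies them on
ensembles: 20 independent master seeds per regime on the default 60 x 60
lattice and 1,000 steps, comparing ensemble *medians* (robust to the
occasional straggler seed). That size keeps the full validation suite under
a couple of minutes on a single core while leaving the three regimes far
from their decision boundaries; `scripts/acceptance.R` re-runs the same
ensembles from scratch and writes the measured medians as JSON. Exact
behaviors (trigger boundaries, removal counts, schedule onset, round-trips)
are tested deterministically on constructed states via `make_fixture()`,
which places a community with prescribed occupancy and dominant share to
the cell.

Other conventions: removal counts round half away from zero; trigger
comparisons are strict; trajectories are recorded once per completed step
(0-based `step` column, `n_steps` rows); TSV output prints reals at full
precision so round-trips are exact to the printed digit; and every run
writes a JSON sidecar with the fully resolved configuration, from which
`run_from_sidecar()` reproduces the trajectory bit for bit.

Configuration files are YAML with sections mirroring the module structure
(`lattice`, `species`, `dynamics`, `surveillance`, `seed`); YAML was chosen
as the lightest human-diffable format with a mature parser available to R,
and unknown or out-of-range keys are rejected by name.

## Known limitations

* The maintenance regime's richness result (all species retained) is a
  statement about 1,000-step horizons at the default lattice size; on much
  longer horizons rare extinction of the slowest species under repeated
  near-misses of the trigger is not excluded.
* Penalization is capped at one event per step; simultaneous multi-taxon
  blooms are handled over consecutive steps instead.
* The mean-field map with `euler_dt = 1` is a coarse integrator; it is exact
  for the questions asked of it here (equilibria, dichotomy), but stiff
  parameter combinations should use a smaller `euler_dt`.

## A minimal session

```{r}
library(hexktw)

# the three regimes of the model
collapse <- ktw_run(ktw_config(seed = 1, surveillance = list(mode = "off")))
maintain <- ktw_run(ktw_config(seed = 1))
cycles   <- ktw_run(ktw_config(seed = 1, surveillance = list(
  mode = "windows", windows = list(c(200, 400), c(600, 800)))))

plot_panels(list(collapse = collapse, maintained = maintain,
                 intermittent = cycles), file = "regimes.png")

tail(maintain$trajectory[, c("step", "hill_q0", "hill_q1", "hill_q2")], 1)
```
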