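---
title: "A multi-valued logical model of speract-activated calcium signaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-valued logical model of speract-activated calcium signaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saspnet)
```

## The biological problem

Sea urchin spermatozoa steer toward the egg by modulating their flagellar
beat with intracellular calcium. The egg-coat decapeptide speract triggers,
through receptors along the flagellum, a cascade of cyclic-nucleotide
production, membrane-potential excursions and ion-channel gating that
produces trains of [Ca²⁺] fluctuations; each Ca²⁺ rise corresponds to a
sharp turn of the swimming path. `saspnet` models this speract-activated
signaling pathway (SASP) as a discrete dynamical system and provides the
machinery to ask a pharmacological question in silico: what happens to the
calcium oscillations when the channels targeted by a multi-target drug such
as niflumic acid — the hyperpolarization-activated cation channel HCN, the
Ca²⁺-gated chloride channel CaCC and the Ca²⁺-gated potassium channel
CaKC — are forced shut (or forced open), alone and in combination?

## The formalism

The network has $N$ nodes $x_1,\dots,x_N$, each taking integer values in
$[0, a_i)$ with arity $a_i \in \{2, 3\}$. Time advances synchronously:

$$x_i(t+1) = F_i\big(x_{i_1}(t), \dots, x_{i_{k_i}}(t)\big),$$

where the $k_i$ regulators of node $i$ and the regulatory function $F_i$
(stored as a complete truth table with $\prod_j a_{i_j}$ rows) are part of
the network definition. Because the state space is finite and the update
deterministic, every trajectory ends on a cycle (an *attractor*); the number
of steps before the trajectory first lies on its cycle is the *transient*,
the cycle length is the *period*, and the fraction of initial conditions
reaching a given attractor is its *basin fraction*.

Interventions are *clamps*: a clamped node ignores its table and holds a
fixed value from the first update onward (`knockout()` clamps to 0,
`constitutive_activation()` to 1). The initial state may hold any value for
a clamped node — it is overwritten at $t = 1$ — so basin statistics remain
comparable across intervention scenarios.

## The bundled SASP network is a reconstruction

The package ships a 21-node SASP model under
`inst/extdata/sasp_synthetic/`. The structural skeleton follows the
published description of this pathway's logical model exactly: 21 nodes;
four ternary nodes — membrane potential `V` (hyperpolarized/resting/
depolarized), the voltage-gated calcium channels `LVA` and `HVA`
(inactive/closed/open) and `Ca` itself (basal/tonic/supratonic) — and a
432-row calcium table driven by the channel activators (LVA, HVA, cAMPCC),
the extrusion systems (CaP, NCE) and calcium self-inactivation.

The truth tables themselves, however, are a **synthetic reconstruction**:
the original model's supplementary table files were not available in
machine-readable form, so every $F_i$ was rebuilt from the wiring diagram
and standard electrophysiology. The directory name and metadata flag this.
Three reconstruction choices deserve emphasis:

* **The seventh calcium regulator.** The six named calcium regulators with
  their stated arities yield a 216-row table, while the published table has
  432 rows, implying one additional binary regulator. The reconstruction
  uses HCN — a weakly Ca²⁺-permeant inward current — which doubles the
  table to $3\cdot3\cdot2\cdot2\cdot2\cdot2\cdot3 = 432$ rows while keeping
  all six canonical regulators in place.
* **Node membership.** Beyond the nodes named in the wiring diagram
  (Speract, SR, GC, cGMP, PDE, KCNG, NHE, cAMPCC, HCN, LVA, HVA, CaP, NCE,
  CaCC, CaKC, V, Ca and the permeability summaries dCa, dCl, dNa, dK), the
  pH/adenylate-cyclase limb is folded into a single NHE → cAMPCC link to
  stay at 21 nodes.
* **Graded state variables integrate.** `V` and `Ca` move one level per
  step in the direction of their drive balance rather than jumping, because
  membrane potential and calcium concentration are graded physical
  quantities. Channel gating rules encode threshold logic with
  inactivation: LVA/HVA open from the closed state when the voltage
  threshold is met, inactivate after one open step and recover only upon
  hyperpolarization; KCNG requires cGMP, a closed channel, *and* K⁺ driving
  force (it is silent at hyperpolarized V) and inactivates after one step.

`sasp_reconstruction()` documents every rule; a test asserts that the
bundled text files and the programmatic definition are identical.

### What the reconstruction does and does not reproduce

Measured on the package's own pipeline, the reconstruction reproduces the
dynamical *class* of the published model: under speract-activated initial
conditions all trajectories reach short-period calcium oscillations
(a period-8 attractor with the Ca motif `0 0 0 1 2 1 0 0`), the maximum
transient (19 steps) respects the published 45-step bound, the
ensemble-averaged trace carries an 8-step recurrence module, and its
spectrum is dominated by the 1/8 line with a 1/4 component — all of which
the original model also exhibits. It does **not** reproduce the fine
structure that lives in the exact table entries: the published coexistence
of a period-4 attractor (88.9% basin) with the period-8 attractor (11.1%),
the specific perturbation periodicities (period 7 under CaKC activation,
period 9 under the triple knockout) and most directions of the published
effect matrix. The acceptance tests assert the published values and
therefore fail on those points by design; they document the gap rather than
hide it. Conclusions drawn from this package about the *reconstruction* are
exact; conclusions about the original model are limited to the structural
and qualitative features listed above.

## Initial conditions, ensembles and the averaged trace

All SASP statistics use the *speract-activated* policy
(`speract_policy()`): the ligand node is pinned at 1 and excluded from the
free dimensions; the remaining 20 nodes are drawn independently and
uniformly, giving $2^{16}\cdot 3^4 \approx 5.3$ million possible initial
states — too many to enumerate routinely, hence seeded uniform sampling
with $10^5$ draws as the default study condition (exhaustive mode exists
for small networks and is used throughout the tests as an oracle).

The modelled counterpart of a fluorescence trace is the ensemble average
of the Ca node over all sampled initial conditions
(`ensemble_average()`), a real series in $[0,2]$. All trajectories start
in phase (speract arrives at $t=0$), which is what keeps the ensemble mean
oscillating; after the 150-step discarded transient the series is *exactly*
periodic — it is a finite average of deterministic periodic trajectories —
with period the lcm of the realized attractor periods. This exactness is
exploited throughout: recurrence modules are detected at tolerance
$10^{-9}$, and a window-$p$ running average annihilates any $p$-periodic
component exactly, which is how envelope structure (e.g. a 72-step beat
between period-8 and period-9 components) is exposed.

Summary metrics over a 50-step window: mean, peak (max), amplitude
(full swing, max − min). The characteristic period is reported both
spectrally (reciprocal of the dominant periodogram frequency) and as mean
peak-to-peak spacing, since the two can differ for attractor mixtures.

## Spectra and the effect matrix

`power_spectrum()` is a plain periodogram of the mean-centered series — no
tapering, because the signals are exactly periodic and the goal is line
positions, not density estimation. The analysis window (default 1000
steady-state steps) is first trimmed to a whole number of recurrence
modules so lines land exactly on rational frequencies $k/p$. Power is
normalized so total power equals the window variance (Parseval; tested).
Lines above 5% of the maximum power count as *dominant*;
`mode_diversity()` (their count) is the regularity metric: one line means a
clean single-period oscillation, many lines mean a temporally elaborate
trace. Harmonics of a retained fundamental are annotated.

`build_arrow_table()` condenses a 12-scenario run (wild type; HCN⁻, CaCC⁻,
CaKC⁻, CaKC⁺; the three double knockouts and two doubles with CaKC⁺; the
triple knockout "scenario 1" and the CaKC-activated triple "scenario 2")
into up/down/equal arrows versus the wild type. A difference within 1% of
the wild-type value counts as "equal" — the published matrix prints "="
without a tolerance, and 1% is well above Monte-Carlo noise at $10^5$
initial conditions while well below any claimed effect.

## Numerical choices

* Attractor identity is canonical: two trajectories share an attractor iff
  their cycles contain identical state sets; the representative is the
  lexicographically smallest cycle member (node order is fixed
  alphabetically, so encodings are comparable).
* The batch engine detects periods as first-return times after a 200-step
  burn-in (well beyond the 45-step transient bound) and fails loudly —
  rather than silently truncating — if any trajectory has not returned
  within 128 steps.
* State vectors are encoded in mixed radix as doubles; exact up to
  $2^{53}$, far beyond the $10^7$-state spaces used here.
* Exhaustive enumeration is refused above $2^{22}$ states.

## The synthetic generators

`random_network()` (uniform tables), `signed_random_network()` (signed
edges with a frozen monotone threshold-balance rule: output = clamped
activator-minus-inhibitor score, ties resolve down) and `ring_fixture()`
(a one-hot cyclic shift register with a designed period $p$ and zero
transient) exist so that every pipeline stage is testable against
closed-form or brute-force oracles without touching the SASP fixture. The
balance rule is a test scaffold, not a claim about the SASP tables.

## Problem sizes used in the tests

Unit and property tests run on networks of 1–10 nodes where exhaustive
enumeration is cheap, with sampled-versus-exhaustive agreement asserted at
three binomial standard errors. The acceptance-level checks run the full
study conditions: $10^5$ initial conditions per scenario, 150-step
transient, 1000-step spectra, 12 scenarios.

## Known limitations

* The bundled network is a reconstruction; see above for exactly which
  published features it does and does not reproduce.
* Synchronous deterministic update only — no asynchronous or stochastic
  schedules, and no symbolic (BDD) attractor computation, so exhaustive
  analyses are bounded by memory at ~$10^6$–$10^7$ states.
* No dose–response: clamping is all-or-none, so drug concentration is not
  a model parameter.
* Fluorescence units, dye kinetics and swimming trajectories are outside
  the model; comparisons with experiments are qualitative, at the level of
  oscillation structure.

## A worked example

```{r example, eval = FALSE}
net <- sasp_network()

# wild-type attractors and basins over speract-activated initial conditions
cat_wt <- basin_statistics(net, ic_policy = speract_policy(),
                           mode = "sample", n = 1e5, seed = 1)
tidy(cat_wt)

# averaged calcium trace and its spectrum, wild type vs triple knockout
wt <- ensemble_average(net, n_ic = 1e5, seed = 1, ic_policy = speract_policy())
ko <- ensemble_average(net, clamps = knockout(c("HCN", "CaCC", "CaKC")),
                       n_ic = 1e5, seed = 1, ic_policy = speract_policy())
summarize_series(wt)
dominant_periods(power_spectrum(wt))
autoplot(wt, window = 8)

# the full 12-scenario effect matrix
suite <- run_scenario_suite(net, n_ic = 1e5, seed = 1)
build_arrow_table(suite)
```
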