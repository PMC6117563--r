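---
title: "Aggregated Markov models of tetrameric NMDA receptor gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated Markov models of tetrameric NMDA receptor gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
gating model and its assumptions, the numerical machinery behind the
missed-event likelihood, the design choices that were genuinely open, and
what the synthetic-data tests do and do not demonstrate about real
recordings.

## The gating model

A single channel is modelled as a continuous-time Markov chain whose states
carry a conductance class, open or shut. Only the class is observable, so
the model is an *aggregated* Markov model: dwell-time distributions are
matrix-exponential mixtures determined by the partitioned transition-rate
matrix `Q`.

The tetrameric schemes shipped with the package encode one structural
hypothesis: after agonist binding, each of the four subunits independently
undergoes a rate-limiting pre-gating conformational change, with one rate
pair for the two GluN1 subunits (`kp_f`, `km_f`) and one for the two GluN2
subunits (`kp_s`, `km_s`), reflecting the twofold symmetry of the
heterotetramer. Channel opening is fast relative to these steps and is
possible once both GluN1 subunits and at least one GluN2 subunit have
completed pre-gating: a long-lived open state O1 (`beta1`/`alpha1`) opens
from the fully gated configuration, a brief open state O2
(`beta2`/`alpha2`) from the three-subunit-gated configuration, and the two
interconvert (`k12`/`k21`). Having two "gateway" closed states is what
produces the (weak, negative) correlation between adjacent open and shut
durations; an alternative topology in which opening requires all four
pre-gating steps (`build_all_four_gate()`) is provided for comparison and
has a single gateway and no open-state cycle.

Key assumptions, all inherited by every builder:

* **Independence / no cooperativity.** A subunit's pre-gating rate does not
  depend on the state of the other subunits. Aggregated states therefore
  carry combinatorial statistical factors (see below).
* **Saturating agonists for the single-channel schemes.** The grid and dimer
  schemes assume every site is occupied throughout; binding appears only in
  `build_binding_extended()`.
* **Microscopic reversibility.** Every cycle obeys detailed balance; `k12`
  is derived from the cycle through the two gateway states rather than
  fitted.

### Statistical factors

With two identical GluN1 subunits, the aggregate transition from "no GluN1
gated" to "one GluN1 gated" proceeds at `2 * kp_f`, and the reverse of the
fully-gated pair at `2 * km_f` — the factors of an independent-subunit
binomial scheme. Whether the published rate constants were estimated with
or without these multiplicities is not stated anywhere we could rely on, so
the builders expose `statistical_factors = TRUE/FALSE`. The default (`TRUE`)
was decided before any response-level comparison by an internal consistency
argument: the packaged `k12` values are reproduced (to three digits) by the
microscopic-reversibility identity around the O1–O2–gateway cycle only when
the factor 2 appears on the GluN2 back-step, and the factor-free convention
gives half the packaged value. The macroscopic acceptance checks were then
run under both conventions and confirm the same choice.

### Dimer-dependent desensitization

`build_dimer_desensitization()` tracks which dimer each step occurred in:
states are unordered pairs of per-dimer configurations, so "one GluN1 and
one GluN2 step completed" is two distinct states (within one dimer vs.
split across dimers). A dimer whose two subunits have both completed
pre-gating may desensitize (`kp_d`, recovery `km_d`); a desensitized dimer
freezes its internal configuration, the channel cannot open while any dimer
is desensitized, and both dimers may desensitize simultaneously.

### Glutamate binding and agonist trapping

`build_binding_extended()` adds a per-dimer GluN2 site that is unbound,
bound, or bound-and-gated. Binding (`kp_a * [glu]`) and unbinding (`km_a`)
occur only while the GluN2 pre-gating step has not happened; the pre-gating
rate from an unbound subunit is set to exactly zero (no value is available
for the "very low" alternative, and zero is the only defensible default —
an optional rate could be added without restructuring). GluN1 pre-gating is
glutamate-independent because glycine is treated as saturating throughout.

Two semantic details were genuinely open and were resolved as follows:

* **Desensitization requires all four subunits bound**, and while any dimer
  is desensitized, agonist exchange on the whole receptor is frozen
  (*agonist trapping*). Conditioning only the desensitization entry on
  partner occupancy, with free partner unbinding, creates a one-way cycle
  (equivalently, an absorbing desensitized-plus-unbound trap at zero
  glutamate) and breaks reversibility; trapping keeps every cycle balanced
  and removes the trap. The variant in which desensitization and recovery
  proceed regardless of partner occupancy is also reversible and was
  evaluated — it leaves every response statistic essentially unchanged
  except the steady-state concentration-effect curve, whose EC50 is the
  most protocol-sensitive quantity the package computes (see Limitations).
* **Opening requires all four subunits bound.** Attaching the brief open
  state additionally to the three-gated-but-partner-unbound configuration
  would put glutamate binding in a cycle through an aggregated open state
  and violate reversibility unless the open state were split.

## Missed-event dwell densities and the likelihood

Events shorter than the recording resolution (dead times `tau_open`,
`tau_shut`, both 50 microseconds in the packaged analyses) are missed and
concatenated into the flanking dwells, which biases every naive estimator.
The likelihood corrects for this exactly.

Within an alternating record, an apparent open dwell of duration `t`
contributes `eG_AF(t) = R_A(t - tau_open) Q_AF exp(Q_FF tau_shut)`: the
terminal factor demands that the following shut sojourn survive its dead
time, and the shift accounts for the open-survival factor carried by the
preceding dwell (the first dwell of a segment is scored unshifted). The
open-aggregate survivor `R_A(v)`, which permits excursions into the shut
class shorter than `tau_shut`, has two regimes:

* **Exact branch, `v <= tau_shut`** (dwells up to the sum of the two dead
  times, i.e. "two dead times" when they are equal): a completed missed gap
  cannot fit in the window, so `R_A(v)` is exactly the open-open block of
  `exp(Q v)`, evaluated in the eigenbasis of the full `Q`.
* **Asymptotic branch beyond:** `R_A(v) = sum_k R_k exp(s_k v)` with one
  real negative root `s_k` of `det W(s) = 0` per open state and area
  matrices `R_k = c r / (r W'(s_k) c)` from the null vectors of `W(s_k)`.

The two branches agree at the switchover to well under 1% for the shipped
mechanisms (`scgate:::branch_continuity()` reports the mismatch), and the
piecewise density integrates to one to about a part in a thousand, the
size of the asymptotic approximation error.

Numerical choices that matter:

* **Root search.** For reversible mechanisms (everything the builders
  produce) `W(s)` is symmetrizable with the square-root equilibrium
  weights, so each sorted eigenvalue branch of the symmetrised `H(s)` is
  bisected against `s` on a log-magnitude grid. This is robust to nearly
  degenerate roots, which the shipped mechanisms do produce (pairs split by
  a few parts in 10^4, where a determinant sign scan needs an impractically
  fine grid). The determinant scan, bracketed by the eigenvalues of the
  uncorrected sub-generator, remains as the fallback for non-reversible
  mechanisms, and a count mismatch is a loud error rather than a silently
  dropped component.
* **Underflow control.** The propagated row vector is rescaled after every
  dwell with the log-scale accumulated (standard hidden-Markov scaling),
  which is mandatory for records of 10^5 dwells.
* **Segment boundary vectors.** Whole-record ("equilibrium") scoring starts
  each segment from the equilibrium occupancies of the open states and
  closes with a unit vector; burst scoring conditions both ends on the
  flanking shut times exceeding the critical shut time, using the
  asymptotic tail integrals of the shut-dwell density.

## Constraints and fitting

Fitting works on log rates, where fixed values, equality ties and MR
conditions are linear. The constraint system is reduced by QR factorization
to an unconstrained parameterization, so the optimizer can never propose an
infeasible rate vector and MR-derived rates are re-derived exactly at every
step. MR constraints are attached by the minimum-spanning-tree
construction: edges whose rates are already tied (fixed, equality-tied, or
shared across several transitions) are weighted into the tree so they stay
free of MR conditions; each off-tree edge contributes one constraint on the
cycle closed by the shortest tree path, except that cycles which balance
identically for any parameter values (the grid cycles of the
shared-parameter schemes) are skipped. Of the two rates on an off-tree
edge the second-listed is constrained — the choice is arbitrary, and the
assembled `Q` (hence every likelihood) is invariant to it, which the test
suite checks by constraining the reverse member instead.

The optimizer is BFGS with central-difference gradients in log-rate space
(step 1e-5) and a Nelder–Mead refinement pass if the line search fails.
Default starts perturb the current rates by factors uniform on (0.5, 2)
under a recorded seed. Profile-likelihood intervals fix one rate,
re-maximize over the rest, bracket the crossing of the requested drop
(0.5 or 2 log-likelihood units) geometrically, root-find it, and polish
with a cubic interpolation of the profile.

## Dwell-time statistics

* `impose_resolution()` applies the standard left-to-right concatenation:
  an unresolvable event is merged, together with everything up to the next
  resolvable opposite-class event, into the current dwell; leading
  unresolvable events merge forward so total duration is conserved exactly,
  and the operation is idempotent.
* `fit_exp_mixture()` fits left-truncated exponential mixtures by EM on the
  shifted durations with ten seeded restarts; areas are reported as
  fractions of resolved events.
* `compute_tcrit()` uses the equal-*numbers* criterion (misclassified slow
  events below the threshold equal misclassified fast events above it),
  solved by bisection between the adjacent time constants; the grouping
  default takes only the slowest component as "between bursts". The
  packaged analyses use a fixed 35 ms critical shut time.

## Macroscopic and synaptic simulation

Constant-concentration protocol segments are solved exactly by spectral
relaxation; synaptic-like exponential transients are integrated with
`deSolve::lsoda` at a relative tolerance of 1e-8 on the exact linear
system `dp/dt = p (Q0 + [glu](t) Q1)`. Output grids are 10 microseconds for
the first 50 ms of each segment and 1 ms after, which resolves millisecond
rise times without making two-second simulations expensive.

Quantities reported by the acceptance script and their conventions:

* **Rise times** are 10–90% of peak with linear interpolation.
* **Exponential decay fits** (deactivation, desensitization) start at the
  waveform peak and, before least squares, resample the window onto a
  uniform time grid: recorded currents are uniformly sampled, and fitting
  the simulation's deliberately non-uniform grid would overweight the early
  fast phase. Desensitization fits include a free steady-state offset.
* **Concentration–effect curves** use 2 s applications on a quarter-log
  ladder from 0.1 to 316 micromolar, with the peak and the
  end-of-application value fitted by the Hill equation with free maximum.
* **Synaptic curves** vary the transient's peak concentration from 10
  micromolar to 10 millimolar at a fixed 1.2 ms decay.
* **Equilibrium binding curves** (`binding_occupancy_ec50()`) default to
  the receptor-level metric — the probability that the receptor holds at
  least one glutamate — with the per-site fractional occupancy available
  as an option. For the restricted (no GluN1 pre-gating) space the per-site
  curve is analytically Hill with midpoint `(km_a/kp_a)/(1 + kp_s/km_s)`,
  several-fold above the receptor-level midpoint; the receptor-level
  number is the one that corresponds to the published restricted binding
  EC50, which is why it is the default.

## The synthetic-data generator

`simulate_trajectory()` samples the chain exactly (exponential sojourns,
embedded-chain jumps) under R's seeded RNG; `simulate_patches()` produces
four records of 27,000 resolved open–shut transitions by default,
mirroring the size of the analysed experimental data set (about 108,000
transitions over four one-channel patches at 50 microsecond resolution).
Records begin at a resolved opening and end at a resolved closing.

The generator emulates an *idealized* record from a single, stationary,
mode-free channel: it contains no baseline noise, no filtering artifacts,
no amplitude information or subconductance levels, no modal switching, and
no idealization errors. Passing the recovery tests therefore demonstrates
that the estimator chain (densities, constraints, optimizer) is correct
and well-conditioned at the study's data size — not that real recordings
are free of the idealization and stability issues that experimental
analyses must screen for.

## Problem sizes and runtime

The test suite simulates and refits two full-size synthetic data sets
(4 x 27,000 transitions each) and verifies every free rate against its
2-unit profile interval, runs a 10^5-event histogram comparison, and
evaluates all macroscopic statistics; it completes in a few minutes on one
core. The acceptance script itself is deterministic and runs in seconds.

## Known limitations

* The steady-state concentration–effect EC50 is the least robust quantity
  the package computes: at two-second applications the low-concentration
  responses are still equilibrating, so the fitted EC50 depends visibly on
  application length and on the desensitized-state binding semantics,
  unlike every other reported statistic. The packaged convention
  (end-of-2-s, agonist trapping) should be kept in mind when comparing
  against values obtained under other conventions.
* Subconductance levels, voltage-dependent rates, glycine binding and
  modal behaviour are out of scope; concentration is the only
  time-inhomogeneity supported.
* The exact density branch covers dwells up to the sum of the two dead
  times, matching the fitting convention used throughout; a general
  piecewise-exact recursion beyond that window is not implemented because
  the asymptotic form already agrees to better than 1% at the switchover
  for all shipped mechanisms.
* SCN (binary idealization) files are not read; DWT and the canonical CSV
  cover the supported interchange formats.
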