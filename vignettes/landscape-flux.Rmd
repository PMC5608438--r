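---
title: "Potential and flux landscapes of stochastic Boolean networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Potential and flux landscapes of stochastic Boolean networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscape)
```

## The model

A regulatory network is a set of `n` named nodes with signed interactions
`a[i, j] ∈ {−1, 0, +1}` (effect of node `j` on node `i`). A global state
is a bit vector `s ∈ {0,1}^n`; its canonical index is `Σ s_i 2^(i−1)`
(node 1 = least significant bit), so probability and potential vectors
are ordered by state index. The total input of node `i` is
`I_i = Σ_j a[i,j] s_j`, compared against a per-node activation threshold
`θ_i` (default 0). The synchronous stochastic update draws every node's
next bit independently:

| effective input `h = I − θ` | next bit is 1 with probability |
|---|---|
| `h ≠ 0` | `1/2 + tanh(μ h)/2` |
| `h = 0`, bit currently 1 | `1 − c` |
| `h = 0`, bit currently 0 | `c` |
| `h = 0`, bit 0, checkpoint node while the state equals G0 | `γ` |

The state-to-state probability is the product of the node factors, giving
a row-stochastic `2^n × 2^n` kernel `T`. The three parameters are
dimensionless: `μ` is the response sharpness (an inverse noise strength;
5 in the canonical setting), `c` the basal flip probability per node per
step (0.001), and `γ` the probability per step that the checkpoint fires
out of the resting G0 state (0.6) — the "energy pump" that turns a
single-attractor landscape into a limit-cycle oscillator.

The `μ → ∞, c → 0` limit is the classic deterministic threshold rule
(on if `h > 0`, off if `h < 0`, hold at `h = 0`), which is what
`deterministic_update()` implements.

### The fission yeast fixture and its thresholds

The bundled ten-node fission yeast cell-cycle network (checkpoint CS
plus SK, Cdc2/Cdc13, Ste9, Rum1, Slp1, Cdc2/Cdc13*, Wee1/Mik1, Cdc25,
PP; 27 signed edges, four of them inhibitory self-degradation loops)
is stored as a plain-text fixture file — the file, not code, is the
source of truth, so every sign is auditable and overridable. The signs
and the two non-zero thresholds are transcribed from the deterministic
Boolean model of Davidich & Bornholdt (2008, PLoS ONE 3:e1672):
`θ = −0.5` for Cdc2/Cdc13 (on unless actively repressed) and
`θ = +0.5` for Cdc2/Cdc13* (needs net positive drive). These two
half-integer thresholds are not optional decoration: without them the
synchronous deterministic path stalls at the G1/S state (Cdc2/Cdc13 has
zero input there and would hold off forever), whereas with them the
update visits the ten biological states START → G1 → G1/S → G2 → G2 →
G2/M → G2/M → M → M → G1/G0 exactly, with G1/G0 absorbing. The test
suite asserts this trajectory.

### Stochasticizing the threshold nodes

For the two threshold nodes, `h = I − θ` is a half-integer and never 0,
so the hold rule never applies to them and the tanh argument is
ambiguous at the stochastic level: `μ(I − θ)` uses half-integer
arguments, while the deterministically equivalent rescaling `2μ(I − θ)`
keeps every node's response on the same integer lattice that the rule
table assumes. Both reproduce the deterministic path; they differ in
how noisy the two threshold nodes are (`tanh(2.5)` vs `tanh(5)` at the
minimal drive when `μ = 5`). We expose both
(`threshold_scaling = "integer"` / `"half"`) and default to
`"integer"`, selected — as prescribed for the gap convention below — as
the variant closest to the published robustness ratio for this network
(2.341 vs 2.383, against a published 2.298). No faithful variant we
examined (five stochasticizations × all gap conventions × moment
populations × probability floors) reproduces the published value to
three significant figures; we keep the corresponding acceptance
assertion red rather than bend a parameter, and report the computed
value. The residual 1.9% discrepancy is attributable to an unprinted
detail of the original computation (most plausibly the threshold-node
stochasticization or the solver's handling of extremely small
probabilities, both of which move RR by exactly this order).

## Steady state

`solve_steady_state()` solves `T' P = P` by a dense LU solve of the
stationarity system with one equation replaced by normalization, then
refines with power iterations. The refinement is not cosmetic: at
`μ = 5` the stationary probabilities span ~20 orders of magnitude, far
below the absolute accuracy of any dense solve, and the landscape
statistics take logs of them. Because each power iteration forms sums
of nonnegative terms only, there is no cancellation and arbitrarily
small entries converge with full *relative* accuracy. Iteration stops
when the residual falls below `1e-12` *and* the largest relative change
of any log-probability over a 50-step block is below `1e-9`.
Reducibility (possible non-uniqueness) is detected by strong
connectivity of the support graph and reported as a warning.

A related precision point: at `μ = 5`, `tanh` saturates to 1 in double
precision, so kernel entries for many-node-flips against saturation
underflow to exact zero even though the model is strictly positive.
`log_transition_matrix()` therefore builds `log T` factor-wise (via
`log(plogis(2μh)) = −log1p(e^{−2μh})`), keeping magnitudes down to
`e^{−1400}`. The entropy production rate uses it to evaluate its log
flow ratios; without it, underflowed edges would masquerade as one-way
(infinite-affinity) edges. Genuinely one-way edges (e.g. at `c = 0`)
are still segregated and reported, never silently dropped.

## Landscape conventions

`U = −ln P^ss`; states with `P = 0` (unreachable, possible at `c = 0`;
probabilities below 1e-300 are treated as 0) are excluded from all
moments. The robustness ratio is `RR = |U_m − ⟨U⟩| / ΔU` with moments
over all finite-potential states (population standard deviation). For a
multi-state native set, the reference `U_m` is a convention:

* `native-mean` (default): mean potential of the native states;
* `native-min`: their minimum;
* `global-min`: the global minimum.

For a single native state all three coincide. The default was selected
by the documented validation against the published fission-yeast value
(native-mean 2.34106 vs native-min 2.38891, published 2.29813). `RR` is
invariant under a constant shift of `U` and under the log base; the
suite asserts both the shift invariance and the Boltzmann normalization
`Σ exp(−U) = 1` on the support.

## Flux decomposition and loop peeling

With `Π_ij = T_ij P_i`, the net flux is `F = Π' − Π`, and the kernel
decomposes into the detailed-balanced part `D` and the one-way part `C`
(`J = max(Π − Π', 0)` entry-wise). `J` is conserved at every state, so
it peels exactly into directed cycles: walk along positive entries
until a state repeats, subtract the cycle's minimum edge value, repeat.
The peeling order is not mathematically unique; our fixed policy (start
at the smallest-index state with positive out-flux, follow the largest
outgoing entry, ties to the smallest target index, entries below
`1e-14` floored to guarantee termination) is implemented in C++ and
documented as such. Only policy-invariant quantities — the total flux,
the edge-wise reconstruction `Σ_loops r·1_edge = J`, and the dominant
loop when it is clearly separated — should be interpreted; the loop
*set* in the tail can differ under another legal policy. The native
loop is matched as a cyclic sequence up to rotation, not reflection:
direction is physical.

Loop probabilities are `P_flux = flux/Σflux`, loop potentials
`U_flux = −ln P_flux`, and `RR_flux` reuses the robustness-ratio core
with the native loop(s) as the native set. For the fixture at the
canonical parameters the ten-state biological loop carries 64% of the
total flux and is the unique minimal-`U_flux` loop among ~5000.

An independent trajectory route (scan a simulated path, excise a loop
whenever a state on the open path recurs, count loops up to rotation;
self-transitions are not loops) is implemented as a cross-check. Its
per-step native-loop completion rate matches the peeled native-loop
flux, and both routes agree on the dominant loop — the suite asserts
this. The *normalized* fractions of the two routes agree exactly on
clean toys (the two-loop figure-eight chain) but need not coincide in
the deep tail, where the peeling policy reshuffles micro-loops.

## Thermodynamics

System entropy `S = −Σ P ln P` (nats); affinities
`A_ji = ln(T_ji P_j / T_ij P_i)`; entropy production rate
`Σ T_ji P_j A_ji` in nats per step (the model is discrete-time; no
physical time unit is implied). Every pairwise term has the form
`(a − b) ln(a/b) ≥ 0`, so the rate is nonnegative and vanishes exactly
at detailed balance — equivalently, exactly when the loop decomposition
is empty; the suite asserts the equivalence and the closed form
`(p_f − p_b) ln(p_f/p_b)` on the biased ring.

## Trajectories and spectra

The simulator samples the same per-state node probabilities as the
kernel (C++, R's RNG, fully seed-reproducible). Spectra use the
mean-removed periodogram `|X_k|²/n²`, folded one-sided — identically
the Fourier transform of the circular biased autocorrelation (the suite
verifies the identity against an explicit autocorrelation route), so
total one-sided power equals the biased variance. The dominant
frequency excludes the zero bin. The default observable averages the
per-gene spectra (constant genes dropped); short-duty-cycle genes put
weight on harmonics of the cycle frequency, so individual-seed peak
locations can land on a harmonic — trends across parameters, not exact
peak positions, are the robust output. A Hann window is available but
off by default (it breaks the exact Parseval identity asserted in the
tests).

With no pumping (`γ = 0`) the resting state only emits rare
basal-flip excursions: the spectrum is a random-telegraph profile
piling up next to DC, with no oscillatory peak. At `γ = 0.6` a clear
peak appears near the ten-step cycle frequency (~0.1 cycles/step).
Along a `γ` grid the native-loop flux, the entropy production rate and
the dominant frequency all rise together — the flux drives, and pays
for, the oscillation speed.

## Sensitivity analysis

`rank_edges_TES()` deletes each edge in turn and ranks, per metric, the
change in `RR`, `P_G1` (stationary probability of the resting state)
and `RR_flux`; the scores (largest change = `n_edges`) sum to the total
evaluation score. Defaults and their rationale:

* **absolute vs signed differences**: default absolute; the published
  ranking for this network is more consistent with signed drops in the
  `P_G1` column (deleting the checkpoint's outgoing edge *raises* `P_G1`
  strongly yet is ranked least impactful there), so `"signed"` is
  exposed, but neither direction reproduces the full published ordering
  under our reconstruction and we keep the simpler magnitude-of-impact
  reading as default.
* **lost native loop**: a mutant whose flux landscape no longer contains
  the native loop gets `RR_flux = 0` with a flag, which makes its
  `RR_flux` difference maximal — several mutants tie there, and their
  relative scores are decided purely by the tie-break.
* **tie-break**: lexicographic (source, target) edge order, applied via
  first-come ranking on the lexicographically sorted edge list, so the
  ranking is reproducible and independent of matrix storage order.

On the fixture the sweep ranks Slp1 → Cdc2/Cdc13 first with TES 72 (the
published top edge; published TES 73 — the one-point difference sits
inside the tie-break sensitivity of the flagged `RR_flux` column), and
the four least-critical published edges land in our bottom quartile.
`backbone_extract()` keeps the top `n` edges and reports whether the
deterministic biological path still runs — the cut is a user choice,
not a package constant.

## Synthetic generators and what a green test establishes

Oracle inputs are generated in code: biased rings (closed-form
stationary law, flux and entropy production), a two-loop figure-eight
chain (closed-form loop fractions), random dense chains (decomposition
identities), and random signed Boolean networks (row-stochasticity,
ergodic consistency). These cover the algebraic contracts exactly but
are small and dense; they do not emulate the extreme probability ranges
(20+ orders of magnitude) of a sharp-response Boolean chain — that
regime is exercised only through the fission yeast fixture itself.
Green tests establish the identities and the fixture's qualitative
claims (funneled landscapes, dominant native loop, monotone trends);
they do not certify the two published scalar values that our
reconstruction misses by 1–2% (kept as red assertions, see above).

## Known limitations

* Exact state-space treatment only: `2^n` states, capped at 20 nodes;
  no sampling-based approximation for larger networks.
* Discrete time throughout; rates are per step.
* The loop tail of the peeling decomposition is policy-dependent.
* Asynchronous update schemes, ODE models, sign inference from data,
  multi-edge simultaneous perturbations and landscape embedding for
  visualization are out of scope.
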