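---
title: "Bistability and dimer buffering in TBP auto-regulation: model and methods"
author: "tbpautoreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bistability and dimer buffering in TBP auto-regulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbpautoreg)
```

## The model

TATA-binding protein (TBP) is required for transcription initiation by
all three eukaryotic RNA polymerases, so its own gene cannot be
transcribed without TBP: production is autocatalytic. In solution TBP
dimerizes, and the dimer cannot bind DNA, so dimerization withholds
monomer from promoters and acts as a built-in negative regulator. The
package implements a deterministic kinetic model of this circuit with
four species — free monomer $T$, dimer $T_2$, promoter-bound TBP $TD$,
and free binding sites $D$ — and six processes:

* reversible dimerization: $2T \rightleftharpoons T_2$ with rate
  constants $k_1$ (association, M$^{-1}$s$^{-1}$) and $k_2$
  (dissociation, s$^{-1}$);
* reversible DNA binding: $T + D \rightleftharpoons TD$ with $k_3$
  (M$^{-1}$s$^{-1}$) and $k_4$ (s$^{-1}$);
* synthesis: a lumped transcription-plus-translation step producing
  monomer at rate $k_0 + k_5\, TD^{k_6} / (k_7^{k_6} + TD^{k_6})$,
  driven by the average promoter occupancy. The Hill form is
  phenomenological: it encodes a saturating, possibly cooperative
  dependence of production on bound TBP without committing to a
  promoter mechanism. $k_6$ is treated as a real number $>0$ and is
  swept continuously;
* degradation: first-order loss of the free monomer only, at $k_8$
  (s$^{-1}$). Dimerization stabilizes TBP, so dimers and bound TBP are
  not degraded.

Binding sites are conserved, $D + TD = D_0$, which reduces the four
mass balances to a three-variable system $(T, T_2, TD)$; the
four-variable form is retained (`tbp_rhs()`) so that tests can verify
conservation rather than assume it. The model tracks concentrations in
molar units and time in seconds.

The reference parameter set (`default_parameters()`) describes a
mammalian cell: roughly 25000 TBP molecules and 25000 binding sites
(site concentration $D_0 = 2.5\times 10^{-8}$ M), dimerization and
DNA-binding constants from in vitro TBP kinetics, degradation from the
reported TBP half-life, half-saturation $k_7$ at half of $D_0$,
cooperativity $k_6 = 2$, and a basal rate $k_0$ of 1% of the maximal
synthesis rate $k_5$. Many analyses set $k_0 = 0$, the natural limit if
no transcription is possible without TBP.

## Steady states

Setting the binding and dimerization reactions to equilibrium collapses
the fixed-point problem to one scalar equation in free TBP,

$$f(T) \;=\; (k_8 T - k_0)\,\bigl(k_7^{k_6} + TD(T)^{k_6}\bigr) \;-\;
 k_5\, TD(T)^{k_6} \;=\; 0,
 \qquad TD(T) = \frac{T\,D_0}{k_4/k_3 + T},$$

with the dimer pool recovered afterwards as $T_2 = (k_1/k_2)T^2$.
Neither $k_1$ nor $k_2$ appears in $f$: the dimer changes the *total*
TBP at a fixed point (by exactly $2(k_1/k_2)T^2$ in monomer
equivalents) but never the number, location (in $T$, $TD$) or stability
of the fixed points. This is tested, not assumed.

`find_steady_states()` locates roots by sign-change bracketing on a
log-spaced grid (default 2000 points on $[10^{-16}, 10^{-3}]$ M, at
least three decades beyond the physiological range on each side),
refines each bracket with `uniroot()` to $10^{-10}$ relative tolerance,
and adds the $T = 0$ root analytically when $k_0 = 0$ (a log grid
cannot bracket the origin; for $k_0 > 0$, $f(0) < 0$ rules it out).
Root pairs closer than $10^{-4}$ relative — which occur only hard
against a fold — are merged into one record with multiplicity 2 rather
than reported as two spurious states. Totals are reported in monomer
equivalents, $T + 2T_2 + TD$, the only bookkeeping under which the
dimer pool is counted by its TBP content.

At the reference constants with $k_0 = 0$ there are three states: the
zero state, an unstable low state (total $2.26\times10^{-9}$ M) and a
stable high state ($2.556\times10^{-8}$ M). With the default basal rate
the zero and low states annihilate and a single state survives, 1.3%
above the high branch.

## Dimensionless groups and critical values

Rescaling concentrations by $D_0$ and time by $1/k_8$
(`nondimensionalize()`) yields the control parameters
$K_5 = k_5/(k_8 D_0)$, $K_7 = k_7/D_0$ and the dimensionless
dissociation constant $K = k_4/(k_3 D_0)$. For the cooperative case
($k_6 = 2$, $k_0 = 0$) the saddle-node (fold) condition $f = 0$,
$f'(T) = 0$ has closed forms, re-derived here from the tangency
condition:

$$K_{5c} = 2\left(K K_7^2 + \sqrt{K^2 K_7^2 + K^2 K_7^4}\right),
\qquad
K_{3c} = \frac{2\left(K_4 K_5 K_7^2 +
  \sqrt{K_4^2 K_5^2 K_7^2 + K_4^2 K_5^2 K_7^4}\right)}{K_5^2}.$$

Below the critical value only the zero state remains; above it the
system is bistable. At the reference constants these evaluate to
$k_{3c} = 9.58\times10^4$ M$^{-1}$s$^{-1}$ and $k_{5c} =
2.39\times10^{-13}$ M s$^{-1}$. Two independent numeric routes confirm
the algebra: bisection on the positive-root count (the package's
`numeric_scan` method) and, in the test suite, a tangency oracle that
minimizes $g(T) = k_8 T (k_7^{k_6} + TD^{k_6})/TD^{k_6}$ — along the
nonzero branch $f = 0$ is equivalent to $k_5 = g(T)$, so the fold is
the minimum of $g$. The basal-rate threshold $k_{0c}$, below which
three states coexist, has no closed form and is found by bisection on
the root count over $[0, k_5]$; at the reference constants it is
$2.99\times10^{-15}$ M s$^{-1}$, i.e. $0.0060\,k_5$.

The tabulated multiplicity conditions (`predicted_multiplicity()`) use
the exact thresholds: for $k_6 = 2$, $k_0 = 0$, bistability iff
$K_5 > K_{5c}$. Numerical exploration showed the root count does not
depend on whether $K_7 < 1$, so no such clause is enforced. Counts
include the zero state whenever $k_0 = 0$ (it is always a root there);
this convention is applied consistently when predictions are compared
with `find_steady_states()`. The non-cooperative case $k_6 = 1$ gives
at most one positive root, present iff $K_5 > K_7 K$; with $k_6 = 1$
and $k_0 > 0$ the tabulated "basal rate much smaller than $K$"
condition is inherently fuzzy and is implemented as a reported
inequality at a configurable factor (default 100×), flagged
`heuristic`.

## Stability

`classify_stability()` evaluates the analytic Jacobian of the reduced
three-variable system (free sites eliminated) and classifies by
eigenvalue real parts with a sign tolerance of $10^{-12}$ s$^{-1}$
scaled by $k_8/7.4\times10^{-5}$ — far below the slowest kinetic rate
at any rescaling, so a "stable" call is never an artifact of rounding,
and near-zero real parts are reported `marginal`, never silently
stable. At the reference constants the pattern is
stable/unstable/stable (zero/low/high): the circuit is bistable, and
initial conditions below the low state's basin boundary collapse to the
zero state — a cell starting with too little TBP can never switch its
own gene on.

For $k_6 < 1$ the Hill derivative diverges at $TD = 0$, so the zero
state's Jacobian is undefined; classification falls back to numeric
perturbation (±1% of each coordinate, or $10^{-3} D_0$ for zero
coordinates, integrated to $10/k_8$ and checked for return within
0.1%). The same return/escape check is applied to every classified
fixed point as a property test.

`linearized_response_time()` gives the single-exponential estimate
$-\ln(1-\rho)/|\mathrm{Re}\,\lambda_{slow}|$ for recovering a fraction
$\rho$ of a small perturbation, with $\lambda_{slow}$ the slowest
stable eigenvalue. On a decoupled toy system (no dimerization, no DNA
binding) it is exact and the simulated response time matches it to
0.1%; on the full system it agrees with simulation in order of
magnitude (within a factor 3 in the tests), which is all a
one-eigenvalue estimate of a coupled three-variable relaxation can
promise.

## Dynamics and the response-time protocol

`integrate_tbp()` wraps deSolve's `lsoda` (stiff-capable, switching to
a BDF method as needed) with `rtol = 1e-8` and `atol = 1e-20` M — the
absolute floor sits far below the smallest physiological concentration
so near-zero species are resolved, which matters because the zero state
is itself an attractor. Site conservation holds along trajectories to
$10^{-6} D_0$ and halving `rtol` moves terminal states by less than
$10\times$`rtol`, both tested.

After the fast binding transient, trajectories collapse onto the
binding pseudo-equilibrium where $T\cdot D/TD$ equals $k_4/k_3$;
`slow_manifold_ratio()` reports the late-time ($t > 10/k_4$) median of
that ratio, excluding points with $TD < 10^{-18}$ M as numerically
meaningless.

The buffering experiment (`response_time()`,
`compare_dimer_effect()`) follows a fixed protocol: start at the stable
high state, reduce free TBP by 10% (dimer and bound pools untouched),
and measure the first time after which free TBP stays within 1% of its
steady-state value — i.e. 90% of the perturbation recovered. Recovery
is detected as *sustained* return, checked through the end of a
$50/k_8$ integration rather than at first crossing, because the
coupled relaxation can overshoot; the crossing instant is interpolated
linearly between output points (3000 log-spaced samples). The
comparison system removes dimerization entirely ($k_1 = 0$) and is
perturbed at its *own* high state, which has identical free and bound
levels. The qualitative claim under test — the dimer pool is decisive
when $T_{2ss}/TD_{ss}$ is large and irrelevant when small — is made
falsifiable with explicit bands chosen here: ratio of response times
below 0.5 whenever $T_{2ss}/TD_{ss} > 10$, and within $[0.8, 1.25]$
whenever $T_{2ss}/TD_{ss} < 0.01$. In the intermediate band the ratio
is reported but not predicted; conditions with similar dimer and bound
pools can fall on either side.

## The scenario generator

`generate_grid()` emulates the spread of cellular conditions over which
the buffering question is posed, rather than any specific tabulated
cases: site concentrations $D_0 \in [10^{-9}, 10^{-5}]$ M (from ~3000
expressed genes in a yeast cell up to dense mammalian site counts, via
$N/(N_A V)$), half-saturation $k_7 \in [10^{-2}, 10^2] \times D_0$, and
synthesis $k_5$ from just above the fold ($1.1\,k_{5c}$ at each
$(k_7, D_0)$, so a high state exists) up to $10^3\,k_{5c}$, all
log-spaced. Anchoring the $k_5$ axis at the per-cell critical value is
essential: a fixed $k_5$ range would leave most of the $(k_7, D_0)$
grid monostable-zero. Scenarios whose stable high-state total falls
inside $[10^{-8}, 10^{-5}]$ M are labeled `physiological`, the rest
`extreme`. A 3×3×3 grid spans more than three decades of
$T_{2ss}/TD_{ss}$ on both sides of the buffering thresholds, which is
what the property tests need. The construction is deterministic; the
`seed` argument is recorded for provenance. The `yeast` preset
recomputes $D_0$ from 3000 sites in a $4.17\times10^{-15}$ L cell and
rescales $k_5$ and $k_7$ proportionally to $D_0$ so the dimensionless
groups $K_5, K_7$ match the reference set, keeping the bistable regime;
the `mammalian` preset is the reference set itself.

What the generator does *not* emulate: extrinsic noise, cell-to-cell
parameter variation, chromatin-state modulation of site availability,
or stochastic copy-number effects (some corners of the grid imply few
molecules per cell, where a deterministic ODE is an idealization).
Passing the grid-based tests therefore demonstrates internal
consistency of the deterministic model across physiological parameter
space, not agreement with any particular cell's measured kinetics.

## Numerical choices and degenerate inputs

* Root scan: 2000 log-spaced points by default; the fold-refinement
  bisections use 6000 (and 20000 for $k_{0c}$, where the coalescing
  pair must stay resolvable close to the fold). Near-fold studies in
  the tests raise the grid to $4\times10^5$ points.
* Critical-value bisection refines to $10^{-7}$ relative; reported
  values are meaningful to about five significant figures for $k_3$ and
  $k_5$ (grid-resolution bias near the fold enters around
  $10^{-5}$–$10^{-6}$ relative) and to ~$10^{-3}$ for $k_{0c}$.
* $k_3 = 0$ makes the binding equilibrium degenerate; $TD(T)$ is then
  identically zero. $k_2 = 0$ with $k_1 > 0$ would make the dimer pool
  infinite at any fixed point with $T > 0$; the completion reports
  $T_2 = 0$ only when $k_1 = 0$ too, and parameter validation otherwise
  leaves such sets to the integrator, where the dimer simply
  accumulates.
* Search-range policy: roots outside $[10^{-16}, 10^{-3}]$ M are
  outside every regime studied here and are not chased; with $k_0 > 0$
  tiny basal rates can push the surviving root below $10^{-16}$ M, in
  which case an empty table is returned rather than an error.
* A root bracket on which refinement fails is kept as a flagged record
  (`converged = FALSE`) rather than dropped.

## Limitations

The model is deterministic and well-mixed; stochastic switching between
basins, which could qualitatively change survival predictions at low
copy number, is out of scope. The Hill term is phenomenological, so
$k_6$ and $k_7$ are effective constants, not measurable binding
stoichiometries. All headline numbers in this vignette are recomputed
by the test suite or by `scripts/acceptance.R`; the analysis scripts
under `analysis/` regenerate every table from scratch.
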