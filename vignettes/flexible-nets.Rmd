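---
title: "Flexible Nets: model, discretization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible Nets: model, discretization and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexnets)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the numerical choices, what the example
nets do and do not exercise, and the design decisions that were genuinely
open.

## The model

A Flexible Net separates *what a process does to the state* from *how the
state sets the speed of processes*. Both relations run through dedicated
handler vertices carrying linear inequality blocks, which is where
uncertainty lives.

**Event side.** Transitions hold actions; places hold tokens. An event
handler $v_k$ with block $(A_k, B_k)$ admits a firing with executed
amounts $a_f$ and token changes $\Delta m_f$ whenever
$A_k \Delta m_f \le B_k a_f$, enough actions and tokens are available,
and the total change is positive. Cumulating firings gives the event state
equations $\sigma = a_T + Y_\sigma a_E$, $A\,\Delta m \le B\,a_E$,
$m = m_0 + Z_m \Delta m$, with $J_m m_0 \le K_m$ on the initial marking.
These are *necessary* reachability conditions: they account for the
cumulative effect of firings, not their order, so they can admit spurious
solutions. Nothing in this package claims sufficiency; the discrete
executor is the constructive counterpart.

**Intensity side.** Tokens are either idle ($\mu_P$) or active on an
intensity edge ($\mu_E$); active tokens produce intensity changes
$\Delta\lambda$ through $C\,\Delta\lambda \le D\,\mu_E$, on top of default
intensities $\lambda_0$ constrained by $J_\lambda \lambda_0 \le K_\lambda$.
The intensity of a transition is the rate at which it produces actions:
$\sigma(\tau) = \lambda_0\tau + Z_\lambda \int_0^\tau \Delta\lambda$.

**Forced sets.** Two modeling switches recur: forced execution
($a_T[t] = 0$ for chosen transitions — produced actions may not
accumulate) and forced activity ($\mu_P[p] = 0$ — tokens may not idle).
A convention worth stating: "all tokens active" is implemented as forcing
the places that *have* intensity edges. Forcing a place with no intensity
edge pins its marking at zero identically, which is never the intended
reading (it would, for instance, forbid any production into an output
buffer).

## Discrete semantics

`is_enabled()`/`fire()` implement single firings. Under integrality the
witness search enumerates integer solutions of the handler block inside
componentwise bounds obtained by interval propagation over the rows; in
continuous mode enabling is a small LP and the strict positivity of the
total change is tested as $\ge \varepsilon$ with $\varepsilon = 10^{-9}$
(an LP cannot express a strict inequality).

`reachability_graph()` closes the `(marking, available actions)` state
under *unit* firings: each edge executes 0 or 1 action (at least one
action when the handler is linked to transitions), silent handlers consume
exactly one token, and nondeterministic production is enumerated over the
integer solutions of the block. This reproduces the published
potential-evolution graphs and keeps branching finite. Nodes are
deduplicated on `(m, a_T)`; execution histories are not part of the node,
matching the marking-level graphs. Between observations, silent firings
may interleave freely — the graph simply contains the silently reachable
states; `consistent_markings()` then filters on the observed
produced/leftover action counts. Its second route enumerates integer
solutions of the state equations directly; on every example the graph
route is contained in the equation route (necessity), and the two agree
where no spurious solutions arise.

## Transcription over a time grid

The timed analysis replaces the integral linkage by a grid
$\tau_0 = 0 < \tau_1 < \dots < \tau_n$ with, per interval:

* interval-constant $\Delta\lambda_k$, $\mu_{E,k}$, $\mu_{P,k}$,
  $\lambda_k$ — so the action integral is exact under the
  piecewise-constant assumption:
  $\Delta\sigma_{k} = \Delta\sigma_{k-1} + \Delta\lambda_k\,\Delta\tau_k$;
* intensity-handler rows coupled to the **interval-average marking**
  $\bar m_k = (m_{k-1} + m_k)/2$. This midpoint coupling makes the
  fixed-intensity limit an implicit-midpoint (trapezoidal) step, hence
  second-order accurate; the tests verify errors of $5\cdot10^{-5}$,
  $1.3\cdot10^{-5}$, $3.3\cdot10^{-6}$ at $\Delta\tau = 0.2, 0.1, 0.05$
  against the matrix-exponential solution of the control-loop cycle;
* nonnegative per-interval increments $\delta a_{E,k}$, $\delta\Delta m_k$
  satisfying the event blocks, cumulated into boundary states that satisfy
  the conservation rows. Because the event rows constrain the *cumulative*
  quantities at each boundary, actions produced during an interval may be
  executed within that same interval — the fluid reading, which avoids an
  artificial one-step transport delay.

Uncertain parameters ($\lambda_0$ inside its block, handler slack inside
the inequality blocks) are decision variables resolved by the optimizer —
the optimistic/control reading. Worst-case (robust) resolution is out of
scope. Horizon averages such as $\bar m[p]$ in objectives are
length-weighted over the grid (on uniform grids both readings coincide).

Degenerate inputs: a grid must increase strictly from 0; quadratic
objectives must be minimised (they are sums of squares, so maximisation
would be nonconvex and is rejected at construction); infeasible forced
sets surface as an `infeasible` solver status, never as a silent partial
result.

## Solvers and numerical choices

No LP solver ships with this R installation, so linear (and the occasional
integer) programs are delegated to HiGHS through the Python scientific
stack, as a batch subprocess with JSON interchange — deterministic, and
fast enough that the 90-interval resource-allocation program (about 5,000
variables) solves in roughly two seconds. Convex quadratic programs stay
in R: the equality rows (numerous and partially redundant by construction)
are eliminated with an SVD null-space reduction, near-vanishing reduced
rows are dropped, the rest normalized and deduplicated, and the reduced
inequality-only QP is solved by the dual active-set method. Feasible sets
produced by forced rows often have empty interior, which that method
rejects; a vanishing uniform relaxation (escalating through
$0, 10^{-9}, 10^{-8}, 10^{-7}$) restores an interior without materially
moving the optimum. Flat objective directions are lifted by a
$10^{-7}$-scaled ridge, a tie-break toward the minimum-norm solution.
Feasibility/optimality tolerances are the solvers' defaults (about
$10^{-8}$); conservation rows are asserted to $10^{-6}$ in tests.

Ties among alternative optima are solver-dependent. For schedule-like
results (when an allocation switches, when a buffer empties) assertions
therefore use a tolerance of one grid step.

## Receding-horizon control

`run_mpc()` rebuilds the transcription from the current marking at every
step, solves it over the configured horizon, applies the first interval
and rolls forward; uncertain $\lambda_0$ and handler slack are re-resolved
every step, which is what makes the scheme a control law rather than a
single open-loop plan. Leftover available actions are carried into the
next step's program (they are identically zero under forced execution,
which covers all shipped examples). The objective is evaluated at the
horizon end; intermediate-stage costs are not used. Convergence is
declared when the boundary marking moves less than $10^{-4}$
(infinity-norm) over 10 consecutive steps — the steady states reported by
the examples are fixed points under re-solving, which the tests check
directly (idempotence to $10^{-3}$).

## The example nets: what they cover, and what they do not

The catalogue spans the formalism's modeling repertoire: uncertain
stoichiometry with an interval initial concentration
(`fn_reaction_chain()`; the initial interval of compound A is an argument
with default `c(0.9, 1.1)`), nondeterministic production and silent moves
(`fn_event_choice()`, `fn_observer_net()`), intensity production,
transfer, splitting and synchronised choice (`fn_intensity_*()`), shared
resources with allocation freedom (`fn_resource_allocation()`, where the
omitted handler equations mean 1:1 equal-transfer throughout), and a
dynamically constrained control input (`fn_control_loop()`, where
$\lambda[t_2] \ge 0$ imposes $u \le m[p_2]/2$ with no explicit rule).

These are small, noise-free, desk-scale systems. Passing on them shows the
machinery is exact on its own terms — printed matrices entry-for-entry,
marking sets by exhaustive enumeration, schedules on the grid, fixed
points within publication rounding. It does not demonstrate scalability to
genome-scale networks, robustness to adversarial parameter resolution, or
the behaviour of genuinely stochastic systems, all of which are outside
the model class implemented here (state variables are nonnegative reals;
spurious state-equation solutions remain possible by design).

## Known limitations

* Reachability answers are one-sided: a marking outside the polytope is
  certainly unreachable; one inside may still be spurious.
* The single-time system (`fn_polytope_at()`) deliberately leaves
  $\Delta\sigma$ linked only by sign, not by $\tau$; time linkage is the
  transcription's job, and single-time optima over produced actions can
  be unbounded as a result.
* Integer enumeration relies on interval propagation to bound the search
  box; pathological blocks that bound no variable raise an error rather
  than search forever.
* The QP path is dense (SVD of the equality matrix) and intended for the
  moderate problem sizes receding-horizon steps produce; long-horizon
  quadratic programs should be reformulated or solved linearly.
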