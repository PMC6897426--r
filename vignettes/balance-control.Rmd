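---
title: "Delayed-feedback balance control: model, criticality and co-adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed-feedback balance control: model, criticality and co-adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pendelay)
```

## The model

Quiet human stance in the sagittal plane is modelled as a single inverted
pendulum rotating about the ankles. Linearized about an equilibrium lean
angle, the ankle angle $\theta$ obeys

$$
\ddot\theta \;=\; \frac{\theta}{\tau_{mech}^2}
\;-\; d_M\,\dot\theta
\;-\; p\,\theta(t-\tau_{delay})
\;-\; d\,\dot\theta(t-\tau_{delay})
\;-\; a\,\ddot\theta(t-\tau_{delay})
\;-\; i\int_0^t \theta(u-\tau_{delay})\,du ,
$$

where all gains are per unit of rotational inertia $J$. The left part of
the right-hand side is the plant: gravity destabilizes the pendulum with
the mechanical time constant

$$
\tau_{mech} = \sqrt{\frac{J}{mgL\cos\Theta_0 - k}}
            = \frac{\tau_{m,0}}{\sqrt{1 - k/K_{crit}}},
\qquad
K_{crit} = mgL\cos\Theta_0 ,
$$

so passive ankle stiffness $k$ slows falling, up to the critical
stiffness $K_{crit}$ at which the restoring torque exactly cancels the
torque of weight and $\tau_{mech} \to \infty$. The remaining terms are
neural feedback (proportional, derivative, and optionally acceleration
and integral), which acts only after the response delay
$\tau_{delay}$. During that delay the body falls freely along the
hyperbolic closed form implemented in `free_fall()`, and a perturbation
aligned with the growing mode is amplified by
$e^{S}$ with

$$
S = \frac{\tau_{delay}}{\tau_{mech}}
$$

the *relative speed* of the plant with respect to the loop. $S$ is the
single dimensionless number that governs the whole problem: scaling time
by $\tau_{delay}$ turns the closed loop into a family parametrised by
$S$ and the dimensionless gains $P = p\,\tau_{delay}^2$,
$D = d\,\tau_{delay}$, $A = a$, $I = i\,\tau_{delay}^3$.

Two conventions are worth stating explicitly because everything numeric
depends on them:

* **Units.** All internal computation is in normalized units: torques are
  divided by $mgL\cos\Theta_0$ (so the weight torque *is* $\theta$) and
  gains are per unit inertia. `from_anthropometrics()` is a thin adapter
  from dimensional quantities. The default base time constant is
  $\tau_{m,0} = 1/\sqrt{9.81}\,\mathrm{s} \approx 0.32$ s exactly (a
  point mass at 1 m with $J = mL^2$), not the rounded 0.32: only the
  exact value reproduces the reference gain $p = 8.08$.
* **Critical stiffness.** $k = K_{crit}$ is represented by the $S = 0$
  code path everywhere (all formulas are continuous in $S$ at 0), never
  by a literal infinite $\tau_{mech}$.

## Stability region

For pure delayed PD control the stable region in the $(P, D)$ plane at a
given $S$ is bounded by the static line $P = S^2$ (below it the total
proportional action cannot hold up the weight) and by the oscillatory
boundary, parametrised by the dimensionless frequency
$x = \omega\,\tau_{delay} > 0$:

$$
P(x) = (x^2 + S^2)\cos x, \qquad D(x) = (x^2 + S^2)\frac{\sin x}{x}.
$$

`is_stable()` decides membership geometrically: the first arc of the
parametric curve ($x \in (0, \pi]$, 2000 samples, prefixed by its
$x\to 0^+$ corner at $(S^2, S^2)$) is closed into a polygon, membership
is decided by even-odd ray casting intersected with the half plane
$P > S^2$, and the distance to the nearest boundary is returned as a
margin diagnostic. Points within `tol` (default $10^{-6}$) of a boundary
are flagged as unreliable. This is deliberately *not* a rightmost-root
computation for the transcendental characteristic equation: the
boundaries are closed-form, and an independent long-horizon simulation
oracle validates the geometry in the test suite. The region is empty for
$S \ge \sqrt 2$, consistently with the criticality algebra below.

## Generalized critical damping

A second-order system is critically damped when its characteristic
polynomial has a unique double negative root: the fastest return without
oscillation. The delayed loop is infinite-dimensional, so the delay is
first replaced by a Padé rational approximant — first order,
$e^{-X} \approx (1 - X/2)/(1 + X/2)$, for the PD, damped-PD and PID
variants; second order for PDA, where the loop order demands it. With
$X = \tau_{delay}\lambda$ the characteristic equation becomes a cubic or
quartic, and criticality generalizes to a unique negative root
$-\omega_0$ of full multiplicity $n$:

* **PD** (`pd_critical()`): matching
  $X^3 + X^2(2-D) + X(2D - P - S^2) + 2(P - S^2) = (X+\omega_0)^3$
  gives the closed form
  $\omega_0 = -2 + (16 - 4S^2)^{1/3}$ (unique real cube-root branch),
  $D_{crit} = 8 - 3(16-4S^2)^{1/3}$,
  $P_{crit} = 4 - S^2 + 6(16-4S^2)^{1/3} - 3(16-4S^2)^{2/3}$.
  $\omega_0 > 0$ requires $S < \sqrt 2$.
* **PD + mechanical damping, PDA, PID**
  (`pd_damped_critical()`, `pda_critical()`, `pid_critical()`): the
  analogous 3- or 4-equation coefficient matches are solved by a damped
  Newton iteration (central-difference Jacobian, tolerance $10^{-12}$,
  at most 200 iterations, step halving) seeded from the PD closed form
  with $A = 0$ or $I = \omega_0^4/2$. Seeding from the continuously
  connected PD solution selects the physical branch of the PID system
  when several exist; solutions leaving $\omega_0 > 0$, $I \ge 0$ are
  rejected. Every returned solution carries the maximum absolute
  coefficient-matching `residual` (required $< 10^{-10}$); the test
  suite additionally verifies by `polyroot()` that all roots cluster at
  $-\omega_0$ (an $n$-fold root is conditioned like
  $\mathrm{residual}^{1/n}$, so the clustering tolerance is
  $5\times10^{-4}$, far looser than the coefficient residual).

The recovery time is $\tau_{balance} = \tau_{delay}/\omega_0$ in
seconds: the multiple root lives in $X$-units, and the change of
variable fixes the scale. Acceleration feedback raises $\omega_0$
(faster recovery, larger $P$ and $D$); integral feedback lowers it;
mechanical damping raises it — the suite asserts these orderings across
$S \in [0, 1.3]$.

## Co-adaptation solvers

Two inverse problems close the loop between stiffness, delay and gains:

* `stiffness_for_critical_p()` finds the stiffness fraction at which a
  prescribed per-inertia proportional gain is exactly critical.
  $P_{crit}$ increases with $S$ and $S$ falls with stiffness, so
  $p_{crit}(k_{frac})$ is strictly decreasing and the root is bracketed;
  `stats::uniroot()` (Brent) solves it to $10^{-12}$. The achievable
  range is reported in the error message when the target is outside it.
* `stiffness_for_constant_S()` is the closed form
  $k_{frac} = 1 - (\tau_{m,0} S / \tau_{delay})^2$: raising stiffness
  with the delay so that $S$ — and therefore every dimensionless
  quantity, including the normalized response shape and the peak CoM
  excursion — is unchanged. `S_target = 0` returns exactly
  $k_{frac} = 1$, the critical-stiffness boundary, which is a valid
  configuration throughout the package; the error is reserved for
  targets that would need negative stiffness.

## Simulating the delayed loop

`simulate_balance()` integrates the closed loop by the method of steps.
Choices that matter:

* **Perturbation convention.** The history is identically zero for
  $t < 0$; at $t = 0$ the angle jumps to the perturbation amplitude
  (default 1) with chosen initial velocity. Feedback contraction is
  therefore exactly zero on $[0, \tau_{delay})$, and the centre of
  pressure during the delay is purely elastic,
  $k_{frac}\,\theta$.
* **Grid.** The step is snapped to an integer divisor of the delay
  (default $\tau_{delay}/200$, at least $/100$ enforced) and the horizon
  is rounded up to a whole number of delay intervals (default 6 s), so
  every solution kink — the multiples of $\tau_{delay}$ where the
  delayed forcing switches on — is a grid node and refined grids nest
  exactly.
* **Stepping and history interpolation.** Classical 4th-order
  Runge–Kutta inside each delay interval; delayed states at half-steps
  are taken from the stored history by cubic Hermite interpolation
  (angle from angle + velocity, velocity from velocity + stored
  right-hand-side acceleration). The delayed acceleration needed by PDA
  control comes from the recorded acceleration history (linear
  interpolation between nodes), not from differencing, which would lose
  order at the kinks.
* **One-sided limits at kinks.** At a kink node the acceleration has two
  one-sided values; both are stored, and each Runge–Kutta stage uses the
  limit belonging to the delay interval being integrated. No stage ever
  evaluates across a discontinuity; index arithmetic is exact (integer
  and half-integer grid positions), so there are no floating-point
  tolerance games in the lookups.
* **Divergence.** Unstable runs are flagged (`diverged`), not raised;
  peaks then cover the pre-divergence span.

`convergence_check()` reruns at $dt/2$ and $dt/4$ and reports the
successive trace differences; at the default resolution the PD error is
of order $10^{-13}$ and the PDA error (limited by the linear
interpolation of the delayed acceleration, a second-order term)
around $10^{-8}$ — both far below the $10^{-6}$ requirement, and
refinement must shrink the error or an error is raised.

The torque decomposition is a direct restatement of the model: weight
torque $= \theta$, stiffness torque $= k_{frac}\theta$, contraction
torque $= \tau_{m,0}^2$ times the per-inertia feedback law (because
$mgL\cos\Theta_0 = J/\tau_{m,0}^2$), and the CoP torque is the sum of
the last two. Peak statistics are signed maxima of the dense traces, the
convention under which the published peaks reproduce.

`classify_response()` labels runs as `unstable` (growth beyond 10 times
the perturbation or overflow), `oscillatory` (more than one zero
crossing beyond the settling tolerance), `sluggish` (settling more than
3 times slower than the critically damped PD run for the same plant) or
`critical-like`. The sluggish regime is meaningfully probed at high
stiffness; at low stiffness a strongly reduced proportional gain falls
below the static stability line and is genuinely unstable rather than
slow.

## Strategy tables and sweeps

`build_table1()` composes the challenging-conditions comparison: the
reference system (50% stiffness, 0.14 s delay, critical PD gains), a
*gain decrease* (proportional gain cut by 15%), and the *co-adaptation*
that makes the reduced gain critical again by raising stiffness. The
gain target is the exact 15%-reduced reference gain
($0.85 \times 8.0840 = 6.8714$), not the 2-decimal printed value — the
distinction moves the co-adapted stiffness from 63.4% to 63.5% of
critical, so it matters at the printed precision. The gain-decrease row
applies the *co-adapted* gain pair at the un-adapted stiffness: that is
the construction under which the printed derivative gain (3.46, the
co-adapted critical value, not $0.967\times$ the reference) and both of
its peak excursions reproduce.

`build_table2()` composes the increased-delay comparison (+20%): *no
adaptation* (old gains at the new delay, which turns the response
oscillatory), *gain adaptation* (critical gains at the new delay), and
*co-adaptation* (constant-$S$ stiffness increase plus its critical
gains, which leaves the peak CoM excursion identical to the reference by
the invariance argument above).

`scenario_changes()` recomputes percent changes from the raw values on
every call (gains and peaks relative to the reference, stiffness in
percentage points of critical stiffness). On printed precision: the
published peak cells are evidently *truncated* toward zero at two
decimals (the no-adaptation peak CoP converges to 1.7692 on all grids
and under an independent integrator, and its printed change cell +5.7%
confirms the raw value, yet the table prints 1.76), while the gain cells
are rounded (3.1471 prints as 3.15). The test suite compares peaks by
truncation and gains by rounding; the package itself always returns raw
values.

`sweep_critical()` fills stiffness-by-delay surfaces of
$\tau_{balance}$, critical gains and (optionally) simulated peaks, with
cells at $S \ge \sqrt 2$ left `NA`. Two monotonicity caveats the
surfaces make visible: the decrease of peak CoP with delay at fixed
stiffness is local (it reverses for delay increases beyond roughly
35%, as the peak migrates onto later feedback-arrival kinks), and all
gain surfaces fall monotonically with both stiffness and delay — the
core of the co-adaptation argument.

## Multi-joint systems

`modal_decompose()` treats
$\tau_{delay}^2\,\ddot{\boldsymbol\theta} = M\boldsymbol\theta -
\boldsymbol C$: in the generic case where $M^{\mathsf T}$ is
diagonalizable with real eigenvalues $s_i$ and eigenvectors
$\boldsymbol e_i$, the projections
$\alpha_i = \boldsymbol e_i^{\mathsf T}\boldsymbol\theta$ evolve as
independent single-joint loops with $S_i = \sqrt{s_i}$. Mode order
(descending $s_i$) and sign (first nonzero component positive) are
fixed for deterministic output; complex pairs and defective matrices
(eigenbasis reciprocal condition below $10^{-8}$) are rejected rather
than approximated. `modal_critical_gains()` solves each mode and
recombines the per-mode gains into physical gain matrices
$K = (E\,\mathrm{diag}(g)\,E^{-1})^{\mathsf T}$; modes with
$s_i \le 0$ are flagged non-pendulum-like and handled through the
$S = 0$ path for gain design, while `simulate_modal()` (which replays
each mode through the 1-D integrator and recombines) requires
$s_i \ge 0$, since a negative modal stiffness has no single-pendulum
counterpart. The test suite verifies recombination against a fully
coupled delayed simulation integrated independently with
`deSolve::dede()`.

## What the generated fixtures do and do not emulate

The package needs no external data: parameter grids, gain probes and
scenario configurations are generated deterministically
(`generate_fixtures()`, seeded). These fixtures represent the model's
own parameter space — stiffness fractions, delays in the physiological
0.1–0.3 s range, gains around the stable region. They do not emulate
any feature of real posturography: no sensor noise, no torque or CoP
saturation (the foot has finite length), no stiffness nonlinearity at
large sway, no stepping. Passing tests therefore demonstrate the
internal consistency of the linearized model and the exact
reproduction of its published consequences, not agreement with
experimental sway data.

## Problem sizes and limitations

Test problem sizes are the package's own choices: simulations run at
$dt = \tau_{delay}/200$ over 6 s (tables) or shorter diagnostic
horizons; the stability-membership check against the simulation oracle
uses a $10\times10$ gain grid per $S \in \{0, 0.3, 0.7, 1.0, 1.3\}$
with a $60\,\tau_{delay}$ horizon, excluding points within 0.1 of a
boundary, where the oracle itself (late-to-early amplitude ratio) is
conclusive; modal equivalence uses random 2×2 and 3×3 systems with
positive, well-separated eigenvalues.

Known limitations, all inherited from the linearization: the model is
valid for small perturbations only; ankle stiffness is constant; the
CoP is unbounded; criticality is defined through the Padé polynomial,
not the exact transcendental characteristic equation (the exact
rightmost root of the critically tuned loop is close to, but not
exactly, $-\omega_0/\tau_{delay}$); and stability regions are computed
for the PD variant only.
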