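---
title: "Delay-induced dynamics in a tumor-immune interaction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-induced dynamics in a tumor-immune interaction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tidelay)
```

## The model

The package studies a three-component model of the interaction between a
growing tumor and the cytotoxic arm of the immune system. Immature T
lymphocytes are produced at a constant rate and mature at a fixed
per-capita rate; mature T lymphocytes kill tumor cells through mass-action
kinetics and are themselves inactivated by the encounter; tumor cells grow
exponentially in the absence of immune pressure; and the tumor recruits
additional immature lymphocytes through a term that saturates in tumor
burden. Both the recruitment and the kill interaction act after a discrete
lag $\Delta$: the time the immune system needs to recognize tumor antigen
and mount an effective response. After nondimensionalization the system is

$$
\begin{aligned}
x'(t) &= -x + \frac{y(t-\Delta)\, z(t-\Delta)}{1 + z(t-\Delta)},\\
y'(t) &= a_1 x - a_2 y + a_3,\\
z'(t) &= a_4 z - y(t-\Delta)\, z(t-\Delta),
\end{aligned}
$$

where $x$ is a scaled *deviation* of immature lymphocytes from their
tumor-free resting level (and may be negative), $y$ is the scaled mature
lymphocyte level, and $z$ the scaled tumor burden. The four dimensionless
rates are $a_1$ (maximum recruitment), $a_2$ (inactivation of mature
lymphocytes), $a_3$ (constant production of immature lymphocytes), and
$a_4$ (tumor growth); all are positive, and $\Delta \ge 0$. An initial
*history* — the state on $[-\Delta, 0]$ — closes the problem;
`dde_solve()` defaults to a constant history at the relevant equilibrium
perturbed by $+0.01$ per component, because the reference simulations
state parameter values but never their histories. Regime classifications
are insensitive to this choice; exact trajectories are not, and the
package makes no claim to reproduce any particular published trajectory.

## Equilibria and regimes

The tumor-free equilibrium $E_1 = (0, a_3/a_2, 0)$ always exists and is
stable precisely when $a_3 > a_2 a_4$ (production outruns tumor growth:
spontaneous regression). The coexistence ("co-axial") equilibrium

$$
E_2 = \left(\frac{a_2 a_4 - a_3}{a_1},\; a_4,\;
      \frac{a_2 a_4 - a_3}{a_3 + a_1 a_4 - a_2 a_4}\right)
$$

exists when numerator and denominator are both positive. Two printed forms
of the lower existence bound circulate, $(a_2 - a_1) a_4 < a_3$ and
$a_2 - a_1 a_4 < a_3$; they are not the same expression, but the first is
algebraically identical to the positivity of the $E_2$ denominator, so the
package adopts numerator/denominator positivity as the operative condition
and treats the second form as a typographical variant. On boundary
equalities the equilibria merge and `compute_equilibria()` flags the
regime `BOUNDARY` rather than returning a coincident duplicate, because
every downstream stability formula divides by a quantity that vanishes
there. The origin is a genuine fixed point only in the degenerate limit
$a_3 = 0$ (otherwise $y' = a_3 > 0$ there); it is reported accordingly,
while its formal Jacobian eigenvalues $(-1, -a_2, a_4)$ remain available.

## The characteristic function, reduced and full

Linearizing about $E_2 = (\hat x, \hat y, \hat z)$ gives a linear
constant-lag system whose characteristic matrix is
$J_0 + J_1 e^{-\lambda\Delta} - \lambda I$. Expanding the determinant
yields

$$
\lambda^3 + (A + B e^{-\lambda\Delta})\lambda^2
          + (C + D e^{-\lambda\Delta})\lambda
          + (E + F e^{-\lambda\Delta})
          - G\, e^{-2\lambda\Delta} = 0,
$$

with the six first-harmonic coefficients of `char_coeffs()` and a
second-harmonic coefficient
$G = a_1 \hat y \hat z^2/(1+\hat z)^2 = (a_2 a_4 - a_3)^2/(a_1 a_4)$,
which is the $2\times 2$ minor of the two delayed Jacobian columns. The
closed-form crossing analysis implemented here — the auxiliary cubic in
$m^2$, the critical-delay table, the transversality sign, and the
delay-length bound — is built on the *reduced* characteristic function
that drops $G$, which is what makes those quantities expressible in closed
form. The package keeps both variants explicit (`char = "reduced"` /
`"full"` wherever a characteristic function is evaluated) for two reasons:

* at $\Delta = 0$ only the full cubic matches the exact Jacobian spectrum
  (the constant terms differ by exactly $G$), so consistency tests against
  `eigen()` must use it;
* the reduced crossing estimate can be off by a material factor when $G$
  is not small against $F$. For the delay-switch rate set
  $(a_1, a_2, a_3, a_4) = (0.4, 0.6, 3.5, 7.0)$ the reduced analysis
  gives $m_0 = 0.6928$, $\Delta_0 = 0.01275$, while the exact crossing of
  the full characteristic function (a two-dimensional Newton refinement
  seeded at the reduced pair, reported by `critical_delays()` as
  `omega_star`, `delta_star`) is $\omega^* = 0.6651$,
  $\Delta^* = 0.03730$. Simulated stability switches track $\Delta^*$, and
  the package's sweep classifiers therefore judge delayed stability by the
  rightmost root of the full characteristic function rather than by
  comparing $\Delta$ with the reduced $\Delta_0$.

```{r crossing}
p <- ti_params(0.4, 0.6, 3.5, 7.0)
critical_delays(p)
```

Whenever $E_2$ exists, $F > |E|$, so the auxiliary-cubic constant
$p_2 = E^2 - F^2$ is negative and at least one crossing frequency always
exists: delay-induced instability is generic for this model, and the
transversality sign is $+1$ at every crossing with $p_0 \ge 0$ (roots only
ever move rightward with increasing delay). The quadrant ambiguity of the
scalar-arctangent form of the critical delay is avoided by solving the
crossing system exactly as a $2\times2$ linear system in
$(\cos m_0\Delta, \sin m_0\Delta)$ and applying a two-argument
arctangent; the identity $\cos^2 + \sin^2 = 1$ then holds exactly when
$m_0$ solves the auxiliary cubic, and is verified to $10^{-9}$ on every
call.

## Delay-length bound

A Nyquist-style argument bounds the frequency of a marginal mode by
$\zeta_+$ and the stability-preserving delay by
$\Delta_+ = \{-\chi_2 + (\chi_2^2 + 4\chi_1\chi_3)^{1/2}\}/(2\chi_1)$,
where $\chi_3$ is algebraically the third Routh–Hurwitz margin
$(A+B)(C+D) - (E+F)$ (computed once and reused, rather than transcribing
the long printed expression twice). Two caveats are surfaced rather than
resolved silently:

* the $\zeta_+$ formula requires $|A| > |B|$, i.e.
  $|1 + a_2 - a_4| > a_4$; for delay-dominated sets such as the
  delay-switch scenario it is undefined, and `delay_length_bound()` either
  raises a classed error or returns a partial result with the margin
  $\chi_3$ only;
* the printed $\chi_2$ has a missing operator between
  $a_1\hat z/(1+\hat z)$ and $(1+a_2-a_4)\hat y$ inside its first brace.
  The default reading takes the literal token sequence as a product; the
  alternative reads the gap as a minus sign, which gives $|D - AB|$ — the
  combination a re-derivation of the inequality produces. Both are always
  computed and reported (`chi2`, `chi2_alt`), with `grouping` selecting
  the one used for $\Delta_+$.

Where defined, the bound is conservative: for
$(0.8, 1.0, 0.5, 0.9)$, $\Delta_+ = 0.0068$ against a first crossing at
$\Delta_0 = 0.28$, and the rightmost characteristic root stays strictly
negative on a grid over $[0, \Delta_+]$.

## Hopf normal form

At a critical delay the center-manifold reduction gives the first
Lyapunov quantity $c_1(0)$ and the classification numbers
$\mu_2 = -\mathrm{Re}\,c_1(0)/\mathrm{Re}\,\lambda'(\Delta_k)$
(supercritical iff $\mu_2 > 0$), $\beta_2 = 2\,\mathrm{Re}\,c_1(0)$
(stable cycle iff $\beta_2 < 0$) and the period coefficient $T_2$. Three
implementation decisions matter here, all following the principle that
the direct solve and the Taylor expansion of the actual right-hand side
are authoritative over printed closed forms:

* **Exact crossing pair.** The eigenvector systems are consistent only at
  an exact root of the untruncated characteristic function, so the
  reduced-form $(m_0, \Delta_k)$ is Newton-refined before the
  computation (`refine = TRUE`, the default). At the unrefined pair the
  eigen-residuals are $O(G)$ and the package reports them as such rather
  than proceeding silently.
* **Eigenvectors by direct solves.** $v = (1, v_1, v_2)^T$ and the
  adjoint $v^*$ come from null-space solves of the characteristic matrix
  and its transpose. The printed closed form for $v_1$ is reproduced
  exactly; the printed $v_2$ and $v_2^*$ forms are not (one drops an
  $a_4$ from the resolvent denominator, the other also carries
  $(1+\hat y)^2$ where the Jacobian entry has $(1+\hat z)^2$), and
  `hopf_normal_form()` records the deviations in `printed_checks` and
  warns. The bilinear pairing is evaluated through its single
  delayed-point correction term — the spectral measure is concentrated at
  $\theta = 0$ and $\theta = -1$, so no quadrature is involved — and the
  identities $\langle v^*, v\rangle = 1$,
  $\langle v^*, \bar v\rangle = 0$ are checked to $10^{-9}$.
* **Quadratic and cubic coefficients from the rhs.** Taylor-expanding
  $y z/(1+z)$ at $E_2$ gives quadratic terms
  $u_2 u_3/(1+\hat z)^2 - \hat y\, u_3^2/(1+\hat z)^3$ and cubic terms
  $-u_2 u_3^2/(1+\hat z)^3 + \hat y\, u_3^3/(1+\hat z)^4$ for the first
  component (the third component's nonlinearity is exactly $-u_2 u_3$).
  Printed normal-form computations for this model drop the
  $(1+\hat z)$-dependent factors and the $u_3^2$ term; the package keeps
  them. For the same reason the constant vectors of the second-order
  center-manifold terms are obtained from the re-derived systems
  $(2i\omega_0 I - J_0 - J_1 e^{-2i\omega_0\Delta_k})E_1 = F_{20}$ and
  $(J_0 + J_1)E_2 = -F_{11}$, whose residuals are checked to $10^{-10}$;
  the undefined symbol $q(0)$ appearing in the printed $W$-expansion is
  read as $v(0)$, the only reading consistent with a Hassard-style
  computation.

$\lambda'(\Delta_k)$ is evaluated by implicit differentiation of the
characteristic function in use; the printed closed form of its inverse is
kept as `lambda_prime_closed_form()` and agrees with implicit
differentiation of the reduced function to machine precision, and with a
finite difference of the tracked root to about two significant figures.

For the delay-switch set the result is a supercritical bifurcation
shedding a stable limit cycle with increasing period
($\mu_2 > 0$, $\beta_2 < 0$, $T_2 > 0$), which the test suite
cross-validates by simulation: trajectories settle on $E_2$ at
$0.9\,\Delta^*$, settle on a bounded cycle at $1.1\,\Delta^*$, and the
squared cycle amplitude grows linearly in $\Delta - \Delta^*$ over
$[1.025, 1.2]\,\Delta^*$ ($R^2 > 0.99$ on 8 points).

```{r hopf}
nf <- hopf_normal_form(p, warn = FALSE)
nf
```

## Numerical integration

For $\Delta > 0$ the integrator uses the method of steps with a classical
fourth-order Runge–Kutta step of fixed width $h = \Delta/n$,
$n = \lceil \Delta/\texttt{max\_step} \rceil$ (default
`max_step = 0.01`). Breakpoints at integer multiples of $\Delta$, where
derivative discontinuities propagate from the history junction, are then
mesh points by construction. Delayed stage values are stored nodes for the
first and last stages and interval midpoints for the middle stages, where
a cubic Hermite interpolant of the stored solution (values and slopes) is
locally $O(h^4)$ — matching the step order, so the observed convergence
order under step halving is $\ge 3$ (measured $\approx 3.6$–$4$ on the
delay-switch scenario). The constraint $h \le \Delta$ (not $\Delta/4$)
suffices for explicitness: the final stage of a step needs the delayed
state no later than the current node. History nodes keep their own slope
array so the derivative jump at $t = 0$ never enters an interpolation
stencil. At $\Delta = 0$ the system is an ODE and is handed to
`deSolve::lsoda()` under `rtol`/`atol` control; at $\Delta = 10^{-6}$ the
two paths agree to better than $10^{-5}$ in sup-norm over $[0, 20]$.

Unbounded growth is a *reported outcome*, not an error: the immune-escape
regime is biologically meaningful, so when a component exceeds the
overflow guard ($10^8$) the trajectory is truncated and flagged
`diverged`. Trajectory summaries analyze the final half (by default) of a
run: `steady` when the largest component amplitude falls below $10^{-4}$
relative to the attractor-mean norm, `divergent` on truncation or window
values beyond $10^6$, `oscillatory` otherwise, with the period estimated
from prominent peaks of $z$ (prominence $\ge 1\%$ of the window range,
three peaks minimum).

### Positivity, and where it fails

From a componentwise-nonnegative history, $x$ stays nonnegative, and so
do $y$ and $z$ *in the regime the model is studied in*: across the four
packaged rate sets, delays in $[0.005, 0.05]$ and constant histories drawn
uniformly from $[0, 2]^3$, the minimum of $y$ and $z$ over hundreds of
seeded trajectories is exactly nonnegative. The claim is not uniform in
the parameters, however: $z' = a_4 z - y(t-\Delta)z(t-\Delta)$ carries a
*lagged* sink, and when the growth-per-delay $a_4\Delta$ is large the
delayed product keeps firing after $z(t)$ has collapsed, driving $z$
through zero (for example $a = (13.5, 0.23, 0.80, 13.96)$,
$\Delta = 0.049$, history $(0.23, 0.95, 1.12)$ — confirmed with an
independent DDE solver). The test suite asserts positivity under the
study conditions and separately documents the overshoot regime as genuine
model behavior.

## Sweeps and regime maps

`branch_sweep()` follows the $E_2$ branch in one parameter, attaching the
analytic verdict and, for unstable points, simulated cycle extrema;
`region_map_2d()` classifies a grid over two parameters as `steady`
(a stable equilibrium: $E_2$ stable at the configured delay, or only
$E_1$ with $a_3 > a_2 a_4$), `oscillatory` ($E_2$ exists, unstable), or
`no-E2` (no coexistence equilibrium and $E_1$ unstable: immune escape).
Classification is analytic-first — region diagrams would be wasteful to
simulate cell by cell — with an opt-in simulation audit of randomly
chosen cells (horizon 1500 by default, since near-boundary cells decay or
grow arbitrarily slowly). An interesting feature of this model is that
the *reduced* Routh–Hurwitz margin at $E_2$ is independent of $a_1$
(all six reduced coefficients are), so the bifurcation structure along
$a_1$ — a Hopf point near $a_1 = 0.294$ for the oscillation-base set,
with cycle amplitude decreasing beyond it — is carried entirely by the
second-harmonic term $G = (a_2a_4 - a_3)^2/(a_1 a_4)$. This is another
reason the sweep classifiers use the full characteristic function.

In parts of the oscillatory region far from the packaged base sets the
bounded-cycle assumption itself fails — the cycle's $z$-collapse deepens
until the lagged kill term drives $z$ through zero, and the trajectory
leaves the physical region. The packaged two-parameter window
($a_1 \in [0.02, 0.30]$, $a_2 \in [0.35, 1.0]$ at the oscillation base)
was chosen to display the cusp-shaped oscillatory region while staying
within the bounded regime; the audit there agrees with the analytic
classes at 100%.

## Problem sizes and tolerances used by the tests

Property tests draw rates log-uniformly from $[10^{-2}, 10^2]$ ($10^4$
draws for equilibria, $10^3$ for crossing existence) under fixed seeds
recorded in the tests. Fixed-point residuals are asserted at $10^{-12}$
(relative, since coordinates reach $10^4$ at the draw extremes), crossing
residuals at $10^{-8}$ to $10^{-9}$, eigenvector and center-manifold
residuals at $10^{-10}$. Simulation-facing checks use horizons of 50
(positivity, convergence), 400 (scenario regimes and branch extrema),
1500 (cell audits) and 3000 (amplitude-scaling near the crossing) time
units — long enough that the slowest mode in each check has decayed or
saturated by a comfortable margin. Newton root searches default to a
$41\times41$ seed grid on $[-5, 2] \times [0, 4\max(m_0, 1)]$ with
tolerance $10^{-12}$ and 100 iterations, all configurable.

## Known limitations

* The closed-form crossing machinery quantifies the printed
  six-coefficient reduction; its $\Delta_0$ is a reliable threshold only
  when $G \ll F$. The refined `delta_star` and the full-characteristic
  rightmost root are the quantities to trust against simulation.
* Normal forms are computed for the first crossing branch by default;
  higher branches ($k \ge 1$) are tabulated but degenerate (Bautin-type)
  situations are not analyzed.
* The region maps export boundary cells, not a continued Hopf curve;
  pseudo-arclength continuation is out of scope.
* Stochastic perturbations, treatment terms, fractional-order derivatives
  and spatial diffusion are out of scope.
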