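---
title: "Delayed reaction-diffusion dynamics of cancer stem cells: model, analysis and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed reaction-diffusion dynamics of cancer stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cscdelay)
```

## The model

`cscdelay` implements a four-field model of tumor-cell plasticity on a
square tissue domain with no-flux boundaries. The fields are the
concentrations of cancer stem cells $S$, differentiated cancer cells
$D$, Wnt–$\beta$-catenin pathway activator $a$, and microRNA $m$ (cells
or molecules per mm$^3$; time in years, space in mm):

$$
\begin{aligned}
\partial_t S &= (2p(D,a)-1)\,\varepsilon S
  + q(m(t-\tau))\,D(t-\tau) + D_S\Delta S,\\
\partial_t D &= 2(1-p(D,a))\,\varepsilon S - (d+q(m))\,D + D_D\Delta D,\\
\partial_t a &= a\!\left(\beta S \tfrac{a}{1+a} - \alpha\right)
  + D_a\Delta a,\\
\partial_t m &= \gamma e^{-S/S_0} - \alpha m + D_m\Delta m,
\end{aligned}
$$

with the symmetric self-renewal probability and the sigmoidal
dedifferentiation rate

$$
p(D,a) = \frac{\eta a}{(1+\eta a)(1+\psi D)}, \qquad
q(m) = \frac{q_0}{2}\left(1 + \tanh\frac{m - m_0}{\sigma}\right).
$$

A stem-cell division yields two stem cells with probability $p$
(activated by $a$, braked by crowding of differentiated cells through
$\psi$). Differentiated cells die at rate $d$ and *dedifferentiate* back
to the stem state at rate $q(m)$: the plasticity feedback. The delay
$\tau$ is the biological lag between microRNA–DC interaction and the
appearance of new stem cells; it is the central bifurcation parameter.
The microRNA field is produced at rate $\gamma e^{-S/S_0}$ — production
switches on when the stem pool falls below the scale $S_0$ — and both
signalling species degrade at rate $\alpha$. Note that $\alpha$ acts
throughout as a first-order rate (year$^{-1}$), even though unit lists
for this model sometimes carry it as mm$^3$/molecule; the package treats
it as year$^{-1}$.

Defaults (see `csc_params()`) are the reference values: $\eta = 1$,
$\psi = 0.5$, $\varepsilon = 1$, $m_0 = 0.05$, $\alpha = 0.3$,
$\beta = 1$, $\gamma = 1$, $\sigma = 0.05$, $S_0 = 0.038$,
$D_S = D_D = 0.031536$, $D_a = D_m = 0.365$ mm$^2$/yr, with the
cancer-specific pairs $(q_0, d)$: prostate $(87.6, 87.2)$, lung
$(109.97, 80)$, breast $(70.39, 45)$ yr$^{-1}$ (`cancer_params()`).

## Equilibria and a consistency subtlety

The homogeneous system has three equilibrium families
(`equilibrium_E1/E2/E3()`). The biologically central one is
$E^{(2)} = (S_2, D_2, 0, m_2)$ with
$S_2 = -S_0\ln(\alpha m_2/\gamma)$ and $D_2 = S_2/d$, describing an
established tumor with inactive Wnt signalling. The closed form is
usually quoted with $m_2$ as a free value, but the $S$ and $D$ balances
close only under the *dedifferentiation balance* $q(m_2) = d$, which
pins $m_2$ to the unique value

$$ m_2^{*} = m_0 + \sigma\,\mathrm{atanh}(2d/q_0 - 1), \qquad 0<d<q_0, $$

returned by `e2_consistent_m2()`. At any other $m_2$ the point is
stationary in $a$ and $m$ only, with residuals $\pm(q(m_2)-d)D_2$ in the
$S$/$D$ components — an identity the test suite asserts exactly. The
conventional anchor $m_2 = 0.08$ (used by the initial conditions and the
linear analysis below) is therefore an approximate equilibrium; the
dynamics relax toward $E^{(2)}(m_2^{*})$.

The fully active state $E^{(3)}$ uses the standard closed form for
$a_3$, which is the positive root of the half-activation condition
$p(D_3, a_3) = 1/2$. That closed form neglects the dedifferentiation
influx $q(m_3)D_3$ (not always small); its $a$ and $m$ balances are
exact and its $S$/$D$ residuals equal the neglected influx exactly, both
of which are tested. $E^{(3)}$ is unstable and not used further.

At $\tau = 0$, $E^{(2)}$ is asymptotically stable exactly when
$d < q_0$ and $m_2 < \gamma/\alpha$ (strict inequalities;
`e2_stable_at_zero_delay()`).

## Hopf analysis with delay and diffusion

`jacobian_at_E2()` builds the linearisation of a zero-flux spatial mode
with squared wavenumber $k^2$ as an instantaneous part $A$ and a delayed
part $B$ (the delayed entries sit in the $S$-row: the gain terms
$q(m_2)\,\delta D(t-\tau)$ and $q'(m_2)D_2\,\delta m(t-\tau)$, written
under the dedifferentiation balance as $d$ and
$(2dD_2/\sigma)(1-d/q_0)$). Diffusion contributes $-D_i k^2$ on the
diagonal. The characteristic function is

$$
\det\!\big(A + Be^{-\lambda\tau} - \lambda I\big)
 = \lambda^4 + C_{11}\lambda^3 + C_{22}\lambda^2 + C_{33}\lambda + C_{44}
 + (E_{11}\lambda^2 + E_{22}\lambda + E_{33})e^{-\lambda\tau}.
$$

`char_coefficients()` obtains the seven coefficients by exact expansion
of the determinant (polynomial cofactor arithmetic), and the test suite
validates them against a complex-LU numeric determinant at random
$(\lambda, k^2)$ points to $10^{-8}$ relative error. Because the
activator row decouples at $E^{(2)}$, the quartic always factors through
$(\lambda + \alpha + D_a k^2)$ — also tested exactly.

**Purely imaginary crossings.** Substituting $\lambda = i\omega$ and
separating real and imaginary parts gives, with
$A_\omega = E_{33} - E_{11}\omega^2$, $B_\omega = E_{22}\omega$,
$R_1 = C_{22}\omega^2 - C_{44} - \omega^4$,
$R_2 = C_{11}\omega^3 - C_{33}\omega$,

$$
A_\omega\cos\omega\tau + B_\omega\sin\omega\tau = R_1, \qquad
B_\omega\cos\omega\tau - A_\omega\sin\omega\tau = R_2,
$$

hence $\cos\omega\tau = (A_\omega R_1 + B_\omega R_2)/(A_\omega^2 +
B_\omega^2)$ and $\sin\omega\tau = (B_\omega R_1 - A_\omega
R_2)/(A_\omega^2+B_\omega^2)$. The sign of the $A_\omega R_2$ term in
the sine matters: with the opposite sign (which circulates in the
literature on such systems) $\cos^2 + \sin^2 \neq 1$ at a genuine root
and the resulting delays are not characteristic roots at all. The
package pins the sign down by back-substitution tests: every branch
delay returned by `critical_delays()` makes
$|P(i\omega, \tau)| < 10^{-6}$.

Squaring and adding eliminates $\tau$ and yields a quartic in
$z = \omega^2$ (solved via companion-matrix eigenvalues in
`omega_roots()`; roots are accepted as real for
$|\mathrm{Im}\,z| < 10^{-9}\max(1,|z|)$ and positive for
$z > 10^{-12}$). For each admissible $\omega$ the delay branches are
$\tau_j = \theta/\omega + 2\pi j/\omega$ with
$\theta = \mathrm{atan2}(\sin, \cos) \in [0, 2\pi)$ — the two-argument
arctangent covers all quadrants uniformly. `transversality()` evaluates
the closed-form sign of $d\,\mathrm{Re}\lambda/d\tau$ at a crossing and
is cross-checked against Newton continuation of the root
(`char_root_near()`). `critical_delay()` scans the homogeneous mode plus
the ten lowest zero-flux modes of the 100 mm domain (the minimum over
modes is the dynamically relevant threshold; with the small reference
diffusivities the $k$-dependence is weak) and reports the minimal
positive-transversality delay $\tau_c$.

**A structural finding.** For the three reference cancer parameter sets
at the conventional anchor $m_2 = 0.08$, the prostate and lung
characteristic equations admit *no* purely imaginary root at any mode —
$E^{(2)}$ is stable for every delay — and the breast set crosses at
$\tau_c = 3.2972$ yr. The prostate set is delay-independently stable
for *every* admissible $m_2$ and $k^2$: its delayed coupling
$(2dD_2/\sigma)(1-d/q_0)$ is suppressed by $d/q_0 = 0.995$.
`critical_delay()` reports this outcome explicitly rather than forcing
a number. Genuine delay-induced oscillations do exist elsewhere in
parameter space — for example $q_0 = 2d$ places $m_2^{*}$ exactly at the
switch threshold $m_0$ and yields $\tau_c \approx 4.2$–$5.9$ yr — and
the test suite verifies there that subcritical/supercritical simulations
are damped/growing, closing the loop between analysis and dynamics.

## The simulator

`simulate_csc()` integrates the method-of-lines system on a cell-centred
grid. Choices that matter:

* **Grid and boundaries.** The domain is $(0,L)^2$ with $L = 100$ mm;
  the reference resolution is $\Delta x = 0.2$ mm. The 5-point Laplacian
  imposes no-flux by ghost-cell mirroring, which makes the discrete
  operator exactly conservative (total mass drift $< 10^{-10}$ under
  pure diffusion — tested). Tests and quick runs use reduced grids
  (e.g. $64\times 64$ cells); all properties exercised are
  resolution-robust.
* **Time stepping.** Classical RK4 with $\Delta t = 0.01$ yr by
  default; the explicit diffusion bound
  $\Delta t \le \Delta x^2/(4\max D)$ is enforced. Delayed values are
  cubic-Hermite interpolated on the stored history (values plus
  stage-consistent derivatives), the standard pairing with RK4 for
  delay systems; only the $D$ and $m$ histories are kept (the only
  delayed fields), over a ring buffer spanning $[t-\tau, t]$. The
  integrator reproduces the method-of-steps solution of
  $y' = -y(t-1)$ to $10^{-6}$ and matches an independent adaptive DDE
  solver on the full 0-D system to $10^{-5}$ (tested).
* **History initialisation.** Constant at the initial field for
  $t \le 0$; initial distributions are specified only at $t = 0$.
* **Initial conditions.** `initial_condition()` evaluates the
  conventional trigonometric perturbations of the $E^{(2)}$ anchor
  (their printed nesting followed literally), clamping negative node
  values to zero. These perturbations are deterministic and
  fine-scaled; they emulate small inhomogeneous deviations from
  homogeneity, not measured tumor geometry — simulations and tests
  therefore speak to the model's pattern-forming dynamics, not to any
  particular patient image.
* **Negativity policy.** Fields are *not* clipped during integration; a
  run is flagged when a field dips below $-10^{-8}$ of its maximum,
  signalling numerical misconfiguration rather than silently altering
  the dynamics.
* **Determinism.** Nothing in the tool consumes randomness.

`pattern_metrics()` summarises snapshots: extrema, centre of mass, a
radial profile, the fraction of variance explained by radius (near 1
for circular patterns) and a localisation radius (smallest radius about
the domain centre holding 90% of the deviation energy; for a field
whose deviation energy is Gaussian with spread $\sigma$ this is
$\sigma\sqrt{2\ln 10} \approx 2.15\sigma$ — tested).

## Fractionated radiotherapy

Radiation enters the $S$ equation as $-\delta R_\mathrm{eff} K_R(t) S$,
with the linear-quadratic daily effect

$$ R_\mathrm{eff} = \alpha_s n\mathcal{D}
   + \beta_s n\mathcal{D}^2 \mathcal{M}, \qquad
\mathcal{M} = g(\mu\tau_r)
   + 2\frac{\cosh(\mu\tau_r)-1}{(\mu\tau_r)^2} h_n(\phi), $$

where $g$ corrects for repair during a fraction of duration $\tau_r$,
$h_n$ for incomplete repair between the $n$ fractions of a day
(separated by $\Delta\tau_r$; $\phi = e^{-\mu(\tau_r+\Delta\tau_r)}$),
and $\mu$ is the repair rate. Reference values:
$\alpha_s = 0.302$ Gy$^{-1}$, $\beta_s = 0.0417$ Gy$^{-2}$,
$\delta = 25$ yr$^{-1}$Gy$^{-1}$, $\mu = 3195.77$ yr$^{-1}$, $n = 2$,
$\tau_r = 9\times10^{-6}$ yr ($\approx 5$ min),
$\Delta\tau_r = 6.9\times10^{-4}$ yr ($\approx 6$ h).

**Gating.** $R_\mathrm{eff}$ is by construction the aggregated effect
of one treatment day's fractions, so `radiation_switch()` defaults to
day-level gating: the kill term is active across each treatment day,
five consecutive days per week, within the treatment span. Gating the
term to the literal 5-minute irradiation windows would scale the
integrated kill by the duty cycle ($\sim 0.7\%$), rendering
fraction-scale doses inert — inconsistent with the eradication dynamics
this term is meant to produce; that literal mode is nevertheless
available (`gating = "fraction"`), as is `"continuous"`.

**BED and the optimum dose.** The tumor biologically effective dose is
$\mathrm{BED}_\mathrm{can} = n\mathcal{D}(1 +
\mathcal{D}/\theta_\mathrm{can})\mathcal{M} - K(T - T_d)$ (repopulation
subtracted only once it has started, $T > T_d$), and
$\mathrm{BED}_\mathrm{late}$ is the same form with
$\theta_\mathrm{late}$ and no repopulation. The two printed forms of
$\mathrm{BED}_\mathrm{can}$ (direct, and rewritten through
$\mathrm{BED}_\mathrm{late}$ with $T = fn - 1$) agree to $10^{-10}$ —
tested on random parameter draws. The fraction number $n$ entering the
BED defaults to the schedule's fractions per day (the convention under
which the worked reference configuration — $\theta_\mathrm{late} = 3$
Gy, $K = 0.2$ Gy/day, $T_d = 40$ d, $f = 7/5$, $T = 45$ d, $n = 2$ — is
coherent; feeding the total fraction count $T$ implies through
$T = fn-1$ would put the BED two orders of magnitude higher).
Maximising $\mathrm{BED}_\mathrm{can}$ over the dose per fraction at
fixed late-tissue BED gives the quadratic
$(1-\theta_\mathrm{late}/\theta_\mathrm{can})\mathcal{M}\mathcal{D}^2 -
2Kf\mathcal{D} - Kf\theta_\mathrm{late} = 0$; `optimum_dose()` returns
its exact positive root (residual $< 10^{-10}$, verified against a
brute-force dose grid). A circulating closed-form variant omits
$\mathcal{M}$ under the square root and does not zero the quadratic;
it is available as `form = "as-printed"` for comparison. Under the
reference configuration the exact optimum is $1.659$ Gy with
$\mathrm{BED}_\mathrm{can} = 3.475$ Gy at the optimum
($\mathcal{M} = 1.0976$); `bed_sensitivity_scan()` quantifies how these
move under alternative schedule conventions. The log cell kill is
$E = \alpha_s \mathrm{BED}_\mathrm{can}$ exactly (repopulation carried
inside the BED, keeping the proportionality dimensionally consistent).

**TCP.** `tcp()` evaluates the Poisson tumor control probability
$\exp(-N e^{-\alpha_s \mathrm{BED}_\mathrm{can}})$ with
$N = \varsigma V$ clonogens ($\varsigma = 8.05\times10^{-4}$
cell/mm$^3$ by default); `tcp_curve()` tabulates it over dose grids and
volumes. TCP is monotone in dose and decreasing in volume — tested; no
"required dose" is reported because that would need an arbitrary TCP
threshold.

## Problem sizes used by the tests

Uniform (0-D) runs integrate up to $t = 80$ yr at $\Delta t = 0.01$;
spatial tests use $24^2$–$64^2$ cells; the radiotherapy ordering
comparison runs three $64\times64$ simulations to $t = 16$ yr at the
reference $\Delta t$. These sizes were chosen so every asserted
property is comfortably resolved (the key comparisons were verified to
be stable under refinement).

## Known limitations

* Explicit time stepping only; no adaptivity, implicit solvers or 3-D
  domains.
* The linear analysis at $m_2 \neq m_2^{*}$ characterises an
  approximate equilibrium; dynamical stability statements should use
  $m_2^{*}$ (the package exposes both).
* The radiation term treats $R_\mathrm{eff}$ as spatially uniform; no
  heterogeneous dose maps or normal-tissue complication modelling.
* The continuous-time dose-rate integral behind the LQ effect is
  represented only through its fractionated closed form.
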