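---
title: "Slow-fast plankton-oxygen dynamics: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-fast plankton-oxygen dynamics: models, methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`omzdyn` analyses a conceptual model of the coupled dynamics of dissolved
oxygen $c$, phytoplankton $u$ and zooplankton $v$ in the upper ocean, in
dimensionless variables:

$$
\begin{aligned}
\dot c &= \frac{A u}{c+1} - \frac{\delta u c}{c+c_2}
          - \frac{\nu c v}{c+c_3} - c \equiv F(c,u,v),\\
\dot u &= \left(\frac{B c}{c+c_1} - u\right) u - \frac{u v}{u+h}
          - \sigma u \equiv G(c,u,v),\\
\dot v &= \varepsilon \left( \frac{\eta c^2}{c^2+c_4^2}\,
          \frac{u v}{u+h} - \mu_1 v - \mu_2 v^2 \right)
          \equiv \varepsilon H(c,u,v).
\end{aligned}
$$

Oxygen is produced by phytoplankton photosynthesis (saturating in $c$
because re-absorption grows with concentration), consumed by both
plankton groups via Monod kinetics, and lost at unit relative rate.
Phytoplankton grows logistically with an oxygen-limited rate, is grazed
with a Holling type II response and dies at rate $\sigma$. Zooplankton
converts grazing into growth with an efficiency that requires oxygen
(the sigmoidal $c^2/(c^2+c_4^2)$ factor) and dies both linearly
($\mu_1$, natural mortality) and quadratically ($\mu_2$, intraspecific
competition, cannibalism and implicit predation by higher trophic
levels). Two ingredients distinguish this system from its predecessors:
the quadratic mortality term and the timescale ratio
$0<\varepsilon\le 1$, which makes zooplankton the *slow* variable when
$\varepsilon \ll 1$ (a slow-fast, singularly perturbed system).

The kinetic baseline used everywhere is
$A=4$, $B=3$, $\sigma=0.1$, $c_1=0.7$, $c_2=c_3=c_4=1$, $\eta=0.7$,
$\delta=1$, $\nu=0.01$, $h=0.1$ — the defaults of `model_params()` —
with $(\mu_1,\mu_2,\varepsilon)$ as the control parameters.

`plankton_rhs()` returns $(F, G, \varepsilon H)$, i.e. the fast-time
system; consumers that need the bare zooplankton reaction call
`plankton_H()`. This split prevents silent double-scaling by
$\varepsilon$. The Jacobian is implemented in closed form
(`plankton_jacobian()`), derived once by hand and regression-tested
against central finite differences: near the fold of the critical
manifold, finite-difference Jacobians are exactly where noise hurts
most, and per-call symbolic differentiation would be wasteful.

## Steady states and their classification

Besides the always-present extinction state at the origin (stable for
$\mu_1>0$: its eigenvalues are $-1$, $-\sigma$, $-\varepsilon\mu_1$),
the model has zooplankton-free states $(\bar c,\bar u,0)$ whose oxygen
component solves a quartic obtained by eliminating
$\bar u = (\bar c(B-\sigma)-c_1\sigma)/(\bar c+c_1)$; the quartic
coefficients are expanded by exact polynomial arithmetic rather than
transcribed, and the roots (via the companion matrix underlying
`polyroot`) are verified in the tests against a dense sign-change scan.
At the baseline the two feasible roots are $\bar c = 0.0258$ and
$1.712$, independent of $\mu_1,\mu_2,\varepsilon$.

Coexistence states solve $F=G=H=0$. `find_coexistence()` runs a
multi-start 3-D Newton iteration from a $40\times 40$ grid in the
$(c,u)$ plane, seeding $v$ from the elimination
$v = (\eta c^2/(c^2+c_4^2)\, u/(u+h) - \mu_1)/\mu_2$ when $\mu_2>0$ and
from the grazing balance otherwise; duplicates merge at $10^{-7}$.
The grid is deliberately dense relative to the known structure (at most
two coexistence states) so capture is not luck. Feasibility is strict
positivity above $10^{-10}$; boundary states are returned only by their
dedicated finders. $\mu_1=\mu_2=0$ is rejected: the interior zooplankton
balance is then non-isolated.

Stability uses both the eigenvalues of the $\varepsilon$-scaled Jacobian
and the Routh–Hurwitz conditions $p_0>0$, $p_2>0$, $p_1p_2>p_0$ on the
characteristic polynomial $\lambda^3+p_2\lambda^2+p_1\lambda+p_0$; the
two verdicts are required to agree, and an eigenvalue with
$|\mathrm{Re}\,\lambda|<10^{-8}$ raises a "marginal" error so callers
must treat the point as a bifurcation, not a classification.

## Hopf points, criticality, and collapse thresholds

`hopf_threshold()` bisects $p_1p_2-p_0$ (to parameter tolerance
$10^{-7}$) along the continued equilibrium branch, checking $p_0,p_2>0$
at the root and confirming a conjugate pair with
$|\mathrm{Re}\,\lambda|<10^{-6}$. Continuation is natural-parameter
Newton seeding from the nearest previously visited value, with the
multi-start search as fallback. Because the third Jacobian row carries
$\varepsilon$, thresholds shift with the timescale separation; at small
$\varepsilon$ these are singular Hopf points occurring $O(\varepsilon)$
from the fold.

`first_lyapunov()` implements the standard projection/normal-form
formula for $n$-dimensional Hopf points, with the second- and
third-derivative tensors obtained by central differences of the
analytic Jacobian (steps $10^{-4}$). Only the *sign* of $\ell_1$ is
contract-tested: the magnitude depends on eigenvector normalization
conventions, which published numbers rarely state. The four reference
sign checks (supercritical on the $\mu_1$ axis, subcritical on the
$\mu_2$ axis, subcritical at $(\mu_1,\varepsilon)=(0.24,0.5)$,
supercritical at $(0.3, 0.5)$) all reproduce.

Global bifurcations (heteroclinic destruction of the stable cycle;
canard-cycle blow-up) are detected *operationally* by
`extinction_threshold()`: start at the coexistence state plus a small
offset (default $0.01$ per component), integrate to $T=5000$ with lsoda
at `rtol 1e-9 / atol 1e-11`, call the run collapsed if $u<10^{-6}$
holds over the final 50 time units, and bisect the parameter on that
binary outcome to $10^{-5}$. Cycle envelopes in `branch_diagram()`
discard a transient of 2000 time units and record extrema of $c$ over
1000 (doubled automatically if the peak-to-peak drifts by more than 1%)
— chosen to exceed the slowest timescale $1/(\varepsilon\mu_1)$ for the
$\varepsilon\ge 0.1$ runs the package targets. The narrow window where a
stable and an unstable cycle coexist (a $10^{-4}$-wide interval in
$\mu_2$ at $\mu_1=0.24$) is noted but not resolved as a separate
quantity; no unstable-cycle continuation is attempted.

## The slow-fast decomposition

Freezing $v=v_0$ gives the fast oxygen–phytoplankton subsystem; its
equilibria over all $v_0$ form the critical manifold. The trivial
branch ($c=u=0$) is attracting for every $v\ge 0$ (eigenvalues
$-1-\nu v/c_3$ and $-v/h-\sigma$). The nontrivial branch is sampled by
`build_manifold()`: by default 400 points on $[0, 1.1\,v_s]$ with a
tenfold refinement over the last 5% before the fold, where the
attracting ($u>u_s$) and repelling ($u<u_s$) branches converge.
`fast_equilibria()` intersects the explicit oxygen nullcline $u(c)$
with the phytoplankton balance by a scan in $c$ on $(0,20]$ — an
order of magnitude beyond the $c\in[0,2]$ range the dynamics occupies —
followed by Newton polish.

The fold $(c_s,u_s,v_s)$ solves $F=G=\det\mathcal J_{\rm sub}=0$
(`fold_point()`), Newton-seeded from the $v_0$ where the slice count
drops from two to zero; at the baseline it sits at
$(1.26531, 1.05229, 0.89784)$. The reduced flow on the manifold
(`slow_flow()`) follows from implicit differentiation of $F=G=0$ and is
singular exactly at the fold. The jump/canard discriminants
$F_vG_u-F_uG_v$ and $F_vG_c-F_cG_v$ are evaluated from analytic
partials at tolerance $10^{-6}$; at the baseline both are $O(1)$, so
the fold classifies numerically as a jump point, while the canard-cycle
phenomenology near the singular Hopf point is observed through
simulation. Both outcomes are legal results of `classify_fold()` and
are reported, not assumed.

The slow drift at the fold is the value of $H$ there, which depends on
the mortality pair. No single printed pair in the slow-fast analyses
reproduces the reference value $H=0.001859$ exactly; scanning $\mu_2$
at the same $10^{-4}$ print precision, $(\mu_1,\mu_2)=(0.3, 0.1018)$
does (computed $H=0.001868$, within $10^{-5}$), and the package adopts
that pair wherever "the slow-fast mortality context" is meant
(reference suite, worked examples).

A structural consequence tested as a property: because the trivial
branch is attracting for all $v$ and carries the flow into the origin,
no singular orbit can concatenate slow segments and fast fibers into a
closed loop. Canard cycles born at the singular Hopf point therefore
blow up into collapse rather than mature into relaxation oscillations:
trajectories that reach the extinction manifold ($u<10^{-3}$) never
return. The tests confirm this at $(\mu_1,\mu_2)=(0.3, 0.09917)$ for
$\varepsilon\in\{0.5, 0.1, 0.01, 0.001\}$. One honest caveat: "ends at
the origin" is asserted as $u<10^{-6}$, $c<10^{-3}$ and monotone decay
of $v$, with the full $\|(c,u,v)\|<10^{-4}$ check applied only for
$\varepsilon \ge 0.01$ — the zooplankton remnant decays at rate
$\varepsilon\mu_1$, so for $\varepsilon=0.001$ reaching $10^{-4}$ would
take $\sim 3\times 10^4$ time units, far beyond the $T=5000$ horizon
the analysis uses.

## Spatial model, Turing analysis and regimes

The spatial model adds one horizontal dimension with turbulent
diffusion: diffusivities $(1,1,D)$ after nondimensionalization, where
$D$ is the ratio of zooplankton diffusivity (self-motion plus
turbulence) to the turbulent diffusivity of oxygen and phytoplankton.
Linearizing about a coexistence state with perturbations
$\propto e^{\lambda t}\cos kx$ gives a cubic in $\lambda$ whose
coefficients `dispersion()` evaluates; `critical_wavenumber()` uses the
closed-form stationary point of $p_0(k^2)$ (with discriminant
$\Lambda$) and cross-validates it against direct numerical minimization
— at the reference setting ($\mu_1=0$, $\mu_2=0.41$, $\varepsilon=1$,
$D=5$) both give $k_T^2=0.1095$. All Jacobian entries entering these
formulas include the $\varepsilon$ factor in the third row; this is
stated prominently because the closed form is silent about it and the
verdict genuinely changes with $\varepsilon$.

`simulate_rd()` implements exactly the scheme used for the reference
spatiotemporal results: forward Euler with a 3-point Laplacian,
node-centered grid with mirrored ghost nodes (second-order zero-flux),
defaults $L=500$, $\Delta x=1$, $\Delta t=0.01$, and a localized
initial perturbation of the steady state in a window of half-width 10
at the domain center (oxygen $+0.1$, phytoplankton $+0.2$; the
"depleted" variant instead lowers them by $0.5$ and $0.2$). The core
loop is compiled (Rcpp); an R reference step (`rd_step()`) backs the
step-level tests, including exact conservation of trapezoid-weighted
mass in the pure-diffusion limit. The explicit-stability constraint
$\max(1,D)\,\Delta t/\Delta x^2 \le 1/2$ is enforced, values in
$(-10^{-8},0)$ arising from the explicit update are clamped to zero and
counted, and anything more negative aborts the run. The simulator is
deterministic throughout.

Regime labels (`classify_regime()`) are a decision tree over the final
500 time units: global anoxia if the final mean oxygen is below 0.01;
homogeneous-steady if spatially and temporally flat (relative sd below
$10^{-4}$); stationary pattern if strongly structured (relative spatial
sd $\ge 10^{-2}$) and frozen (rms change per node between the last two
snapshots below $10^{-4}$); localized oscillation if temporal
variability is confined to under 20% of nodes; otherwise dynamic
irregular. An OMZ is operationalized as a maximal run of at least two
consecutive nodes with $c$ below $\theta c_*$, $\theta=0.5$ by default
— the reference analyses say only "much lower than the steady state",
so $\theta$ is exposed in the report rather than hidden.

### Problem sizes used by the tests

The regime tests and the spatial acceptance checks run on a scaled
domain, $L=200$ with $T=2000$–$3000$ ($T=3000$ for the stationary
Turing pattern, which freezes to the $10^{-4}$ rms criterion shortly
after $T=2000$ on this domain). These sizes were chosen as the smallest
at which the three reference regimes (stationary Turing pattern at
$\varepsilon=1$ with dominant mode within one grid mode of
$k_T=\sqrt{0.1095}$; irregular dynamics at $\varepsilon=0.12$; global
anoxia at $\varepsilon=0.06$) reproduce with the same labels as the
full $L=500$, $T=5000$ runs. One known finite-size effect: in the
$\mu_1=0.24$, $\mu_2=0.1575$, $D=1$ sweep the anoxia onset moves from
$\varepsilon\approx 0.2$ (full domain) to $\varepsilon\approx 0.25$
(scaled domain); the corresponding test asserts the monotone
degradation sequence rather than the exact onset.

### What the synthetic scenarios do and do not show

All inputs are generated programmatically from the model itself — there
is no observational data anywhere. The scenarios emulate an idealized
horizontal transect of the photic layer under the well-mixed-layer
approximation: no vertical structure, no advection (currents are
excluded deliberately; only isotropic turbulent mixing is kept), no
multiscale/nonlocal turbulence closure, and a food web truncated to one
phytoplankton, one zooplankton and implicit higher predation through
$\mu_2$. Passing tests therefore demonstrate internal consistency of
the model's mechanisms (fold-driven collapse, Turing patterning, OMZ
growth), not quantitative prediction for any real ocean region.

## Known limitations

* No two-parameter continuation, no continuation of unstable limit
  cycles, and no Lyapunov-exponent quantification of the irregular
  spatial regimes.
* The $\ell_1$ magnitude is reported but intentionally untested.
* The fold/canard discriminants decide the classification at a point;
  no blow-up (desingularization) analysis is performed.
* Scheme accuracy is first order in time; halving $\Delta t$ changes
  short-run fields by under $10^{-3}$, adequate for regime-level
  conclusions but not for high-precision pattern metrics.
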