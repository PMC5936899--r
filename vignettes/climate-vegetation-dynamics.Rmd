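---
title: "Methods: deterministic and stochastic dynamics of the climate-vegetation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deterministic and stochastic dynamics of the climate-vegetation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vegclim)
```

## The model and its assumptions

`vegclim` implements a two-variable conceptual model of the coupled
climate–vegetation system.  The state is the global mean temperature $T$
(kelvin) and the fraction $A \in [0,1]$ of land covered by vegetation.

$$C_T \frac{dT}{dt} = \bigl(1 - \alpha(T, A)\bigr) Q_0 - R_0(T), \qquad
\frac{dA}{dt} = \beta(T)\,A(1-A) - \gamma A.$$

The energy balance is zero-dimensional: all spatial structure is collapsed
into the albedo mix
$\alpha(T,A) = (1-p)\,\alpha_o(T) + p\,(\alpha_v A + \alpha_g (1-A))$,
where $p$ is the land fraction of the planet and vegetation is darker than
bare ground ($\alpha_v < \alpha_g$), so more vegetation warms the planet.
The ocean albedo $\alpha_o$ is a ramp in $T$ between an ice-covered value
$\alpha_{max}$ (for $T \le T_{\alpha,\ell}$) and an ice-free value
$\alpha_{min}$ (for $T > T_{\alpha,u}$): the ice–albedo feedback.  The
outgoing flux is linearized, $R_0(T) = B_0 + B_1 (T - T_{opt})$, and the
vegetation growth rate is a clipped parabola
$\beta(T) = \max\{0, 1 - k (T-T_{opt})^2\}$ with optimum $T_{opt}$ and
support $|T - T_{opt}| < \sqrt{1/k}$ (about $\pm 15.8$ K for the default
$k$).  The two feedbacks — ice–albedo (destabilizing on the ramp) and
vegetation–albedo (stabilizing through growth) — generate bistability:
a cold "snowball" state with bare land and a warm vegetated state.

All temperatures are absolute kelvin and time is measured in years; with
$C_T$ in W yr K$^{-1}$ m$^{-2}$ the temperature tendency comes out in
K yr$^{-1}$.  Parameters are validated once at construction
(`climate_params()`); all operations assume a valid set.

### Parameters

The defaults are the standard published calibration of this model:
$C_T = 500$ W yr K$^{-1}$ m$^{-2}$, $Q_0 = 342.5$ W m$^{-2}$, $p = 0.3$,
$\alpha_v = 0.1$, $\alpha_g = 0.4$, $\alpha_{max} = 0.85$,
$\alpha_{min} = 0.25$, $T_{\alpha,\ell} = 263$ K, $T_{\alpha,u} = 300$ K,
$B_0 = 200$ W m$^{-2}$, $B_1 = 2.5$ W K$^{-1}$ m$^{-2}$,
$T_{opt} = 283$ K, $k = 0.004$ yr$^{-1}$ K$^{-2}$.  The vegetation death
rate $\gamma$ (yr$^{-1}$) is the bifurcation parameter; no canonical
default exists, and the package uses $\gamma = 0.02$ (a value in the
limit-cycle regime) when none is given.

## Deterministic analysis

### Equilibria

`find_equilibria()` reduces the 2-D problem to two 1-D root searches.

* **Vegetation-free branch** ($A = 0$, an invariant line): solve
  $(1-\alpha(T,0))Q_0 = R_0(T)$.  The residual is only piecewise smooth
  (kinks at the ramp breakpoints), so each ocean-albedo segment is
  scanned separately on a 0.1 K grid and each sign change is passed to
  `uniroot()` and polished by Newton steps.  On the ice-covered segment
  the balance is linear, giving the closed form
  $T = T_{opt} + ((1-\alpha_{cold})Q_0 - B_0)/B_1 = 242.045$ K for the
  defaults — independent of $\gamma$.
* **Interior branch**: the nontrivial vegetation nullcline is
  $A(T) = 1 - \gamma/\beta(T)$.  Near the edges of the growth support
  $\beta \to \gamma$ makes $A(T)$ arbitrarily steep in $T$, and a uniform
  $T$ scan misses roots there (at $\gamma = 0.001$ the warm root sits
  within $10^{-2}$ K of the support edge).  The branch is therefore
  parameterized by $A$ instead:
  $T(A) = T_{opt} \pm \sqrt{(1 - \gamma/(1-A))/k}$, one half-branch on
  each side of the optimum, scanned on a uniform grid of 4001 points in
  $A$.

Duplicates within $10^{-6}$ K are merged; every root is classified by the
eigenvalues of the analytic Jacobian.  For the default parameters and
every $\gamma$ between 0.001 and 0.35 this yields exactly three
equilibria: the snowball (stable node), a saddle (279–287 K, moving up
with $\gamma$), and a warm interior equilibrium.

The Jacobian of the drift is only piecewise smooth; at a seam (ramp
breakpoint or growth-support edge) the derivative of the segment the
state itself belongs to is used, matching the $\le$/$>$ branch convention
of the model functions.  Seams are measure-zero sets and no default
equilibrium sits on one.

### Hopf scan and limit cycle

The warm equilibrium is a focus whose real part crosses zero between
$\gamma = 0.025$ and $\gamma = 0.1$ (`scan_hopf()` brackets the change on
a user grid and can bisect it to arbitrary width).  Below the crossing
the warm attractor is a limit cycle, above it a stable equilibrium —
a supercritical Andronov–Hopf transition, which the package observes
through the cycle's existence rather than by computing normal-form
coefficients.

An important numerical point: the instability is weak
($\mathrm{Re}\,\lambda \sim 10^{-3}$–$10^{-5}$ yr$^{-1}$), so the cycle
develops from a small perturbation only on $10^4$-yr timescales.
`detect_limit_cycle()` therefore settles for 20000 yr (default) before
measuring the period from successive temperature maxima over a 5000-yr
window; shorter settles would report the tiny unconverged spiral around
the focus rather than the order-1 relaxation cycle.  The converged cycles
for the defaults have periods of 827 yr ($\gamma = 0.02$), 1087 yr
($\gamma = 0.01$) and 3123 yr ($\gamma = 0.001$) — the period decreases
with the death rate — and the $\gamma = 0.01$ cycle swings across
$A \approx 10^{-4}$–0.64, nearly touching the vegetation-free line each
period.  Close to the Hopf point (e.g. $\gamma = 0.025$) the growth rate
is so small that the measured orbit is still near-linear after the
default settle; it is reported as a cycle with the linear period
$2\pi/\mathrm{Im}\,\lambda$, which is the honest small-amplitude answer
there.

### Separatrix and basins

The separatrix is the stable manifold of the saddle, traced by
reverse-time RK4 from the saddle displaced $\pm 10^{-6}$ along the stable
eigenvector until the arm leaves $T \in [230, 310]$, $A \in [0, 1]$.
Reverse-time stages may probe infinitesimally outside $A \in [0,1]$; the
albedo is affine in $A$ and extends smoothly, so these probes are
evaluated without the state validation applied to user input.  One arm is
geometrically striking: it hugs $A \approx 0$ (at double precision,
astronomically small values such as $10^{-100}$) across the whole warm
temperature range, because the basin boundary at warm temperatures is the
knife edge where vegetation regrowth exactly loses the race against the
slow radiative cooling.  `basin_of()` classifies initial states by
forward integration: "cold" within 1 K of the snowball, "warm" inside a
2 K / 0.1 A box around the warm attractor (point or cycle bounding box —
the attractor is not a point, hence a box), "undecided" otherwise
(trajectories near the separatrix can shadow it for thousands of years,
so generous horizons are advisable near the boundary).

### Integration

Both deterministic (classical fixed-step RK4) and stochastic integrators
run on the same fixed grid, dt = 0.01 yr by default, so deterministic and
stochastic runs are directly comparable; both are implemented in C++
(Rcpp) because ensemble sweeps are $10^8$-step workloads.  $A$ is clamped
to $[0,1]$ after each step; for the deterministic integrator the clamp
only absorbs machine-precision excursions.  Halving dt changes 1000-yr
endpoints by less than $10^{-6}$ K, and the integrator agrees with an
adaptive reference solver (deSolve's lsoda at $10^{-10}$ tolerances) to
better than $10^{-6}$ over 200-yr runs.

## Stochastic simulation

The stochastic system perturbs the growth rate with Gaussian white noise,
$\beta(T) \to \beta(T) + \varepsilon \xi(t)$, giving multiplicative noise
$\varepsilon A(1-A)\,dW$ on the vegetation equation.  The prescribed
scheme is Euler–Maruyama, which targets the Itô integral; the package
documents and implements the Itô reading.  Per step, the temperature is
advanced with plain Euler (it carries no noise) and

$$A \mathrel{+}= \bigl(\beta(T)A(1-A) - \gamma A\bigr)\,dt +
\varepsilon A(1-A)\sqrt{dt}\,Z, \qquad Z \sim N(0,1),$$

with exactly one deviate per step drawn from R's generator, so a given
(seed, dt, horizon, $\varepsilon$) reproduces a trajectory bit-identically
and ensemble member $i$ (seed $+ i$) is independent of batch order.
$\varepsilon$ carries the units of $\beta$ (yr$^{-1}$) with the
$\sqrt{\mathrm{yr}}$ scaling absorbed into the Wiener increment; no
physical calibration of $\varepsilon$ is asserted.  $A$ is clamped to
$[0,1]$ after each step rather than rejected or reflected: the exact SDE
never leaves $[0,1]$ (drift and diffusion both vanish at the edges), so
the clamp only absorbs discretization overshoot and preserves the
invariant edges — rejection or reflection would bias the dynamics where
trajectories linger near $A = 0$.  Clamp activations are counted and
reported in the trajectory metadata; they stay below 1% of steps for
$\varepsilon \le 0.2$.  With $\varepsilon = 0$ the scheme reduces exactly
to deterministic Euler, which the tests assert bit-for-bit.

## Transition statistics

* **Transition criterion**: a trajectory has transitioned when $T$ drops
  below 260 K.  260 K lies below every saddle of the default calibration
  (279–287 K) and far above the snowball (242 K), so crossings are
  unambiguous and effectively irreversible.
* **Transition window**: on an ascending $\varepsilon$ grid,
  `epsilon_sweep()` estimates the transition probability within a 5000-yr
  horizon (100 runs per point by default, Wilson 95% intervals, named in
  the output) and reports the window as the smallest grid $\varepsilon$
  reaching probability 0.1 and 0.9.  The 0.1/0.9 thresholds are a
  convention operationalizing "the range over which transitions set in";
  both the raw curve and the window are returned.
* **Densities and the noise-induced shift**: `temperature_density()`
  pools post-burn-in (default 500 yr) temperature samples into a
  normalized histogram.  At large $\varepsilon$ the accumulated snowball
  mass would dominate, so a `pre_transition` mode truncates each
  trajectory at its first passage; both variants are available.
  `shift_statistics()` summarizes a density series by mean, mode and the
  central 90% interval, flagging a monotone decrease of the mean with
  $\varepsilon$ — the noise-induced cooling shift.

### What the measured windows show

With the default calibration the measured windows (100 runs per point,
0.05 grids) are approximately $\varepsilon \in (0.65, 0.70]$ at
$\gamma = 0.35$, $(0.60, 0.80]$ at $\gamma = 0.01$ and $(0.85, 1.00]$ at
$\gamma = 0.1$.  Three qualitative features are robust: the probability
rises from 0 to 1 over a narrow range of $\varepsilon$; above the window
the collapse is effectively certain; and the $\gamma = 0.01$ window lies
below the $\gamma = 0.1$ window.  At $\gamma = 0.35$, noise intensity
$\varepsilon = 0.7$ drives every tested seed into the snowball within
5000 yr.  The mechanism is a race: fluctuations collapse $\log A$ during
phases where $\beta(T) < \gamma + \varepsilon^2/2$ (the Itô drag), and
the transition succeeds only if vegetation regrowth then loses against
the slow radiative cooling ($\sim 10^{-2}$ K yr$^{-1}$ with $C_T = 500$)
across the growth window — which is why small death rates, whose
attractor already grazes $A \approx 0$, and large death rates, whose
regrowth margin $\beta - \gamma$ is thin, both transition more easily
than intermediate ones.

## Design choices and limitations

* Root finding per continuity segment (and per half-branch in $A$) was
  chosen over 2-D Newton iteration for enumerability: every sign change
  on the scan grid is a bracketed root, and kinks can never be straddled.
  The residual grids (0.1 K / 4001 $A$-points) bound the resolvable root
  separation; roots closer than that would be merged.
* The warm-start used by sweeps is a point on the warm attractor: the
  stable equilibrium where one exists, otherwise the endpoint of a
  20000-yr settle onto the cycle.
* Ensembles default to 100 runs per grid point, sized for desk-scale
  runtime; the binomial intervals make the resulting sampling error
  explicit.  Sweep grids use 0.05 steps, which bound the achievable
  window precision to one grid step.
* No Fokker–Planck solver and no large-deviation machinery: densities
  and transition probabilities are empirical Monte Carlo estimates only.
  No higher-order SDE schemes: the model is explicitly tied to the
  Euler–Maruyama discretization, and first-passage summaries are
  reported at the scheme's own order.
* The model is a caricature of the real climate system: no CO$_2$
  dynamics, ocean heat transport, seasonality or spatial structure.
  Passing tests demonstrate properties of this idealized system, not
  predictions about the real climate.  Within the model, conclusions near
  the Hopf point depend on very long transients, and stochastic window
  edges carry one-grid-step plus binomial uncertainty.
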