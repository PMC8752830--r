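---
title: "Multi-timescale viscoelastic characterization of AFM force curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-timescale viscoelastic characterization of AFM force curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscofit)
```

## The problem

A quasi-static AFM force curve — a micron-scale bead pressed into a living
cell at a micron per second while force and indentation are sampled at tens
of kilohertz — is usually reduced to a single Hertzian Young's modulus. That
number discards the rich temporal information in the record: soft matter
stores *and* dissipates energy, and it does so differently at every
deformation timescale. `viscofit` instead parameterizes a discrete
viscoelastic network from each curve and reports frequency-resolved storage
modulus, loss modulus, and loss angle.

## Model and contact mechanics

Two physically equivalent discrete networks are supported:

* **Generalized Maxwell** (stiffness side): an equilibrium spring $G_e$ in
  parallel with $N$ arms $(G_n, \tau_n)$. Its relaxation modulus is the
  Prony series $G(t) = G_e + \sum_n G_n e^{-t/\tau_n}$.
* **Generalized Kelvin–Voigt** (compliance side): a glassy spring $J_g$ in
  series with $N$ retardation arms $(J_n, \tau_n)$, with creep compliance
  $J(t) = J_g + \sum_n J_n (1 - e^{-t/\tau_n})$.

For a rigid sphere of radius $R$ indenting an incompressible half-space, the
Lee–Radok extension of Boltzmann superposition links the full loading
*history* to the observables through hereditary convolution integrals:

$$F(t) = \frac{8\sqrt{R}}{3(1-\nu)} \int_0^t Q(t-\zeta)\, h(\zeta)^{3/2}\, d\zeta,
\qquad
h(t)^{3/2} = \frac{3(1-\nu)}{8\sqrt{R}} \int_0^t U(t-\zeta)\, F(\zeta)\, d\zeta,$$

where $Q$ and $U$ are the material's relaxance and retardance. Both contain
impulsive (Dirac) components, so this package never materializes them as
time-domain arrays. Instead the convolutions are integrated by parts — valid
because every curve starts from zero contact, $h(0) = F(0) = 0$ — which
leaves only the smooth kernels $G(t)$ and $J(t)$:

$$\int_0^t Q(t-\zeta) g(\zeta)\, d\zeta
 = G(0)\,g(t) - \sum_n \frac{G_n}{\tau_n} \int_0^t e^{-(t-\zeta)/\tau_n} g(\zeta)\, d\zeta,
 \qquad g = h^{3/2}.$$

A zero-arm model therefore reduces *exactly* to the elastic Hertz expression,
with no quadrature error at all — a useful built-in sanity limit.

The $8\sqrt{R}/(3(1-\nu))$ prefactor is the shear form of spherical contact,
so every fitted modulus in this package is a shear-type magnitude. The
pseudo-elastic module converts to Young's form with $E = 2G(1+\nu)$; harmonic
spectra are reported in the shear convention.

## Numerics

The exponential integrals are evaluated with the trapezoid rule on the
uniform acquisition grid via the recursion
$I_i = a I_{i-1} + \tfrac{\Delta t}{2}(g_i + a\,g_{i-1})$, $a = e^{-\Delta
t/\tau}$, which reproduces the full trapezoid sum exactly per step in $O(n)$
(implemented in C++). A direct $O(n^2)$ double-loop evaluation of the same
sum ships alongside it (`predict_force(..., method = "direct")`) as an
independent oracle; the two agree to float roundoff, and the quadrature
converges at the expected $O(\Delta t^2)$ against adaptive-quadrature
references. The relative quadrature error of an arm scales as
$(\Delta t / \tau)^2 / 12$, so the fastest resolvable timescale is set by the
sampling rate; `simulate_curve()` warns when $\Delta t > \tau_{\min}/2$.

**Decimation.** Long curves are expensive to fit, and the common practice is
to decimate them. Naively decimating *before* convolving is dangerous: once
$\Delta t \gtrsim \tau_1$ the fast arm's integral degrades as above and the
recovered parameters inherit the bias. `viscofit` therefore decouples the
two roles of the grid: the hereditary recursions always run at full
acquisition resolution, while the fitting SSE is evaluated only at
`decimate_to` (default 1000) uniformly strided *cost points*, united with a
log-spaced early block (25 points per decade of sample index). The log block
matters: the fastest arm is identified almost entirely by the first ~$\tau_1$
worth of samples, which a bare uniform stride would discard. Decimation then
only thins the least-squares weighting and costs no quadrature accuracy; the
reported SSE of every fit is recomputed on the full grid.

Relatedly, each arm's timescale box is floored at twice the sampling
interval: an arm faster than the grid can resolve is not identifiable, and
under noise an under-resolved arm with an enormous modulus becomes a
spurious near-degenerate optimum. Identifiability has a softer edge too —
the magnitude/timescale ridge of a fast arm is shallow in the likelihood
even at full resolution (a fit displaced 2–3x along it costs only tens of
chi-square units at 1% force noise on a typical curve), so individual-curve
estimates of the fastest decade scatter substantially; population averaging
in the frequency domain is what stabilizes the reported spectra.

## Fitting

The cost is the plain sum of squared differences between the normalized
observable and the model convolution ("action integral"): for the Maxwell
family, between $\tfrac{3(1-\nu)}{8\sqrt R} F(t)$ and $\int_0^t Q(t-\zeta)
h^{3/2} d\zeta$. All parameters are optimized as $\log_{10}$ values —
magnitudes span decades and positivity becomes free — inside finite boxes:
moduli in $[10^0, 10^7]$ Pa (compliances in the reciprocal box) and the
$n$-th arm timescale inside a one-decade window centered on
$10^{-4+(n-1)}$ s, operationalizing the ladder that starts near $10^{-4}$ s
and climbs one decade per term. The windows carry a hair of interior margin
so adjacent arms stay strictly ordered.

The local solver is a bounded Levenberg–Marquardt on the residual vector
with an analytic Jacobian (the $\tau$-sensitivity of each exponential
integral obeys its own $O(n)$ recursion), steps projected onto the box.
Two problem-specific accelerations matter in practice, both found necessary
during development:

* **Linear-subproblem hops.** The convolution is linear in the moduli given
  the timescales, so each iteration first solves that least-squares
  subproblem exactly (clamped to bounds, kept only if downhill). This
  collapses the notoriously flat "Prony valley" along which magnitude/
  timescale combinations trade off almost freely.
* **Coarse multistart + deep polish.** Random restarts are capped at
  `max_iter` (default 80) iterations; only the winning attempt is then
  continued with a `polish_iter` budget, restarting with fresh damping until
  the SSE stops improving (premature stationarity declarations deep in the
  valley are a known LM failure mode). This gives exact noiseless recovery
  at a fraction of the cost of polishing every attempt.

Two strategies are exposed. `fit_open_search()` draws all $2N+1$ parameters
log-uniformly in their boxes for each of `n_attempts` restarts.
`fit_iterative()` fits the elastic term first in closed form, feeds it
forward, and then grows the model one arm at a time, warm-starting all
previously fitted parameters and randomizing only the new pair
$(G_N, \tau_N)$ in its window; a deterministic fallback attempt seeds the
new arm at negligible magnitude, so a stage can never do (more than
negligibly) worse than its predecessor. Because arm magnitudes are bounded
below at 1 Pa, a redundant arm cannot vanish exactly; the nesting guarantee
holds up to a floor around $10^{-10}$ of the signal energy.

Every random start comes from a counter-based seed stream indexed by
(stage, attempt), so results are independent of evaluation order and exactly
reproducible; ties among equal-cost attempts break toward the lowest attempt
index. Defaults are desk-scale (50 restarts); the published protocol this
package re-implements used 500–1000.

**Term-count selection.** `select_terms()` resamples each candidate's
action-integral residuals onto a log-spaced time grid (10 points per decade)
with double weight on the final decade — long-timescale improvements are the
discriminating signal, while dense early samples would otherwise dominate —
and returns the smallest term count whose weighted SSE is within
$1 + \varepsilon$ (default 5%) of the best. All three knobs are config keys,
because the original selection was judgment-guided and defaults must be
explicit and overridable.

## Harmonic spectra

A constant-velocity ramp excites mechanical response at every frequency
between the inverse experiment duration and the sampling rate; the grid is
log-spaced between exactly those endpoints. Storage and loss moduli follow
from the closed forms (Maxwell: $G' = G_e + \sum G_n \omega^2\tau_n^2 /
(1+\omega^2\tau_n^2)$, $G'' = \sum G_n \omega\tau_n/(1+\omega^2\tau_n^2)$;
Kelvin–Voigt via inversion of the complex compliance), and the loss angle is
$\delta = \arctan(G''/G')$. Frequencies in Hz are converted to angular
frequency by default (`angular = TRUE`); the convention is switchable since
it only shifts spectra horizontally by $2\pi$ and the figure-axis convention
of the original study is not stated.

Population results average *per-curve predicted spectra* in the frequency
domain — not pooled raw parameters — with Student-$t$ bands at a 95%
confidence level. Both the CI-of-the-mean band (default) and the
"range-of-observations" style band ($\pm t\,s$) are implemented, because the
source wording is ambiguous between them; the choice is recorded in the
spectrum object.

## The simulator: what it emulates and what it does not

`simulate_curve()` drives $h(t) = vt$ on the uniform grid, evaluates the
hereditary force, truncates at a force or indentation trigger, and adds
seeded Gaussian force noise. Defaults are the stated experimental world: a
25 µm polystyrene bead ($R = 12.5$ µm), $\nu = 0.5$, 2 µm/s approach, 50 kHz
sampling, 10 nN trigger (forces in the 5–18 nN working range), quasi-static
ramps at or below 1 s. Ground-truth draws use moduli log-uniform in
$[10^2, 10^4]$ Pa with timescales a decade apart from $10^{-4}$ s — the
regime of the live-cell fits. The fixed benchmark model (`benchmark_model()`)
is $G_e = 1000$ Pa with arms (3000 Pa, $10^{-4}$ s), (1500 Pa, $10^{-3}$ s),
(800 Pa, $10^{-2}$ s); the original benchmark's exact ground truth is not
published in the text this package was built from, so it was fixed once
inside that regime.

`simulate_population()` adds mean-one log-normal jitter (defaults: 10% on
moduli, 5% on timescales) to emulate cell-to-cell heterogeneity, with 1% of
the trigger force as a typical noise floor. The mean-one correction matters:
the aggregate spectrum of a jittered population is then an unbiased estimate
of the base model's spectrum, which is what the coverage test checks.

Not emulated: cantilever dynamics and hydrodynamic drag, thermal drift,
retract/adhesion segments, indentation noise (noise enters force only, the
dominant AFM detection channel), finite sample thickness, and large-strain
corrections. A green recovery test therefore establishes that the estimator
inverts its own forward model under realistic sampling and noise — not that
instrument artifacts are handled; on real data the preprocessing choices
below matter more.

## Preprocessing choices

The contact-point procedure is this package's own design (the original
study's preprocessing is in code not available to this implementation): a
linear baseline is fitted over the configured pre-contact fraction of the
approach, contact is localized where the corrected force exceeds 3 baseline
SDs with 10-sample forward confirmation, and the contact sample is then
refined by a two-pass grid search minimizing the SSE of a piecewise Hertz
model (zero force before contact, $a\,h^{3/2}$ after, with the indentation
coordinate re-zeroed per candidate). The refinement is essential: at
realistic noise the 3-SD crossing sits far after true contact, so the
threshold rule alone is biased late by hundreds of samples. Even the
refined maximum-likelihood-style estimator carries an intrinsic scatter of a
few tens of samples at a signal-to-noise ratio of 20 — contact-point
uncertainty is a genuine physical limit, not an implementation detail.
Setting `refine_contact = FALSE` restores the bare threshold rule for
comparison.

All internal units are SI; readers convert from declared units at parse
time. Vendor-specific column names are handled by a user-supplied column map
rather than built-in vendor parsers, keeping I/O dependency-free and
auditable.

## Worked example

```{r example, eval = FALSE}
geom <- contact_geometry(R = 12.5e-6, nu = 0.5)
truth <- benchmark_model(2)
curve <- simulate_curve(truth, ramp_protocol(), geom, seed = 1)

cfg <- fit_config(max_terms = 3, n_attempts = 50, seed = 7)
fits <- fit_iterative(curve, geom, cfg)
n_opt <- select_terms(fits, curve, geom, cfg)
best <- fits[[n_opt]]

f <- frequency_grid(curve)
sp <- spectrum(best$model, f)
plot(f, sp$angle, log = "x", type = "l",
     xlab = "frequency (Hz)", ylab = "loss angle (deg)")
```

## Known limitations

* Multi-arm Maxwell–Kelvin–Voigt interconversion is not closed-form and is
  not implemented; only the single-arm (standard linear solid) conversion is.
* No steady-flow (fluidity) term: both networks are solids, so the loss
  angle tends to zero at both frequency extremes.
* Trapezoid quadrature limits the fastest identifiable timescale to a few
  sampling intervals; arms faster than that are absorbed into the glassy
  response.
* The open-search and iterative strategies share this package's accelerated
  local solver, which is considerably more robust than a bare bounded
  least-squares call; the stability gap between the two strategies at
  desk scale is therefore smaller than the published full-scale gap, though
  its direction is unchanged (the method-comparison test asserts exactly
  this qualitative form).
* Fits assume the repulsive approach segment of a quasi-static ramp;
  oscillatory (multiharmonic) drive schemes are out of scope.
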