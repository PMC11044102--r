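---
title: "Predictive LC×LC method optimization: models, simulator and design choices"
author: "lcxlcopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive LC×LC method optimization: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Method development in online comprehensive two-dimensional liquid
chromatography (LC×LC) requires choosing many coupled parameters: flow
rates in both dimensions, gradient programs, the modulation (sampling)
time, the make-up flow that dilutes the first-dimension effluent before it
enters the sample loop, and the loop volume itself. For mode pairings with
opposite strong solvents — the canonical case being HILIC coupled to
reversed-phase LC — every modulation transfers a plug of *strong* solvent
onto the second-dimension (²D) column. Depending on the plug volume and
its strength relative to the ²D mobile phase, this injection broadens,
deforms or outright splits the ²D peaks of weakly retained analytes.

`lcxlcopt` evaluates candidate methods in two ways:

* a fast **theoretical** route, using gradient retention theory, plate
  theory, and a closed-form injection-variance expression; and
* a **Craig counter-current simulation** route that propagates each
  analyte *and the solvent plug it sits in* through a discretized column,
  reproducing breakthrough and peak splitting that no Gaussian variance
  formula can represent.

A three-objective Pareto optimizer (maximize 2D peak capacity, minimize
analysis time, minimize total dilution) combines the two: theory screens
the full candidate grid, simulation re-evaluates only the preliminary
front. This hybrid keeps the number of expensive simulations equal to
(front size) × (number of analytes) rather than (grid size) ×
(number of analytes).

## Retention models

Two two-parameter retention laws map strong-solvent fraction
$\varphi \in [0,1]$ to the retention factor $k$:

* linear solvent strength (reversed phase): $k(\varphi) = k_0 e^{-S\varphi}$;
* adsorption (HILIC): $k(\varphi) = k_{100}\,\varphi^{-n}$.

By convention $\varphi$ is always the fraction of *that dimension's*
strong solvent (water for HILIC, acetonitrile for RP-LC); the conversion
between dimensions happens explicitly at the modulation interface
(`sample_solvent_composition()`), which prevents silent sign errors.

Gradient retention times solve the migration integral

$$\int_0^{t_R - t_0} \frac{dt}{t_0\,k(\varphi_{inlet}(t))} = 1$$

with the inlet composition given by the programmed linear ramp delayed by
the dwell time. Numerical choices:

* adaptive trapezoid quadrature of the cumulative integral with grid
  doubling until the located retention time is stable to $10^{-4}$ min,
  plus bisection inside the crossing interval — robust against the very
  steep $k(\varphi)$ of the adsorption law;
* when $k$ is composition-independent (flat program, or $S = 0$ /
  $n = 0$) the isocratic closed form $t_R = t_0(1+k)$ is returned exactly;
* the adsorption law diverges at $\varphi = 0$; inside the simulator and
  the evaluators the composition is floored at $10^{-6}$, which represents
  "effectively infinitely retained" without special-casing;
* after the programmed ramp the composition is held at the final value,
  so late analytes elute under the final isocratic conditions;
* if the integral does not reach 1 within a horizon of
  $10\,(t_{grad} + t_0 + t_{dwell} + t_{hold})$ the analyte is reported
  *not eluted* — an explicit flag, never a clipped value.

`fit_retention_parameters()` recovers $(k_0, S)$ or $(k_{100}, n)$ from
retention times observed under several gradient slopes (the classic
three-to-four gradient calibration with slopes spaced by a factor of
three). The residual sum of squares is minimized by Nelder–Mead simplex
(`stats::optim`) seeded from a coarse log-grid scan over both parameters;
on noise-free synthetic data the round trip recovers parameters to much
better than 1%.

## Theoretical performance metrics

**Injection variance.** The variance added to a ²D peak by injecting a
volume $V_{inj}$ of sample solvent is

$$\sigma_v^2 = \frac{V_{inj}^2}{\delta_{inj}^2}
  \left(\frac{1+k_e}{1+k_{ss}}\right)^2,$$

with $\delta_{inj}^2 = 8$ by default (a plug-like injection), $k_e$ the
local retention factor at the column exit at elution, and $k_{ss}$ the
retention factor in the sample solvent. A weak sample solvent
($k_{ss} \gg k_e$) focuses the band; a strong one inflates it. The
formula is exposed as a pluggable hook (`variance_fn`) so alternative
injection-variance expressions can be substituted.

**Peak widths** come from plate theory,
$\sigma = G\,t_0(1+k_e)/\sqrt{N}$, with the plate count taken from each
analyte's van Deemter curve at the operating velocity. The gradient
compression factor $G$ defaults to 1 (off); it is a single scalar the
user can set because the compression correction in the literature is not
uniquely defined for the adsorption law.

**Peak capacities.** Each dimension uses
$n_c = 1 + (t_{last} - t_{first})/(4\bar\sigma)$ with the window ending
at the *predicted last-eluting analyte*, not the programmed gradient end;
the ²D window is additionally capped at one modulation cycle. The
first-dimension value is divided by the undersampling factor
$\beta = \sqrt{1 + 0.21\,(t_s/\sigma_1)^2}$, and the 2D peak capacity is
the product $n'_{c,1} \times n_{c,2}$ (full coverage assumed;
orthogonality descriptors are out of scope).

**Dilution** multiplies the Gaussian peak-maximum dilution of both
dimensions, $DF_i = \sqrt{2\pi}\,\sigma_{v,i}/V_{inj,i}$, with the
make-up dilution $(F_1 + F_{mu})/F_1$, averaged over analytes. A focused
injection can legitimately give $DF_i < 1$ for a single stage.

**Pressure feasibility** uses Darcy's law
$\Delta P = \phi_{res}\,\eta\,L\,u/d_p^2$ with the worst-case viscosity
over the gradient span, interpolated from a shipped water/acetonitrile
table at 30 and 60 °C. The table values are the package's own
interpolation anchors chosen to represent typical water/ACN mixtures; a
user table can replace them.

## The Craig simulator

`simulate_elution()` divides the column into $N$ cells (one per
theoretical plate) and advances in transfer steps of $t_0/N$ min. Each
step (1) shifts all mobile-phase contents — analyte mobile fraction *and*
solvent composition — one cell toward the outlet, feeding the inlet from
the injection profile and then from the dwell-delayed gradient, and
(2) re-equilibrates every cell to a mobile fraction $1/(1+k(\varphi))$.
Mass leaving the last cell forms the elution profile. Because the solvent
plug travels with the mobile phase while the analyte exchanges with the
stationary phase, breakthrough arises naturally: analyte trapped in a
strong plug rides nearly unretained until it slips out of the plug's rear
edge.

Implementation notes:

* solvent parcels propagate unretained and unmixed, so the mobile
  fraction of a cell depends only on the age of its solvent parcel; all
  retention-law evaluations are precomputed per inlet step and the inner
  loop (in C++) does pure arithmetic;
* mass balance (injected = eluted + in column) is tracked at every step;
  the maximum relative error is reported on the profile and is at
  machine precision in practice;
* the isocratic point-injection limit is *exactly* the binomial Craig
  distribution $\binom{n}{r} p^r (1-p)^{n-r}$, $p = 1/(1+k)$, which the
  test suite verifies to $10^{-9}$;
* in the Gaussian limit the discrete Craig chain has elution-time
  variance $t_R^2\,q/N$ with $q = k/(1+k)$ — the plate-theory
  $t_R^2/N$ multiplied by $q$. Plate-count recovery from moments is
  therefore accurate for well-retained solutes ($k \gtrsim 20$, where
  $q \to 1$), and the Gaussian-limit tests use $k = 25$;
* the plate count is capped (default 20 000, configurable via
  `instrument_config(n_max = )`) with a warning, because simulation cost
  grows with $N^2$;
* the simulation is completely deterministic — identical inputs give
  bit-identical profiles.

**Injection profiles.** The default valve model
(`make_injection_profile()`) places the sample plug of volume
(fill fraction × loop volume) at the loop outlet; for partial fills
loop-resident mobile phase elutes first (counter-current flushing).
Exponential dispersion with a volume constant of `tail_constant`
(default 0.15 × loop volume) smears both plug interfaces. That constant
is a tunable modelling choice standing in for measured valve profiles; a
measured two-column profile can be supplied verbatim through
`injection_profile_from_table()`.

**Profile analytics.** `profile_moments()` reports the apex, first
moment, second-moment standard deviation, and the half-height width
(÷2.355). For distorted peaks the two widths deliberately diverge: the
half-height width sees only the tallest feature while the second moment
integrates everything, so the simulated metrics use the second moment.
`detect_peak_splitting()` counts maxima above 5% of the global maximum
separated by valleys below 0.8 of the lower peak.

One property worth stating precisely: the simulated second moment grows
monotonically with loop fill *below breakthrough*. Once the plug is
strong and long enough to carry analyte to the outlet, mass redistributes
between the breakthrough and retained features and the second moment is
no longer monotone in fill; the package's tests assert monotonicity in
the pre-breakthrough regime only.

## Optimizer design

`enumerate_feasible_configs()` takes the full Cartesian product of the
candidate lists and filters by pressure in both dimensions, loop capacity
$(F_1+F_{mu})\,t_s \le V_{loop}$, and cycle feasibility
$t_{grad,2} + t_{reeq} \le t_s$ (re-equilibration default 0.1 min). A
²D gradient time given as `NA` expands to $t_s - t_{reeq}$. No
constraint forces the sampling time to divide the ¹D window evenly: the
modulation runs continuously, so any sampling time is physically
realizable, and imposing a divisor rule would only thin the grid.

Per-analyte evaluation uses the **apex-fraction policy**: the ²D
injection of an analyte is the single modulation fraction containing its
¹D apex, with $V_{inj}$ equal to the full fraction volume. Analytes
genuinely spanning several fractions affect the *chromatogram* module
(which slices the ¹D Gaussian exactly), but the performance metrics use
one fraction per analyte so that each analyte contributes one ²D peak
capacity, and the policy is isolated in a single helper should a
different reading be preferred.

`hybrid_optimize()` runs the three stages described above and logs the
points removed at stage 3 — configurations that looked optimal under the
theoretical injection model but lose enough ²D peak capacity (or gain
enough dilution) under simulation to become dominated. Dominance keeps
ties: identical objective vectors all stay on the front.

## The chromatogram module

`build_2d_chromatogram()` slices each analyte's theoretical ¹D Gaussian
peak into modulation fractions, simulates the ²D elution of every
populated fraction with that fraction's mean effluent composition, and
assembles the retention-plane intensity grid. Fractions are rendered at
their midpoints. ¹D peaks are modelled as Gaussian — the autosampler
injection is small and matched, so ¹D overload is not modelled; the
simulation effort is spent where mismatch occurs, in the ²D. Shares
below $10^{-4}$ are dropped and the remainder renormalised, so the
per-analyte grid mass is conserved exactly.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_analytes()` draws log-uniform parameters emulating
small polar analytes (e.g. phenolics) on sub-2-µm HILIC/RP columns:
adsorption parameters $k_{100} \in [0.05, 0.6]$, $n \in [0.5, 2]$ (weak
to moderate HILIC retention, strongly retained at 1% water), LSS
parameters $k_0 \in [5, 500]$, $S \in [10, 40]$ (spanning
breakthrough-prone to well retained in the ²D), and van Deemter
coefficients around minimum plate heights of roughly two particle
diameters. The generator is the package's stand-in for an experimentally
measured analyte table; it reproduces the *structure* of such data, not
any particular compound set. Real data additionally contain measurement
noise in the fitted parameters, measured (asymmetric) valve profiles,
retention-law misspecification, and thermal effects such as frictional
heating — none of which the synthetic sets carry. Green tests therefore
demonstrate internal correctness of the models and algorithms, not
agreement with any particular instrument.

All randomness in the package lives in this generator; the simulator and
optimizer are seed-free and deterministic.

## Problem sizes

The shipped tests and the acceptance script run at deliberately modest
sizes chosen to exercise every code path while keeping a full run in
well under a minute of simulation time: Craig columns of 200–1000 cells
(binomial and Gaussian-limit checks), a 27-configuration optimization
grid with three synthetic analytes for the hybrid-versus-full-simulation
comparison, and 500-point fronts for the dominance oracle. Production
use scales the same functions up through `instrument_config(n_max = )`
and larger candidate lists.

## Known limitations

* No nonlinear isotherms: "overload" here is volume/solvent-strength
  overload, not thermodynamic column overload.
* No axial dispersion beyond the intrinsic Craig broadening; the Craig
  variance carries the $k/(1+k)$ factor discussed above, which
  understates widths of very weakly retained isocratic solutes relative
  to plate theory.
* Orthogonality/coverage corrections and resolution-based objectives are
  hooks only; the 2D peak capacity assumes full coverage.
* Viscosity, temperature and frictional-heating effects on plate height
  are not modelled; pressure feasibility uses a static viscosity table.
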