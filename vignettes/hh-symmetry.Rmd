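---
title: "Methods: symmetry analysis of Hodgkin–Huxley membrane dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symmetry analysis of Hodgkin-Huxley membrane dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhsym)
```

## Scope and model

`hhsym` treats the classical Hodgkin–Huxley (HH) membrane model as a
dynamical system with an explicit symmetry structure. The state is
(E, m, h, n): membrane potential in mV and three dimensionless gating
variables, with

$$C_M \frac{dE}{dt} = I_{inj} - \bar g_{Na} m^3 h (E - E_{Na})
  - \bar g_K n^4 (E - E_K) - \bar g_L (E - E_L),$$

and first-order kinetics $d\xi/dt = \alpha(E)(1-\xi) - \beta(E)\xi$ for
each gate. Units are fixed package-wide — mV, ms, mS/cm², µA/cm²,
µF/cm² — with no conversion layer, so a number is wrong only if it is
wrong, never because of hidden unit arithmetic.

**Voltage convention.** All voltages are absolute membrane potentials
(rest near −65 mV). The canonical rate constants carry the −65 mV shift
inside their prefactors: e.g. the sodium activation closing rate is
$\beta_m = 0.108\,e^{-E/18}$ ms⁻¹, which equals the textbook
$4\,e^{-(V+65)/18}$ because $4 e^{-65/18} = 0.10797 \approx 0.108$. The
same identity holds for $\alpha_h$ (0.0027 vs 0.07) and $\beta_n$
(0.0555 vs 0.125). We verified each prefactor algebraically before
freezing it.

**Functional forms.** Each rate is one of four parameterised families
(`linoverexp`, `pure_exp`, `logistic`, `constant`), each described by a
prefactor, an offset voltage and an e-fold scale. The sodium
inactivation closing rate is implemented as the logistic
$1/(1+e^{-(E+35)/10})$: among the sign variants of that expression it is
the only one that is nonnegative at all voltages, and nonnegativity of
both rates is exactly what makes the gate interval [0, 1] forward
invariant. For the same reason the potassium gate relaxes through its
own value ($-\beta_n n$, not any other state variable): the n-equation
is the n-gate's closed/open bookkeeping and anything else would be
dimensionally and biophysically incoherent.

## Numerical choices

* **Removable singularities.** The linear-over-exponential rates are
  0/0 at one voltage ($\alpha_m$ at −40 mV, $\alpha_n$ at −55 mV).
  Within 10⁻⁷ mV of the singular point the analytic series limit
  (prefactor × e-fold scale) is returned; elsewhere the ratio is
  computed through `expm1`, which is accurate arbitrarily close to the
  window. This keeps the rate C¹-continuous across the joint.
* **Overflow guard.** Any exponential argument beyond ±700 is rejected
  with a diagnostic rather than silently saturating to `Inf` or 0;
  the physiological range of interest is [−120, 60] mV, far inside the
  guard.
* **Integrator.** Classical fixed-step 4th-order Runge–Kutta with
  default dt = 0.01 ms, about 1/20 of the fastest gate time constant.
  A fixed-step explicit scheme was chosen deliberately: runs are
  deterministic and bitwise reproducible, the time-translation audit
  can demand sup-norm agreement at 10⁻¹⁰ because a shifted run performs
  *identical* floating-point arithmetic (time grids are built as
  origin + k·dt and the right-hand side is autonomous within a
  segment), and the 4th-order convergence contract is directly testable
  (halving dt shrinks the error ≈16×). Steps above 0.05 ms are accepted
  but recorded with a stability warning.
* **Voltage clamp.** Under a command potential only the gates evolve;
  the voltage coordinate is prescribed, not integrated. Each gate then
  satisfies a scalar linear ODE whose closed form
  $\xi(t) = \xi_\infty + (\xi_0 - \xi_\infty)e^{-t/\tau}$ serves as the
  integrator's oracle (agreement within 10⁻⁵ is asserted for 12
  gate × step combinations).
* **Finite differences.** Voltage log-slopes use central differences at
  h = 10⁻³ mV; numerical Lie brackets use h = 10⁻⁵ in the field
  coordinates. Both are far from the truncation/rounding crossover for
  the smooth coefficients involved.

## The symmetry layer

Three generators act on the coordinates (θ, g, t): the conformational
rotation $X_c = \partial_\theta$, conductance scaling
$X_g = g\,\partial_g$, and time translation $X_t = \partial_t$. The
gate is the projection $\xi = (1+\cos\theta)/2$, which is why it cannot
leave [0, 1]; `check_bounds` verifies the dynamical counterpart (the
simulated gates never stray beyond 10⁻⁹).

**Brackets, twice.** `lie_bracket` has two routes: an exact symbolic
route that differentiates the component expressions with base R's `D()`
and returns another `vector_field` (so brackets nest, enabling Jacobi
identity checks at machine accuracy), and a numeric route that builds
the Jacobians by central differences at a point. The test-suite uses
the symbolic route as the oracle and cross-checks the numeric route on
random polynomial fields; antisymmetry of the numeric route is enforced
at 10⁻⁸.

**Structure constants.** The voltage–time coupling constants are read
off the kinetics: each exponential rate factor has an e-fold scale
(10, 18, 20, 10, 10, 80 mV across the six canonical components), the
aggregate $E_0$ is their arithmetic mean (24.67 mV — the simplest
declared, reproducible aggregate, and comfortably inside the 20–30 mV
range a per-gate inspection suggests), and $\gamma_2 = 1/E_0 = 0.0405$
mV⁻¹. $\gamma_1$ is reported as the same order of magnitude with an
explicit `approximate` flag and is excluded from pass/fail gates: its
normalisation is not fixed by the kinetics, only its scale.
Voltage-independent (`constant`) components carry no e-fold scale and
are excluded with a notice. For context the report also carries the
thermal voltage $k_BT/e$ (26.7 mV at 310 K) and `q10_scale` applies the
standard $Q_{10}^{(T-T_{ref})/10}$ kinetic temperature scaling.

**Realizing the nonzero brackets.** The bare generators above commute
pairwise, so they realise the commutation table
$[X_c,X_g]=0,\ [X_c,X_t]=\gamma_1X_g,\ [X_g,X_t]=\gamma_2X_g$
only with $\gamma_1=\gamma_2=0$. `verify_commutation_table` therefore
reports relations with a nonzero expected γ as **unrealized** (not
failed) when given the bare fields. A genuine realization must couple
the sectors. Requiring $[g\partial_g,\ f(\theta,g)\partial_g] =
\gamma_2\, g\partial_g$ gives the ODE $g f_g - f = \gamma_2 g$, whose
minimal solution is $f = \gamma_2\, g\log g$ — a coefficient
proportional to $t\,g$ or $g$ alone is homogeneous of degree one in $g$
and brackets to zero, so the logarithm is essential. Adding the
analogous conformational coupling yields the shipped
`coupled_realization`:
$$X_t \mapsto \partial_t + (\gamma_1\theta + \gamma_2\log g)\,
  g\,\partial_g \quad (g > 0),$$
which satisfies all three relations exactly (symbolic residuals at
rounding level, asserted below 10⁻⁶ on a sample grid).

## The synthetic clamp generator

`synthesize_clamp` emulates the step voltage-clamp experiments from
which gating exponents are classically inferred: hold at rest, step to
a command voltage, record macroscopic conductance
$g(t) = \bar g\,\xi_{act}^p\,\xi_{inact}^q$. Design choices:

* Gates are evolved by the **closed-form** relaxation at the clamp
  voltage, not the ODE integrator, so the fixtures are oracle-exact and
  any fitting error is attributable to the fitter.
* Default conditions mirror the classical protocol at desk scale:
  −65 mV hold, steps spanning −40…+20 mV, 20 ms traces (≥5 relaxation
  time constants at every commanded voltage — a warning fires
  otherwise) sampled at 0.05 ms, classical maximal conductances
  (120 mS/cm² Na, 36 mS/cm² K).
* Noise is additive i.i.d. Gaussian on conductance with a recorded
  seed; the generator restores the global RNG state so library code
  never perturbs a user's stream. The 0.5 mS/cm² level used in the
  robustness tests is ≈4% of the largest trace amplitude — moderate for
  a macroscopic clamp recording.
* Non-integer activation exponents are accepted deliberately: they
  generate the symmetry-broken channels the fractional diagnostic is
  designed to detect.

What the generator does **not** emulate: series-resistance and
space-clamp errors, leak subtraction artifacts, capacitive transients,
and stochastic single-channel gating. Recovery tests on these fixtures
therefore demonstrate the *identifiability logic* of the fitting
procedure — that the integer exponent is recoverable when the model
class is correct and flagged when it is not — and say nothing about
robustness to those instrumental nonidealities in real recordings.

## Exponent inference

Fitting exploits the clamp design: at a known command voltage the gate
time courses follow from the canonical rate functions, so for each
candidate exponent pair only the maximal conductance is free and is
profiled out by linear least squares of $g$ on
$\xi_{act}^p \xi_{inact}^q$ (all traces stacked). The reported exponent
minimises the residual sum of squares over the integer grid (default
p ∈ 1…8, q ∈ 0…2); exact ties break toward the smallest exponent, the
most parsimonious representation.

* **Weak identifiability.** When the candidate inactivation exponents
  barely change the achievable residual the data do not constrain q. A
  max/min SSE *ratio* degenerates on noiseless data, where the SSE at
  the true exponent is numerically zero; the diagnostic instead flags q
  as weakly identified when the spread of the best SSE across q is
  below 0.1% of the total signal power. Traces truncated well before
  inactivation develops (e.g. 0.1 ms against a ≈1 ms inactivation time
  constant) trigger the flag; full-length traces do not.
* **Symmetry-breaking diagnostic.** A golden-section/parabolic
  minimisation (`stats::optimize`) over real-valued p ∈ [0.5, 8] (with
  q at its integer estimate) provides the continuous-exponent
  comparison. The fit is flagged when the best integer SSE exceeds 1.5×
  the fractional SSE *and* the excess is more than 0.1% of the total
  signal power — the two-part rule keeps noiseless integer data (both
  SSEs ≈ 0) and well-fit noisy data (both SSEs ≈ the noise floor) from
  triggering. Data generated with exponent 2.5 are flagged across
  seeds, with the continuous optimum recovering ≈2.5.

## Problem sizes and tolerances

The default test and acceptance workloads are desk-scale by design:
clamp datasets are 3–4 traces × 20 ms at 0.05 ms sampling (≈1200–1600
points per fit), simulations 10–50 ms at dt = 0.01 ms, ensemble checks
up to 1000 noisy traces of 51 samples. Tolerances are stated per check
and deliberately tight where determinism earns it: gate excursion
10⁻⁹, time-shift sup-norm 10⁻¹⁰, conductance-ratio invariance exact,
clamp-vs-closed-form 10⁻⁵, steady-state derivative identity 10⁻⁶ on a
141-point grid, bracket antisymmetry 10⁻⁸ and Jacobi residuals 10⁻⁵.

## Known limitations

* The exponent fitter assumes the canonical kinetics are known exactly;
  it does not jointly estimate rate-function parameters (that joint
  problem is ill-posed on single-step traces and out of scope).
* $\gamma_1$ has no canonical normalisation here; treat it as an order
  of magnitude.
* The winding-number bookkeeping implements the net-exponent arithmetic
  p − q; no claim is made for channels outside the activation ×
  inactivation product form.
* The composite rate forms (`linoverexp`, `logistic`) are *not* pure
  exponentials; `check_exponential_form` reports them as composite with
  a local log-slope rather than forcing an exponential reading. The
  exponential idealisation is accurate only in each form's exponential
  tail.
* Temperature enters only through the Q₁₀ scalar and the thermal
  voltage; no temperature-dependent rate tables.
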