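# hhsym — symmetry analysis of Hodgkin–Huxley membrane dynamics

`hhsym` is an R toolbox for studying the *symmetry structure* of the
classical Hodgkin–Huxley (HH) conductance model of excitable membranes.
It is aimed at computational neuroscientists and biophysicists who want
to go beyond simulating the equations and ask *why they take the form
they do*: why gating variables are bounded in [0, 1], why rate functions
are (near-)exponential in voltage, why conductances carry integer gating
exponents such as m³h and n⁴, and how these facts are organised by a
three-generator Lie algebra.

## The model

The membrane current obeys

    I_M = ḡ_Na m³h (E − E_Na) + ḡ_K n⁴ (E − E_K) + ḡ_L (E − E_L) + C_M dE/dt

with first-order gate kinetics dξ/dt = α(E)(1 − ξ) − β(E)ξ for
ξ ∈ {m, h, n}. The package uses absolute membrane potential (rest near
−65 mV); the canonical rate functions, with the resting shift absorbed
into the prefactors, are

    α_m = 0.1 (E+40) / (1 − e^{−(E+40)/10})     β_m = 0.108 e^{−E/18}
    α_h = 0.0027 e^{−E/20}                      β_h = 1 / (1 + e^{−(E+35)/10})
    α_n = 0.01 (E+55) / (1 − e^{−(E+55)/10})    β_n = 0.0555 e^{−E/80}

(ms⁻¹, mV). Derived per-gate quantities are the steady state
ξ∞ = α/(α+β) and time constant τ = 1/(α+β).

On top of the dynamics, `hhsym` implements the symmetry layer:

* **Conformational compactness.** The gate is the projection
  ξ = (1 + cos θ)/2 of a circular coordinate, which is what bounds it in
  [0, 1] (`gate_from_angle`, `check_bounds`).
* **Conductance scaling.** Scaling every maximal conductance by λ leaves
  conductance ratios invariant while ionic current scales exactly by λ
  (`check_conductance_scaling`).
* **Time translation.** The autonomous dynamics are invariant under time
  shifts (`check_time_translation`).
* **Lie algebra.** The generators X_c = ∂/∂θ, X_g = g ∂/∂g, X_t = ∂/∂t
  close into an so(2) ⋉ ℝ² algebra with structure constants γ₁, γ₂ set
  by the voltage sensitivity of the kinetics: [X_c, X_g] = 0,
  [X_c, X_t] = γ₁X_g, [X_g, X_t] = γ₂X_g. Brackets are computed both
  symbolically and by central differences (`lie_bracket`,
  `verify_commutation_table`, `coupled_realization`), and
  γ₂ = 1/E₀ is estimated from the e-fold voltage scales of the rate
  functions (`estimate_structure_constants`), with the thermal scale
  k_B·T/e and Q₁₀ temperature scaling for context (`thermal_voltage`,
  `q10_scale`).
* **Integer exponents.** Because conductance must transform as a
  single-valued representation of the compact rotation group, gating
  exponents are integers — the representation's winding number
  (p − q, e.g. 2 for sodium's m³h, 4 for potassium's n⁴). `hhsym` infers
  them from voltage-clamp conductance traces by profiled integer
  grid-search least squares (`fit_k_exponent`, `fit_na_exponents`), with
  a continuous-exponent diagnostic that flags symmetry breaking
  (fractional effective exponents).

A seeded synthetic voltage-clamp generator (`synthesize_clamp`) produces
oracle-exact step-protocol conductance traces (optionally with Gaussian
noise) for all fitting and audit workflows.

## Worked example

```r
library(hhsym)
params <- membrane_params()          # classical squid values: 120/36/0.3 mS/cm2

estimate_structure_constants()
#> <structure_constant_report>
#>   e-fold scales (mV): m.alpha=10, m.beta=18, h.alpha=20, h.beta=10, n.alpha=10, n.beta=80
#>   E0 = 24.6667 mV;  gamma2 = 0.0405405 mV^-1;  gamma1 ~ 0.0405405 mV^-1 (order of magnitude)
#>   thermal E0 at 310 K: 26.71 mV

ds <- synthesize_clamp(params, "K", steps = c(-40, -20, 0, 20), hold = -65,
                       duration = 20, dt = 0.05, exponents = c(4, 0),
                       noise_sd = 0.5, seed = 42)
fit_k_exponent(ds)
#> <exponent_fit> K channel: p = 4  | gmax = 35.979 mS/cm2 | winding number = 4
#>   SSE at optimum: 395.44 | fractional optimum p = 4.0047 (SSE 395.37 )

traj <- simulate_membrane(params, current_clamp(50, 10))   # 10 uA/cm2 step
max(traj$E)                          # spike overshoot: +40.3 mV at t = 2.14 ms
check_bounds(traj)
#> <hh_audit> gate_bounds : PASS | metric = 0 | tolerance = 1e-09
```

Reading the output: the six e-fold scales (10–80 mV) aggregate to a
representative voltage scale E₀ ≈ 24.7 mV, i.e. γ₂ ≈ 0.041 mV⁻¹, close
to the 26.7 mV thermal voltage at 37 °C. The exponent fit recovers the
potassium gating exponent p = 4 and a maximal conductance of ≈36 mS/cm²
from noisy traces; the continuous-exponent diagnostic sits at ≈4.005
with essentially the same residual, so there is no evidence of symmetry
breaking. The current-clamp run fires an action potential peaking at
+40.3 mV while every gate stays inside [0, 1] to machine accuracy.

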