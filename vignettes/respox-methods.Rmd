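---
title: "Methods: respiratory-system modelling and adaptive oxygen-supply control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory-system modelling and adaptive oxygen-supply control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respox)
```

## The problem

Severe respiratory infection stiffens and thickens the alveolar walls,
impairing oxygen exchange; the SpO~2~ of such patients falls below 90% and
supplemental oxygen must be titrated continuously. Manual titration is slow
and over-oxygenation is itself harmful, so the question this package
addresses is: given a dynamical model of the oxygen path from the cylinder
valve to the capillary blood, can a controller regulate the supply so the
patient's SpO~2~ tracks a commanded level quickly, without overshoot, and
without retuning when the patient's condition (delays, exchange parameters)
changes?

`respox` provides the plant model, three controllers of increasing
sophistication (PID, MIT-rule MRAC, and the set-point-modulated fuzzy-PI
MRAC — SFPIMRAC), and a deterministic fixed-step closed-loop simulator for
studying them.

## The plant

### Airway morphometry and the electrical analogy

The conducting airways are a dichotomously branching tree: generation $z$
has $2^z$ identical branches of diameter $d$, length $l$, total
cross-section $s$, and mean flow velocity $u$. Each generation maps onto an
electrical RLC triple:

$$R = \frac{8\mu l}{\pi r^4}\cdot\frac{1}{n}, \qquad
  L = \frac{\rho l}{s}, \qquad
  C = \frac{l s}{\rho\, n\, u^2},$$

with $r = d/2$. Two conventions matter and are fixed by validating against
the shipped reference table: the resistance is the *parallel* combination
over the $n$ branches (the printed per-generation resistances match the
Poiseuille value only after dividing by $n$), while the inertance uses the
listed *total* area directly. Computation is in cgs units with air at
roughly 20 °C ($\mu = 1.81\times 10^{-4}$ P,
$\rho = 1.225\times 10^{-3}$ g/cm³ — the reference table never states its
air constants, and these standard values reproduce its R and L columns
within a few percent), then converted to cm H~2~O and litres; the
conversion is a pure scalar $1000/980.665 \approx 1.0197$ on R and L.

The shipped morphometry fixture is transcribed verbatim and never
recomputed. Its generation-0 compliance (0.06311 L/cm H~2~O) disagrees
with the formula by a factor of ten while generations 1–3 agree within a
few percent; we treat this as a transcription anomaly in the source, keep
the printed value in the fixture, and exclude that single cell from
formula-validation tests. Four distal generations (where the printed
geometry itself is irregular, e.g. the generation-22 length) also miss the
10% band; the tests require 20 of 24 resistances to agree.

### Lumped airway sections

For simulation the tree is lumped into four cascaded second-order sections
— nasal cavity, trachea, bronchi, alveoli — each
$1/(LC\,s^2 + RC\,s + 1)$ with unity DC gain. The canonical coefficients
are the published segment polynomials; a reconstruction path from the
section R, L, C table exists for cross-validation only, because the two
sources disagree in the fourth digit for the nasal s-coefficient (2.165 vs
2.156) and the validation tolerance absorbs the 0.4% gap. Respiratory
distress is modelled as a 100–1000-fold loss of alveolar compliance; the
distressed-alveoli biquad
$1/(10^{-10}s^2 + 1.15\times10^{-6}s + 1)$ is used verbatim. The cascade
is an exact polynomial convolution (order-8 denominator), so tests can
compare coefficients literally.

### Gas exchange

Oxygen transfer through the alveolar-air / lung-tissue / capillary-blood
compartments is a linear exchange network,

$$\dot v_{AA} = k_{AA}(v_{LT}-v_{AA}), \quad
  \dot v_{LT} = k_{TT}(v_{CB}-v_{LT}) + k_{AT}(v_{AA}-v_{LT}), \quad
  \dot v_{CB} = k_{BB}(v_{LT}-v_{CB}),$$

with printed rates $k_{AA}=0.2429$, $k_{AT}=4.76$, $k_{TT}=15.87$,
$k_{BB}=88.88$ s⁻¹. Two structural facts are asserted by tests: the
autonomous coupling matrix is singular (pure exchange conserves the
potential at equal states), and its negative trace, 109.75, matches the
$s^2$ coefficient (110) of the canonical third-order transfer function

$$TF_{BO2}(s) = \frac{20s^2 + 200s + 62}{s^3 + 110s^2 + 350s + 67}$$

within 0.25%. Note that this printed model and the autonomous ODEs are
*not* the same object: a singular state matrix cannot produce the nonzero
denominator constant 67. The transfer function is therefore canonical for
all closed-loop work, and the ODE path (with an explicit input coupling,
default $k_{in} = k_{AA}$) is provided for time-domain experiments and
labelled non-canonical. Similarly, the rate constants cannot all be
recovered from the physical parameter table under any single unit
convention we tried: with a 0.1 scale factor and the mid-range diffusion
rate $D_{TB} = 8.0\times10^{-12}$ L/s the blood-side rates 15.87 and 88.88
come out exactly, but 0.2429 and 4.76 do not. `derive_rate_constants()`
therefore exposes the scale explicitly (default 1, nothing hidden) and
`canonical_rates()` returns the printed constants.

The parameter file also corrects two duplicated labels in the source table
(the second "sigma_A" is the tissue coefficient; the second "D_TA" is
$D_{TB}$), with the correction trail in the YAML comments.

The full patient model is $TP_M = TF_M \times TF_{BO2}$ (order-11
denominator, DC gain 62/67 ≈ 0.925), optionally with a transport delay
between the airway and exchange blocks (0.25–0.75 s physiologically).
Dead time is kept symbolic on the transfer-function object and realized
exactly — as a phase factor in the frequency response and as a whole-sample
shift in the simulator. No Padé approximation is used anywhere, so there
is no approximation order to argue about.

Stability is checked two ways: denominator roots (all strictly left of the
imaginary axis) and Bode margins. The composite plant's gain never reaches
0 dB (its DC gain is 0.925 and it only rolls off), so the phase margin is
reported as `Inf` with an explicit no-crossover flag — the convention for
systems that cannot reach the critical point.

## The controllers

### MRAC and the MIT rule

The plant output $y$ is driven to follow a fixed reference model
$y_m = r/(s^2+2.5s+1)$ by adapting a single feedforward parameter
$\theta$ in $u = r\theta$, descending the loss $F(\theta)=e^2/2$ with
$e = y - y_m$:

$$\frac{d\theta}{dt} = -\gamma_1\, y_m\, e.$$

The test suite verifies parameter recovery on the classic matched
first-order pair (plant $2/(s+1)$, reference $1/(s+1)$): $\theta$
converges to $K_0/K = 0.5$, and the package's fixed-step trajectory agrees
with a tight-tolerance `deSolve` integration of the same coupled ODEs to
three decimals. Choosing $\gamma_1$ for the respiratory plant is
notoriously delicate — the shipped sweep {5e-5, 1e-4, 2e-4} spans
well-damped-but-slow to oscillatory-non-settling behavior and is the
package's own grid (the source studies print none).

### Fuzzy adaptation

SFPIMRAC replaces the fixed $\gamma_1 e$ factor by a gain $m(e, \Delta e)$
inferred online: five equal-width triangular membership functions on
$[-100, 100]$ (% SpO~2~) for $e$ and $\Delta e$ and on $[-1, 1]$ for $m$,
a 25-rule table, and Mamdani inference. Three design points the sources
leave open are pinned here, with reasons:

* **Implication is product, not min.** With min (clipped consequents) the
  inferred gain is *not* monotone along the $e = \Delta e$ diagonal: at
  (−75, −75) all firing rules map to NB at strength 0.5 and the clipped
  centroid is −0.806, while at (−50, −50) it is −0.833 — the surface dips
  outward. With product (scaled consequents) the centroid of a
  single-label aggregate is strength-invariant and the diagonal is
  monotone non-decreasing, which is both the physically sensible shape and
  an invariant the test suite asserts. Both are standard Mamdani variants.
* **Centroid defuzzification over the universe.** The output universe is
  discretized on a symmetric 201-point grid (so the centroid at rest is
  exactly zero). Boundary labels peak at the universe edge; the corner
  gain is therefore ±0.837, i.e. "high" but not ±1 — consistent with the
  qualitative corner behavior the rule table encodes (signs are what the
  acceptance checks assert).
* **Input scaling and the adaptation integrand.** The law integrates
  $$\frac{d\theta}{dt} = -m(G_e e,\; G_{de}\,\Delta e)\cdot
    \frac{y_m}{y_{scale}}, \qquad y_{scale}=100,$$
  with defaults $G_e = 1$, $G_{de} = 5$. The normalization by the SpO~2~
  span is load-bearing: with $y_m$ in raw percent (≈95) a saturated $m$
  slews $\theta$ at ±95/s while the equilibrium $\theta$ is ≈1.08, and
  simulation shows the loop then limit-cycles with ±20% swings. Reading
  $y_m$ as a fraction of scale bounds the slew at ~1/s. Near equilibrium
  the fuzzy stage has slope $\partial m/\partial e \approx 0.02$ per
  %SpO~2~, so the adaptation loop gain is
  $r' \cdot (y_m/100) \cdot 0.02 \cdot G_e \approx 2 G_e$ per second
  against a plant whose slowest pole is 0.2 rad/s; $G_e = 1$ puts the
  adaptation crossover in the plant's bandwidth, and the derivative lead
  $G_{de}/G_e = 5$ s supplies the phase that keeps the loop damped when
  0.3–0.7 s transport delays are inserted. With these defaults every
  shipped scenario converges with zero overshoot; the tests assert that.
* The memoryless reading of the published adaptation law
  ($\theta = -m\,y_m$ applied directly) forces $u = 0$ whenever $e = 0$
  and cannot hold an operating point; it contradicts the rule table's own
  "zero error → maintain the same flow" row. The integrated form above is
  therefore the package default, and the memoryless variant is available
  behind `literal = TRUE` for comparison.

### Set-point modulation

The commanded set-point is temporarily inflated or deflated by the current
tracking error, $r' = r + (r - y)$ clipped to $[0, 100]$, and the control
is $u = r'\theta$ clamped to $[0, u_{max}]$ (a supply cannot be negative;
default $u_{max} = 200$% of scale). At $y = r$ the modulation vanishes, so
the steady-state target is unchanged; during undershoot it boosts the
drive, during overshoot it backs off. The reference model is driven by the
raw command $r$ by default (the target trajectory stays fixed); a
configuration switch drives it with $r'$ instead, since the original
block-diagram is ambiguous on this point.

### PID baseline

The PID gains are nowhere specified in the source studies; the shipped
baseline ($k_p = 1$, $k_i = 0.3$, $k_d = 0$, clamped to $[0, 200]$ with
integrator-freeze anti-windup) is a documented hand-tuning on the
composite plant: fast enough to be a fair comparator, and visibly
overshooting — which is exactly why an overshoot-free adaptive scheme is
preferable for oxygen therapy.

## The simulator

A single global fixed step (default $dt = 1$ ms) advances every block:
exact zero-order-hold discretizations (via the augmented matrix
exponential) of the source lag, the four airway biquads, the gas-exchange
block, and the reference model, chained with delay lines that shift by
whole samples (rounding to the nearest sample is recorded on the delay
object). Each block's output is its state output before consuming the
current input, so the loop is strictly causal and there are no algebraic
loops. Consequences the tests verify: with zero measurement noise the
engine is bit-deterministic; halving $dt$ changes the closed-loop steady
state by less than 0.1%; cascaded unity-DC blocks settle at the composite
DC gain predicted in the frequency domain.

Scenario horizons are the package's own choice (the source trajectories
are figures without printed time axes): 60 s contains settling for every
tracking scenario (SFPIMRAC settles in ≈22 s at both studied set-points),
120 s for the MRAC sweep and the load event. The load event follows the
source description as a set-point drop (95 → 80 for 20 s, then back, with
a 0.3 s input delay); an additive output disturbance would be an
alternative reading and can be configured manually.

Optional Gaussian measurement noise is the only randomness; a seed is
mandatory when the noise is on, and the engine restores the caller's RNG
state.

## What the scenarios do and do not show

The scenario library is a faithful reconstruction of a simulation study:
a linear time-invariant plant, piecewise-constant commands, noise-free
measurements by default. Passing tests therefore demonstrate properties
of the *model* — tracking without overshoot, robustness to the modelled
delays and to the printed gas-exchange perturbations — not clinical
performance. Real patients present nonlinear, time-varying dynamics,
saturation-dependent oximeter accuracy, motion artifacts, and
physiological feedback none of which is represented here; the package is
a controller-design testbed, not a medical device.

## Known limitations

* The airway model is four lumped sections; no distributed ladder network,
  no frequency-dependent (Womersley) resistance.
* Gas exchange is oxygen-only: no CO~2~/bicarbonate chemistry, no
  hemoglobin-binding kinetics, no ventilation–perfusion heterogeneity.
* The printed gas-exchange transfer function is taken verbatim even where
  its provenance (numerator, denominator constant) cannot be re-derived
  from the compartment model; the discrepancies are documented above
  rather than resolved.
* No discrete-time frequency-domain design, no Lyapunov-based MRAC
  variants, no stability proofs — robustness is established by simulation
  over the shipped scenario grid only.
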