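---
title: "A bi-hemispheric cerebellar rate network controlling an inverted pendulum: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bicnn methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`bicnn` implements a rate-coded cerebellar microcircuit, duplicated into a
left and a right hemisphere, acting as an adaptive side-path of a classical
PD feedback controller that balances and steers a simulated two-wheel
inverted-pendulum robot. The wheel angle $\varphi(t)$ must track
$\varphi_{ref}(t) = \pi \sin(2\pi\,0.25\,t)$ while the body tilt
$\theta(t)$ stays near zero; everything runs at the 10 ms control period.

Each hemisphere is a spatially embedded network of 4694 nodes: 281
mossy-fiber (mf) glomeruli, 4096 granule (gr) cells, 28 Golgi (Go) cells,
274 basket/stellate (ba) cells and 15 Purkinje (Pk) cells, placed by
rejection sampling in (granular layer) and on top of (molecular layer) a
100 um cube, wired by a nearest-neighbour rule under fixed per-class
convergences (mf→gr 4, Go→gr 4, mf→Go 66, gr→Go 1639, ba→Go 28, gr→ba 41,
Pk→ba 3, pf→Pk 1024, ba→Pk 110; 110,358 synapses per hemisphere).
Initial weights are truncated-normal magnitudes (mean 0.9, sd 0.1, range
[0.8, 1]) scaled by $d = 1/(\text{class in-degree})$, negative for
inhibitory classes. The network is stored in Address Event Representation
(AER): vectors `ID`, `N_P`, `P`, `W` plus population id ranges.

Neurons are saturated-affine rate units centered at the resting rate 0.5:
a neuron's target rate is $0.5 + \sum_i w_i (r_i - 0.5)$ clipped to
$[0,1]$, updated population-by-population in circuit order (gr, Go, ba,
Pk) each control step.

Two plastic sites drive adaptation. At pf–Pk synapses,

$$\Delta W = \begin{cases}
\gamma_{LTD}\, cf(t)\, pf_i(t) & cf(t) > cf_{spont}\\
\gamma_{LTP}\, pf_i(t) & cf(t) < cf_{spont}
\end{cases}$$

with $\gamma_{LTD} = -4\times10^{-6}$, $\gamma_{LTP} = 0.3\times10^{-6}$
per step and $cf_{spont} = 0.05$. At Pk–Vn synapses,
$\Delta W = \gamma\, Vn(t)\,(Pk_j(t) - 0.5)$ with $\gamma = 10^{-4}$.
The climbing fiber (cf) of each hemisphere carries directional kinematic
error: $raw = g_e (\varphi_e + w_v \dot\varphi_e)$,
$cf_{left} = \mathrm{clip}(cf_{spont} + raw)$,
$cf_{right} = \mathrm{clip}(cf_{spont} - raw)$, so an error in a
hemisphere's non-preferred direction dips its cf below the spontaneous
rate — the property the spontaneous level exists to carry.

The vestibular output combines the pathways:
$vn = \mathrm{clip}(pd - (\sum_j W^{R}_j Pk^R_j - \sum_j W^{L}_j Pk^L_j))$,
i.e. the left hemisphere enters inverted.

## Parameters that matter, and why

| parameter | default | units | rationale |
|---|---|---|---|
| control period | 0.01 | s | robot sampling period |
| `rate_relax` | 0.3 | – | first-order neuron relaxation per step (membrane time constant ≈ 23 ms). The memoryless unit (`relax = 1`) makes the gr–Go and ba–Pk loops oscillate at the Nyquist period and the two hemispheres decorrelate violently; a 2–3-step relaxation restores the slow rate dynamics the circuit assumes. |
| `error_gain` | 0.02 | 1/rad | maps kinematic error into cf rate. Small on purpose: the LTD/LTP equilibrium is informative only while cf stays near `cf_spont`; with gains of order $1/\pi$ the early-learning errors saturate cf, LTD floors entire weight tables within a few cycles, and the controller locks into a degenerate fixed point in which the cerebellar output cancels the PD command and the robot parks off-reference. |
| `w_v` | 0.1 | s | velocity-error weight in cf (phase lead). |
| mossy full-scales | ref: $\pi$, $\pi^2/2$; errors: 3x shallower | rad, rad/s | error and efference channels are encoded at one third the modulation depth of the reference channels. Deeply modulated error channels make the learned pf–Pk pattern act as a parasitic feedback controller around the plant (positive feedback at DC for one error sign), which destabilizes learning; shallow error channels keep the reference channels as the feedforward basis while still letting slow DC transfer happen. |
| `theta_damping` | 0.01 | N m s/rad | structural/bearing pitch damping. Sets the ultimate gain of the sampled proportional loop and hence the Ziegler–Nichols PD stiffness; with less damping the tuned PD is too soft to coexist with the untrained cerebellar output. |
| motor constant | 0.25 | N m per unit command | torque authority of the single drive motor. |
| load | 0.3 kg at 0.175 m | kg, m | "50% of the robot's mass placed on top"; the height is chosen so the stiffened plant sits just outside the PD-only stability margin (PD falls within ~5 cycles of onset) while remaining inside the better-tracking biCNN margin. |
| `friction_asym` | 0.05 | – | directional viscous-friction asymmetry emulating the intrinsic forward/backward differences of a physical robot; makes baseline forward and backward RSE differ. |

PD gains are not hand-picked: `tune_pd()` runs the ultimate-gain procedure
on the body-tilt loop (raise the proportional gain until a sustained
oscillation at $K_u$ with period $T_u$; here the stabilizable band of a
sampled inverted pendulum is an interval and the classical oscillation
appears at its *upper* edge), sets $K_p = 0.8K_u$, $K_d = K_p T_u/8$, and
then grid-selects the wheel-loop pair on the 0.1 Hz design task. The
frozen result (`default_pd_gains()`) tracks the 0.1 Hz design task
indefinitely and the 0.25 Hz task with RSE ≈ 1 rad — mediocre on purpose:
the cerebellar pathway is what improves it (to ≈ 0.3 rad within 40
cycles).

## What the closed-loop experiments emulate

`run_scenario()` executes: read sensors → encode 7 signals into 562 mf
channels (round-robin, truncated at 562) → build the cf pair → one staged
update of each hemisphere → cerebellar combination → $vn = pd - bicnn$ →
plant step (RK4 at 1 ms) → plasticity. Perturbations switch on at cycle
50 of 100: a centered or fore/aft-offset 300 g load, or a ±10° platform
tilt. Repeats rebuild both hemispheres from fresh seeds ("hemisphere
uniqueness") against the same plant.

The directional performance metric splits each cycle by the sign of the
reference velocity (forward = rising reference) and reports the RSE of
$\varphi$ and $\theta$ per direction; cycles at or after a fall are
reported as `Inf`. The split can also be computed from a time-shifted
copy of the reference (`split = "shift"`), since the phase convention of
the original split is ambiguous at 0.25 Hz; the velocity split is the
default because it labels forward/backward motion robustly at any
frequency.

## Interpretation of the slope (incline/decline) scenarios

Holding a slope needs a standing torque, so $vn$ must acquire a DC
component (±0.116 command units for ±10° here — the value is fixed by
$m g \sin\alpha\, r / k_\tau$, not by the controller). In this plant a
single motor both balances and drives, so climbing also requires a
standing body lean of ≈ 0.07 rad, and the PD's tilt term is therefore
mechanically pinned at a nonzero DC. The discriminating property is in
the *wheel* loop: without the cerebellum the PD can only produce its
share of the DC through a standing wheel-angle error of ≈ 2 rad, whereas
with the biCNN the learned DC absorbs it and the standing error shrinks
toward zero. The acceptance suite tests exactly that contrast, plus the
sign of the $vn$ DC.

## What a green test does and does not establish

The plant is a stand-in: a planar wheeled-inverted-pendulum with made-up
(but documented) masses, lengths and friction, integrated by RK4. No
motor electrical dynamics, no wheel slip, no sensor noise by default.
Real-robot numbers (RSE improvements in rad, peak transients,
firing-rate percentage changes) are therefore *not* reproduced
quantitatively; the suite asserts ordered, qualitative properties:
learning reduces RSE; the PD alone fails where the bi-hemispheric
network survives; off-center loads hit the matching motion direction
harder; slope compensation requires a cerebellar DC; and the spontaneous
cf level is what lets a hemisphere learn from contradirectional error.

## Numerical choices and degenerate inputs

* Truncated-normal weight draws use rejection sampling; builds are
  bit-reproducible given the seed, and RNG state is restored afterwards.
* Nearest-neighbour ties are broken by lower neuron id (determinism).
* Divergence ratios are not enforced; convergence is the binding
  constraint (realized divergences come out within ~2% of the nominal
  table anyway).
* `cf == cf_spont` exactly triggers no weight update (the rule covers
  only strict inequalities).
* pf–Pk weights clip to [0, 2/1024] (twice the largest initial weight);
  Pk–Vn weights to [0, 2/n_Pk]. Rates clip to [0, 1], commands to
  [−1, 1].
* A fall (|θ| > π/6) latches: the plant freezes, the log keeps its
  shape, and per-cycle RSE becomes `Inf` from that cycle on.
* The C++ engine and the pure-R reference loop perform the same
  arithmetic in the same order; the suite checks them against each other
  and against a naive per-synapse oracle on small networks.

## Design choices where the design was genuinely open

* **Per-hemisphere counts.** The hemisphere total (4694, including 281
  glomeruli) is reconciled with the bi-hemispheric table (562 mf, 8192
  gr, …) by reading the table as two-hemisphere totals.
* **Normalization $d$.** Defined per connection class (1/class
  in-degree), following the worked example rather than the
  stricter-sounding per-nature phrasing, which the example itself
  contradicts.
* **Exclusion radii.** gr 2, mf 4, Go 8 um inside the cube; ba 3, Pk 8 um
  in the 20 um molecular slab. Larger molecular radii are geometrically
  impossible: 274 ba spheres of radius 6 um cannot pack pairwise-disjoint
  into 100×100×20 um.
* **Neuron transfer function.** The rate unit with first-order
  relaxation is the single largest modelling gap (the source defers
  neuron details to companion work); `relax` is exposed and `relax = 1`
  recovers the memoryless unit.
* **cf error source.** Wheel-angle error plus a velocity term; the
  error-to-rate gain is deliberately small (see table above) — this is a
  deviation from mapping the full amplitude into [0, 1], forced by the
  closed-loop stability analysis summarized above.
* **Uni-hemispheric ablation.** One hemisphere driven by a full-wave
  (absolute) error cf, the natural single-comparator reading.
* **Pk–Vn weights** are per-Pk (the subscript reading), initialized
  uniformly at 1/n_Pk so the untrained combination is mean(right) −
  mean(left) ≈ 0.

## Known limitations

* Learning has a degenerate attractor in which the cerebellar output
  cancels the PD and the robot parks off-reference with near-zero motor
  command. The default operating point avoids it in the tested
  scenarios, but fore-offset loads still end there after their (correct,
  direction-specific) transient, and very long runs can drift toward it
  because the LTP flux slightly exceeds the LTD flux at zero error.
* The stability window of the whole loop (error gain, mossy modulation
  depth, PD stiffness) is narrow; the methods above document where its
  edges are and why.
* Without the spontaneous cf level the LTD-only rule monotonically
  depletes pf–Pk weights, so the no-spontaneous variant adapts to the
  symmetric load only transiently in this plant (it falls a few cycles
  later), a weaker result than the hardware demonstration it mirrors.
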