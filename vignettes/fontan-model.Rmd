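---
title: "Modelling the Fontan circulation with fontansim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the Fontan circulation with fontansim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fontansim` simulates pulsatile blood flow in a surgically created
single-ventricle (Fontan) circulation as a closed loop of three model
classes: a 0-D univentricular heart, 1-D pulse-wave domains for the aorta
and the total cavopulmonary connection (TCPC), and 0-D lumped compartments
for the upper body, lower body and lungs. This vignette documents the
model equations and assumptions, the parameters that matter, the numerical
choices, and the design decisions taken where the problem was genuinely
open.

## The heart

Each chamber is a time-varying elastance: `P = E(t)(V - V0)(1 - Ks Q)`,
where `Q` is the chamber's outflow and `Ks` (s/ml) a source-resistance
coefficient that lowers developed pressure during ejection. The
activation is a product of a sigmoidal contraction and relaxation factor,

```
E(t) = k * g1/(1+g1) * 1/(1+g2) + E_min,
g1 = ((t - t_onset)/tau1)^m1,   g2 = ((t - t_onset)/tau2)^m2,
```

with `k` chosen so the maximum over one period equals `E_max` exactly; the
package locates that maximum on a dense grid refined by golden-section
search. Time is taken modulo the period relative to `t_onset`, so the
atrial activation (onset at 0.7 of the cycle) wraps across the cycle
boundary.

Valves are dynamic Bernoulli orifices. The flow obeys
`dQ/dt = (ΔP - B|Q|Q)/L` with `B = rho/(2 A_eff^2)`,
`L = rho l_eff/A_eff`, `A_eff = A_ann * xi`; the opening state `xi`
grows at rate `(1-xi) K_vo ΔP` under a favourable gradient and decays at
`xi K_vc ΔP` under an adverse one. Because `B` and `L` diverge as
`xi -> 0`, the effective area is floored at `1e-6 * A_ann`; a valve at
that floor under an adverse gradient carries exactly zero flow while the
state equation retains its reopening dynamics. The floor is our
regularisation choice — any floor small enough leaves the haemodynamics
unchanged, because the Bernoulli drag already throttles the flow to
near zero well before the floor is reached.

## 1-D vessels

Nine tapered, compliant vessel domains (ascending and descending aorta,
brachiocephalic and left carotid arteries, venae cavae, right pulmonary
artery and a two-segment left pulmonary artery describing an external
compression) solve mass and momentum conservation

```
dA/dt + d(AU)/dx = 0
dU/dt + d(U^2/2 + P/rho)/dx = -22 pi mu U / (rho A)
```

closed by the tube law `P = P0 + (beta/A0)(sqrt(A) - sqrt(A0))`, whose
wave speed is `c^2 = beta sqrt(A)/(2 rho A0)`. The friction coefficient
`22 pi` corresponds to the classic axisymmetric velocity-profile constant
`2(zeta+2) pi` with `zeta = 9`. The wall stiffness `beta(x) = 2 rho c0^2
sqrt(A0(x))` is set from the (constant per vessel) measured pulse wave
velocity, so the reference-state wave speed equals the measurement
everywhere along the taper. Diameters taper linearly between the measured
end values.

The diastolic reference pressure `P0` is regional: aortic segments use the
measured aortic diastolic pressure (40 mmHg), the TCPC uses the pulmonary
capillary wedge derived value (6 mmHg). The per-vessel values are not
measured individually; this regional assignment is an interpretation and
is configurable.

### Discretisation

Cell-centred finite volume, `N = max(2, round(L/h))` cells with element
size `h = 5` mm by default (the vessels span 12–90 mm). Interior faces use
minmod-limited MUSCL reconstruction of pressure and velocity with Rusanov
fluxes, advanced by a two-stage strong-stability-preserving Runge–Kutta
step: formally second order in space and time on smooth solutions and
oscillation-free at fronts. Reconstructing *pressure* rather than area
makes a spatially uniform pressure an exact discrete steady state on any
taper. We originally used a non-dissipative two-step Lax–Wendroff variant;
it reproduced the same converged cycles at the default mesh but developed
grid-scale odd–even modes on refined meshes during the violent start-up
transient, which motivated the upwind-biased scheme. Area updates are in
flux form, so each vessel's discrete volume changes exactly by its
boundary-face fluxes.

The time step satisfies a CFL bound of 0.5 against `max(|U| + c)` with a
velocity headroom of 150 cm/s; for the built-in patient this gives
`dt ≈ 3.2e-4` s, about 2 700 steps per cardiac cycle.

### Boundaries and junctions

Every boundary face couples the outgoing characteristic invariant
`U ± 4c(A)` of the adjacent cell with the attached element's relation.
Junctions (2–4 ends) enforce mass conservation and continuity of total
pressure `P + rho U^2/2`, solved by a damped Newton iteration with
analytic Jacobian to residuals below 1e-10 (ml/s and mmHg scales). Whether
a junction should conserve total or static pressure is not observable
from the calibration data; total pressure is the conventional choice for
this model family and is what we adopt. If the total-pressure system
transiently has no subcritical solution — which can happen during the
start-up front — the solver falls back to static-pressure continuity,
whose mass imbalance is strictly monotone in the common pressure and
therefore always solvable; converged cycles never engage the fallback.

Terminal faces solve the characteristic jointly with the attached Ohmic
relation (peripheral inlet resistances, venous resistances, lung
resistances, or a three-element Windkessel's proximal resistance). This
implicit face solve matters: prescribing the 0-D flux explicitly is
unstable whenever the attachment resistance is small against the vessel's
characteristic impedance (the upper-body venous resistance is 0.0054
mmHg·s/ml), whereas the joint solve is unconditionally benign.

### 0-D/1-D coupling and conservation

Each global step advances, in order: junction faces, terminal faces, the
heart (RK4 with atrial inflow and aortic root pressure frozen), the body
compartments (RK4 with the already-solved interface fluxes frozen), and
the 1-D interiors. Every interface flux is used identically on both of
its sides — the heart's RK4 stage-weighted mean aortic valve flow is the
same number imposed as the ascending-aorta inflow flux — so total stored
blood volume is conserved to round-off, orders of magnitude below the
0.1%-per-cycle invariant the tests assert.

## Lumped periphery

The upper body receives the brachiocephalic and carotid outflows through
arterial resistances into a common arterial compliance node, drains
through a capillary resistance into a venous compliance node, and returns
to the superior vena cava through a venous resistance; the lower body is
the single-feed analogue via the descending aorta and inferior vena cava.
This patient lacks the left subclavian artery, so the upper body has two
feeding branches; the compartment accepts any number. The lungs are two
pure resistors from the distal pulmonary arteries into the atrium — no
pulmonary venous compartment, matching the model's wiring.

## Initial conditions and total blood volume

Simulations start from rest: zero velocity, aortic vessels at their
reference (diastolic) geometry, arterial compartment nodes at the initial
pressure (6 mmHg, the wedge-derived diastolic value). The total blood
volume parameter `V_blood = 556.69` ml fixes the initial volume
allocation: chambers start at the measured end-diastolic ventricular
volume and the atrial volume matching the initial pressure, and the
remaining volume is stored on the venous side — in the venous compliances
and, self-consistently, in the TCPC vessels, which are initialised at the
same venous pressure because the venous resistances are nearly zero.
(Pressurising the venous compliances without the directly-coupled TCPC
creates a start-up surge of over a litre per second through a
0.005 mmHg·s/ml resistance; co-pressurising removes the surge and, since
the closed loop conserves total volume exactly, leaves the converged
cycle unchanged.) Because the loop is closed, the converged operating
point depends on the *total* allocated volume but not on its initial
distribution.

This makes `V_blood` the single most influential calibration constant for
mean pressures: the converged venous pressure — and through it ventricular
preload and cardiac output — is whatever absorbs the allocated volume.
What the published value of `V_blood` includes (whether, for example, the
1-D luminal content was counted, or unstressed compartment volumes were
carried separately) is not derivable from the calibration tables; we count
chamber volumes, vessel luminal content and compliance-stored volume. Under
this accounting the converged cardiac output sits about 4% below the
published baseline, and the two most flow-sensitive indices (mean left
pulmonary flow; cardiac output under vasodilation) land just outside a 5%
band while all pressure-side and volume-side indices land well inside it.
A ~25 ml different reading of `V_blood`'s scope would close that gap; we
keep the face-value accounting rather than adjust it.

## Periodicity, probes, outputs

The loop runs whole cycles until the cycle means of every probe signal
change by less than 0.1% (relative) between consecutive cycles — reached
in about 16 cycles from rest, matching the expected transient length —
with a hard cap of 30 cycles. Probe sites mirror the examination: mid
ascending/descending aorta, arch, both cavae, both pulmonary branches,
chamber pressures/volumes, valve states and compartment nodes. The final
cycle is resampled to 1 kHz. The superior vena cava's axis points away
from the heart in the vessel table; its reported flow is re-signed to the
physiological direction at the probe layer.

Cardiovascular indices follow the standard definitions: SV as the cycle
integral of aortic valve flow, HR = 60/T, CO = SV·HR/1000,
SVR = (mean arterial − mean atrial)/CO and
PVR = (mean pulmonary arterial − mean atrial)/CO. "Mean arterial" is the
ascending-aortic cycle mean and "mean pulmonary arterial" the unweighted
average of the two branch means; both conventions reproduce the published
index arithmetic and are kept explicit in `cardiac_indices()`.

## Interventions

Pulmonary vasodilation scales both lung resistances by `1 - fraction`
(default 0.25) and nothing else. The atrial fenestration splits the
inferior vena cava at its axial midpoint and adds an Ohmic shunt
(0.5 mmHg·s/ml; 3 cm × 4 mm tube) from that node into the atrium, entering
the junction's mass balance. The tube's inertance `rho l/A` can be added
via `inertance = TRUE`; the default is the pure resistor, which is the
configuration the published scenario describes.

## Error metrics

Relative point-to-point errors over one cycle use point-wise
normalisation for vascular pressures and volume, and cycle-maximum
normalisation for flows and ventricular pressure; mean-value errors are
signed with the same denominators. Because invasive pressures and imaging
flows are acquired asynchronously, the metric aligns the two signals at
the waveform foot by default (a fixed-offset and a no-alignment mode are
available). The measured waveform traces themselves exist only as
published figures, so the package validates the metric implementations
against closed-form cases rather than attempting to reproduce the
published error percentages.

## Calibration helpers

The stepwise calibration used four open-loop submodels, all available
here: the heart against a single systemic Windkessel with prescribed
pulmonary inflow; the 1-D aorta with Windkessel terminals and prescribed
root flow; the 1-D TCPC with prescribed caval flows draining through the
lung resistances to a fixed atrial pressure; and the coupled open loop.
Their default Windkessel parameters are derived from the patient's own
periphery (proximal resistance = the vessel's characteristic impedance,
distal = the configured bed resistance minus it, compliance split by path
conductance); the per-submodel calibrated values live in supplementary
material we deliberately do not reproduce, so these defaults are
conveniences for exploration, not calibrated constants. `ohmic_resistance()`
provides the estimation primitive for resistive elements, and
`provenance_report()` the bookkeeping of which of the 70 parameters were
data-derived (45) versus manually adjusted (25).

## Known limitations

* No baroreflex or autoregulation: resistances are constants, so
  intervention responses are purely mechanical.
* Oxygen transport is out of scope; the desaturation cost of a
  fenestration is not modelled.
* Calibrated against a single anaesthetised patient; the fixture is not a
  population prior.
* The operating point inherits the ambiguity of the total-blood-volume
  accounting discussed above.
* Vessel collapse (negative transmural pressure buckling), viscoelastic
  walls and turbulence are not modelled.
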