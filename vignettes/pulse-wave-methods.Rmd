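---
title: "Modelling staged kidney removal with a 1-D arterial pulse-wave simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling staged kidney removal with a 1-D arterial pulse-wave simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pulsetree` simulates pressure and flow wave propagation through a branching
network of compliant arteries and measures arterial stiffness from the
simulated waveforms the way a vascular laboratory would: as foot-to-foot
pulse wave velocity (PWV) between standard measurement sites. Its study
layer reproduces a staged-kidney-removal experiment — the renal arteries
are high-flow, low-resistance outlets, and removing them from an otherwise
unchanged circulation raises blood pressure and, through the
pressure-dependence of the arterial wall, raises measured PWV.

This vignette documents the model, the numerical choices, the calibration
of the packaged reference tree, and the limits of what the package's tests
demonstrate.

## The haemodynamic model

### 1-D flow equations

Each artery is a tapered axisymmetric tube. Averaging the incompressible
Navier–Stokes equations over the cross-section gives, for area $A(x,t)$ and
volumetric flow $Q(x,t)$,

$$\frac{\partial A}{\partial t} + \frac{\partial Q}{\partial x} = 0,
\qquad
\frac{\partial Q}{\partial t} +
\frac{\partial}{\partial x}\!\left(\frac{Q^2}{A}\right) +
\frac{A}{\rho}\frac{\partial P}{\partial x}
= -k_f \frac{\mu}{\rho} \frac{Q}{A},$$

with blood density $\rho$ (default 1050 kg/m³), viscosity $\mu$ (0.004
Pa·s) and a friction coefficient $k_f = 2\pi(\zeta + 2)$ derived from an
assumed power-law velocity profile; the default $\zeta = 9$ is a near-plug
profile, giving roughly 2.8 times Poiseuille friction.

### Tube law

Pressure closes the system through a wall model $P(A)$ defined per segment
by its distensibility $D = (1/A)\,dA/dP$ at the reference pressure
$P_\mathrm{ref}$ = 100 mmHg. Two laws are available:

* **linear-elastic** — constant area compliance
  $C_A = A_\mathrm{ref} D_\mathrm{ref}$;
* **pressure-dependent** (default) — an arctangent-shaped compliance
  $$C_A(P) = \frac{C_\mathrm{peak}}{1 + \left((P - P_\mathrm{peak})/P_\mathrm{width}\right)^2},$$
  constrained so that $C_A(P_\mathrm{ref}) = A_\mathrm{ref} D_\mathrm{ref}$,
  with an optional cap pressure above which the wall enters a linear
  high-pressure regime of constant compliance (the collagen-dominated
  part of the distension curve). The cap is essential in practice: without
  it, sharply nonlinear muscular segments develop runaway systolic
  stiffness, which shows up as non-physical radial pressure amplification.

Local wave speed follows from $c^2 = A/(\rho C_A)$; at the reference
pressure this reduces to the Bramwell–Hill relation
$c = 1/\sqrt{\rho D}$, which `bramwell_hill_pwv()` and
`distensibility_from_pwv()` expose directly. Distensibility values are
handled throughout in the conventional printed unit, kPa⁻¹·10⁻³.

The conventional density 1050 kg/m³ is the package default. A published
10-artery distensibility/PWV reference table that the package carries for
cross-checks is internally most consistent with a density near 1052 kg/m³
(`fit_blood_density()` recovers this by brute-force scan); at exactly 1050
one of its 20 cells misses the printed rounding by 0.002 m/s. The
table-reproduction test therefore checks Bramwell–Hill consistency at the
scan-fitted density, while all single-value conversions use 1050.

### Boundary conditions

* **Terminals.** Every terminal segment drains through a three-element
  Windkessel (characteristic resistance $R_1$, peripheral resistance
  $R_2$, compliance $C$, venous pressure $P_\mathrm{out}$), integrated
  implicitly with the solver step.
* **Junctions.** Conservation of mass and continuity of total pressure
  $P + \tfrac{1}{2}\rho (Q/A)^2$ couple a parent to 1–3 children.
* **Root.** Either a prescribed periodic inflow or the time-varying
  elastance ventricle: $P_\mathrm{lv} = E(t)(V - V_0)$, with $E(t)$
  running between $E_\mathrm{min}$ and $E_\mathrm{max}$ along a
  normalised double-Hill activation curve peaking at 38% of the cycle. An
  ideal valve with a small series resistance opens when ventricular
  pressure exceeds root pressure and closes on flow reversal; the chamber
  refills from a constant preload through a filling resistance. No atrium
  and no regurgitation are modelled — sufficient for a periodic aortic
  ejection pattern.

Default heart parameters ($E_\mathrm{max}$ 1.75 mmHg/mL, $E_\mathrm{min}$
0.07 mmHg/mL, $V_0$ 10 mL, preload 9.5 mmHg, period 0.8 s) are a
calibration to a resting adult operating point: heart rate 75 bpm, cardiac
output ≈ 5 L/min, aortic pressure ≈ 114/73 mmHg and mean pressure ≈ 91
mmHg on the reference tree. A deliberately moderate $E_\mathrm{max}$ makes
stroke volume appropriately sensitive to afterload, which controls how
much pressure rises when outflow beds are removed.

## Numerics

The interior scheme is the two-step (Richtmyer) Lax–Wendroff method,
second-order in space and time, on a per-segment uniform grid (target
spacing 0.5 cm, at least 3 nodes per segment). The time step is the
smaller of the user step (default 10⁻⁴ s) and 0.4 of the CFL limit
evaluated over a 40–220 mmHg pressure sweep of every node's tube law.
Solver output is stored at the solver rate and resampled (periodic cubic
spline) to the analysis rate of 900 Hz; it is never *solved* at 900 Hz.

Boundary nodes are conservative half-cells: the boundary flow is the
unknown of the boundary condition solve, and the boundary area follows
from the half-cell mass balance. This makes the scheme globally
mass-conservative (cycle volume closes to better than 0.1% at periodic
steady state; the per-cycle acceptance check allows 1%). Junction systems
are solved by a damped Newton iteration with analytic Jacobians in two
stages: a static-pressure stage, which is monotone and unconditionally
solvable, seeds the total-pressure refinement; in rare stiff,
advection-dominated states where the refinement's Jacobian becomes
ill-conditioned the static solution is kept (the dynamic-pressure term is
then a fraction of a mmHg). Mass closure at junctions is enforced to
10⁻¹⁰ of the local flow scale.

Runs start from a uniform pressure (default 90 mmHg) at zero flow and
repeat cardiac cycles until the largest cycle-to-cycle change of any
extracted site pressure falls below a tolerance (0.5 mmHg by default; the
study runners use 0.2 mmHg and up to 20 cycles). Non-convergence is
reported with a warning and flagged in study reports, never silently.

Degenerate inputs are handled explicitly: flat waveforms raise a no-foot
error, zero transit times are flagged as degenerate, removing a
non-terminal or root segment is refused, and areas are floored at 2% of
the reference area with an abort-and-diagnose path for genuine
instability.

## PWV measurement

The foot of each pressure wave is the time of the maximum second
derivative on the systolic upstroke, the standard foot-to-foot convention:

1. the periodic waveform (one cycle at 900 Hz) is smoothed with a
   zero-phase low-pass filter (4th-order Butterworth, 25 Hz cutoff,
   applied to a periodic tiling so filter transients never touch the
   cycle) — raw double-differencing at 900 Hz is noise-dominated, and the
   source convention does not state a smoothing, so the cutoff is a
   documented choice;
2. the second derivative is searched only between the end-diastolic
   minimum and the systolic peak, which keeps incisura curvature maxima
   out of the window;
3. the discrete maximum is refined by parabolic interpolation, though
   precision is still quoted at the 1/900 s sample.

Transit time is the difference of two foot times wrapped into one period,
and PWV divides the anatomical path distance by it. Path distances are
tree distances — summed segment lengths through the nearest common
ancestor — not clinical surface-tape distances; on the reference tree the
carotid–femoral, carotid–radial and radial–digital paths measure exactly
66, 70 and 19 cm. Sites sit at explicitly chosen positions within their
segments (the measurement position within a segment is otherwise
unspecified, so fixed positions are declared once in the topology).

The absolute foot time of a single waveform carries a small systematic
offset (a few samples) from the smoothing of the upstroke corner; it
cancels in transit-time differences, which is why the estimator recovers
constructed delays of 5–300 ms to within one sample and shows sub-sample
bias over 100 noisy replicates at 1 mmHg RMS.

Waveform metrics follow the reporting conventions of staged-removal
studies: SBP is the cycle maximum, end-DBP the cycle minimum (the wave
foot), PP their difference, and early-DBP — never formally defined in
that literature — is operationalised as the first post-systolic local
minimum (the incisura region) and validated only qualitatively (it must
lie between end-DBP and SBP). Some simulated central waveforms have no
detectable incisura, in which case early-DBP is reported as missing with
a message.

## The reference tree and its calibration

`make_reference_tree()` builds a 27-segment reduced systemic tree: aorta
from root to bifurcation, left common carotid, left
subclavian–brachial–radial/ulnar arm with a hand lump, symmetric
iliac–femoral legs, two renal arteries on the abdominal aorta, and lumped
visceral, head and contralateral beds. It is a calibrated fixture, not a
reproduction of the unpublished 143-segment research topology; dimensions
start from the classic systemic-tree tables and the arm/hand/leg branches
are scaled so the three measurement paths come out at 66/70/19 cm. The
renal arteries carry ids 36 (left) and 38 (right) and the right external
iliac id 44, following the conventional numbering of the kidney
configurations.

Terminal Windkessels are sized from the design operating point: total
peripheral resistance from a design outlet pressure of 81 mmHg (the
aortic mean sits higher by the conduit resistive losses) at 5 L/min,
split over the outlets by resting flow fractions; $R_1$ matches the
terminal characteristic impedance capped at half the outlet total; 0.9
mL/mmHg of peripheral compliance is distributed in proportion to flow.
The two kidneys together receive 17% of cardiac output — inside the
usually quoted 15–20% renal share — a value chosen during calibration of
the blood-pressure response to staged removal.

The wall-law classes (`wall_law_classes()`) encode the fixture's central
scientific calibration. Elastic central arteries get a moderately sharp
compliance curve (peak 45 mmHg, width 25 mmHg, cap 120 mmHg); arm
muscular arteries a very sharp curve peaking just below their diastolic
operating point (55/10, cap 88 mmHg); the carotid a broad curve (30/50)
so the shared proximal measurement site contributes little pressure
sensitivity; the hand a sharp curve with a higher cap (60/15/125). These
make the *foot-region* wave speed strongly pressure-sensitive in the arm
and moderately so in the aorta, which is what lets a purely mechanical
removal of the renal outflows raise measured carotid–radial PWV by more
(relative) than carotid–femoral PWV, with bounded systolic stiffening.
Several alternatives without the high-pressure cap, or with uniformly
sharp or uniformly broad laws, were rejected during calibration because
they produced runaway radial amplification or non-monotone systolic
pressure orderings across configurations.

### Kidney configurations

Surgery operations transform the control tree (`2KDN`): `1KDN` removes
terminal segment 36, `0KDN` removes 36 and 38, and `TX` removes both and
grafts a branch with the donor renal artery's geometry, wall and
Windkessel onto the terminal right external iliac (segment 44), which
becomes a junction feeding the graft and a short distal stub that
inherits the iliac's original Windkessel. The graft is placed on the
*right* iliac — the measurement leg stays pristine — following the
configuration diagram; the accompanying text mentions the left side once,
a discrepancy resolved in favour of the diagram and of keeping the
femoral site unperturbed. Surgery never alters untouched segments, and
removal order does not matter.

### Study conditions and problem sizes

All study runs share identical heart and Windkessel parameters across
configurations ("the kidney is removed, nothing else changes"). The
packaged studies and the acceptance script use the 27-segment tree at
0.5 cm resolution, ≈ 2×10⁻⁵ s time steps (CFL-limited by the stiff
muscular segments at systole), 0.2 mmHg cycle tolerance and a 20-cycle
budget; one configuration converges in 15–17 cycles, about 10 s of CPU.
Unit tests use single- and two-segment fixtures, and coarse grids for
full-tree trend checks.

## What the synthetic generators do and do not show

`make_delayed_pair()` produces analytic periodic waveforms (a logistic
upstroke with exponential decay and a dicrotic bump, or a Gaussian bump)
whose distal copy is delayed by a continuous, exactly known shift, plus
optional seeded white noise. It validates the transit-time estimator
against ground truth — delay recovery, equivariance, noise bias. It does
not emulate shape *distortion* during propagation (amplification,
steepening, reflections), so estimator accuracy on real or simulated
propagated waves is established separately by the single-tube solver
fixture, where the measured foot-to-foot speed agrees with the tube law's
Bramwell–Hill speed within 5% across the stiffness range of interest.

A passing suite therefore shows: the conversion algebra is exact; the
estimator is unbiased on constructed delays; the solver propagates waves
at the right speed, conserves mass and volume, and reproduces the
qualitative and most quantitative patterns of the staged-removal study on
*this reduced, recalibrated fixture*. It does not show that the fixture
matches any individual patient, nor that absolute simulated PWV values
match the full 143-segment topology (see limitations).

## Known limitations

* **Absolute PWV levels.** Foot-to-foot PWVs on the reduced tree (cf ≈
  6.7, cr ≈ 8.0, rd ≈ 6.4 m/s in the control) differ from the full-scale
  study's absolute values; the studied quantities are the *relative*
  changes between configurations, which is where calibration effort went.
* **The non-uniform stiffening comparison.** With the diameter-stratified
  reduction (−40% above 14 mm tapering to −5% below 3 mm), the
  carotid–femoral increase (+21%) reproduces the reported +20%, but the
  carotid–radial increase comes out near +8%, far below the reported
  +40%. Mechanistically the arm path receives only −10/−15% distensibility
  cuts (a +5–8% Bramwell–Hill effect) and the stiffened tree's faster
  diastolic decay leaves arm foot pressures nearly unchanged, so no
  foot-to-foot kinematic route to +40% exists in this model class; the
  original study itself noted that its non-uniform PWV-ratio pattern
  contradicted in-vivo expectations. The corresponding acceptance checks
  are expected to fail and are retained unweakened.
* **Radial/digital systolic amplification** in the reduced arm is larger
  than physiological; it is bounded by the high-pressure cap but still
  makes absolute peripheral SBP levels run high relative to the reported
  tables. Orderings across configurations are unaffected.
* **No wall viscoelasticity.** The wall is purely elastic;
  high-frequency damping that a viscoelastic modulus would provide is
  absent (friction and the smoothing in the foot detector compensate for
  measurement purposes).
* **No coronary or cerebral sub-networks, no venous return, no
  autoregulation or neurohormonal control** — the model isolates the
  purely biomechanical consequence of removing renal outflow beds.
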