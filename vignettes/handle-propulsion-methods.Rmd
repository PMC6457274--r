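---
title: "Methods: muscle-driven optimization of handle-based wheelchair propulsion"
author: "hbpsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: muscle-driven optimization of handle-based wheelchair propulsion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbpsim)
```

## The problem

Push-rim wheelchair propulsion is discontinuous and drives the shoulder and
wrist through extreme joint ranges, which is associated with rotator-cuff and
carpal overuse injury. A handle-based alternative replaces the rim with a
crank-slider mechanism: a crank rotating at constant (isokinetic) cadence
about a fixed centre carries a slider whose travel varies the effective crank
length $C_L$, so the handle can follow an arbitrary closed, star-shaped path
rather than a circle. `hbpsim` asks the design question directly: *which
handle-path shape, and which muscle excitation pattern, maximize the net
mechanical power the upper limb can deliver to the crank?*

## Model

### Handle-path family

The candidate paths form a four-parameter family in the crank frame,

$$P_x(\theta) = A\cos\theta, \qquad
  P_y(\theta) = B\sin\theta\,\sin^{n}(\theta/2),$$

rotated clockwise by a tilt angle $\beta$ about the crank centre. $A$ and
$B$ (both in $[0.030, 0.155]$ m) are bounded by the slider travel; the
exponent $n \in [0,1]$ morphs the curve from an ellipse ($n=0$) toward an
egg-like profile. The family produces smooth closed curves that are, over
the admissible box, star-shaped about the crank centre, which is what the
mechanism requires: the path must be expressible as a single-valued function
$C_L(\varphi)$ of the crank angle. Conversion to that profile samples the
curve densely, converts to polar form in the crank's rotation sense, and
resamples by linear interpolation onto a uniform periodic grid (720 points
by default). Shapes that fail the star-shape test are rejected with an
error by the conversion and handled by penalty during optimization; path
convexity is an empirical property of the family, reported but never
enforced.

Shape compactness is summarized by the isoperimetric (Miller) circularity
ratio $4\pi\,\mathrm{Area}/\mathrm{Perimeter}^2$, computed by the shoelace
formula and the chord-length sum; it equals 1 exactly for a circle, which
pins down the normalization among the several "circularity" conventions in
use. It is invariant to tilt and overall scale, and converges at the
trapezoid rate $O(1/N^2)$ in the number of samples.

### Mechanism and power

The crank turns clockwise at a constant $\omega$ (default 50 rpm, an
over-ground daily-living cadence) about a centre placed anthropometrically:
the x coordinate midway between the seat reference point and the knee, the
y coordinate a forearm height above the seat reference point. The crank
angle is measured in the rotation sense from the crank frame's +x axis — a
convention the geometry itself does not fix, so it is fixed once here.
Positive crank torque drives the propulsion sense; instantaneous power is
$\tau_{crank}\,\omega$ and net propulsion power is its trapezoidal
time-average over exactly one cycle.

### Musculotendon actuators

Fifteen Hill-type actuators span the shoulder, elbow and wrist: three
deltoid compartments, pectoralis major, biceps long/short, triceps
long/lateral, brachialis, two wrist flexors, and the four rotator-cuff
muscles. Excitation-to-activation is first order with the
activation-dependent time constant ($\tau_{act} = 10$ ms rising,
$\tau_{deact} = 40$ ms falling, modulated by $0.5 + 1.5a$); the active
force–length curve is Gaussian with width 0.45, the passive curve
exponential reaching the isometric force at 60 % strain, and the
force–velocity curve is the Hill hyperbola (curvature $A_f = 0.25$) on the
concentric side, vanishing at $V_{max} = 10\,L_{opt}/\mathrm{s}$. On the
eccentric side the standard constants fix only the plateau (1.4) and the
isometric point, so the package uses a smooth exponential saturation whose
initial slope $1 + 1/A_f$ matches the concentric branch, making the curve
$C^1$ at zero velocity — a property gradient-free search still benefits
from, since it keeps the objective smooth across shortening/lengthening
transitions.

The tendon is rigid: $L_{fiber}\cos\alpha = L_{MT} - L_{slack}$ with
constant pennation $\alpha$. This removes the fiber-length state (halving
the state dimension to the 15 activations) and is accurate for short-tendon
upper-limb muscles at this cadence; an elastic tendon is an acknowledged
extension, not implemented. Muscle paths reduce to constant moment arms per
muscle–joint pair, $L_{MT}(q) = L_{MT,0} - \sum_j r_{ij}\,(q_j -
q_{ref,j})$, replacing 3-D wrapping geometry. The reference posture
$q_{ref}$ — where every fiber sits at its optimal length — is the
inverse-kinematics pose of the crank centre: shape-independent, and central
to the workspace, so fibers excursion symmetrically around optimum
(simulated normalized fiber lengths stay within roughly 0.83–1.17 for the
default geometry). The rotator-cuff muscles are retained with small
in-plane shoulder moment arms so the control vector keeps its full size;
their three-dimensional stabilizing action is out of scope.

The shipped parameter table is a **synthetic fixture** with
literature-plausible magnitudes for a 50th-percentile adult male; it is not
a reproduction of any published subject-specific data set, and every value
is replaceable through `muscle_set()`.

### Planar closed chain

The mechanism lies in the parasagittal plane through the shoulder, which
motivates a planar reduction: a two-link arm (upper arm 0.33 m / 2.0 kg,
forearm+hand 0.46 m / 1.7 kg, standard COM and radius-of-gyration
fractions) with the hand welded to the handle and the wrist fixed at a
neutral angle. With the crank speed imposed and the chain closed, the
skeleton's motion is fully prescribed: joint angles follow by two-link
inverse kinematics (the elbow branch is chosen once per simulation — the
branch whose flexion lies inside $[0^\circ, 130^\circ]$ — and never
switched mid-cycle), joint velocities through the hand Jacobian, and joint
accelerations by periodic central differences. "Forward" dynamics therefore
applies to the muscle states only; the rigid-body side enters through
inverse dynamics (standard planar two-link equations) and the crank torque
follows by virtual work:

$$\tau_{crank}(\theta) = \sum_j \left(\tau_{app,j} - \tau_{ID,j}\right)
  \frac{\partial q_j}{\partial \theta},$$

where $\tau_{app}$ collects moment-arm-weighted muscle forces plus the
passive joint-limit torques (elastic $K = 20$ N m/rad plus damping
$c = 1$ N m s/rad, engaged only beyond a limit), and
$\partial q_j/\partial\theta = \dot q_j / \omega$. This formulation makes
the energy bookkeeping exact in the continuous limit: over a periodic cycle
the inverse-dynamics work vanishes (no net change of kinetic or potential
energy), so crank work must equal musculotendon work plus passive-element
work — a balance the test suite verifies to within 1 % and that holds to
quadrature accuracy in practice.

### Optimization

The control vector stacks 10 excitation nodes per muscle (periodic cubic
splines at equal time fractions of the cycle, clipped to $[0,1]$) and the
four shape parameters: $15 \times 10 + 4 = 154$ variables. Periodicity of
the excitations is structural — the first node serves as both cycle
endpoints — and the terminal condition (crank angle $360^\circ$ at the
final time) holds identically because the crank angle is prescribed as
$\omega t$. Each objective evaluation simulates three settling cycles plus
one evaluation cycle with activations started at 0.050, and returns the
negative net power plus quadratic penalties: joint-range excursion
(weight 100 per rad$^2$ s), crank-length-bound excursion ($10^3$ per
m$^2$), and an indicator ($10^4$) for geometrically infeasible shapes
(non-star-shaped or unreachable), which are rejected without simulation.
The weights are tunable configuration; they need only dominate the watt
scale of the power term.

The search backend is a (1+1) evolution strategy with per-dimension steps
proportional to the bound widths and 1/5-success-rule step adaptation.
A gradient-free method was chosen deliberately: the objective is smooth
only up to adaptive-integrator and interpolation noise, and the accepted-
iterate history it produces is monotone and exactly reproducible for a
given seed. Any bound-constrained backend honouring the same history
semantics could be substituted.

## Numerical choices

* Path sampling: 720 points per revolution (tests also use 360); the
  crank-length profile is linearly interpolated, as is conventional for
  prescribed slider motions, with central-difference derivatives.
* Integrator: adaptive embedded Runge–Kutta 4(5) (`deSolve::ode`,
  `"ode45"`), relative tolerance $10^{-6}$, absolute $10^{-8}$.
* Output grid: 240 samples per cycle by default, a multiple of 4 so that
  propulsion-zone boundaries fall on grid points; per-zone work assigns
  each inter-sample trapezoid to the zone of its midpoint crank angle, so
  zone works sum *exactly* to the cycle total.
* Quadrature: all cycle averages and work integrals are trapezoidal on the
  output grid. Identities that are exact in the continuous model (zero net
  power without excitation, conservative passive work) therefore carry an
  $O(h^2)$ residual, about $2\times10^{-3}$ W at 240 samples per cycle on a
  ~30 W work scale; tests assert such signs up to $10^{-2}$ W.
* Degenerate inputs: unreachable handle points raise an error reporting the
  distance and the reach limit; non-star-shaped paths are rejected, never
  silently repaired; slider-travel violations name the offending crank
  angle. Inside the optimizer all three become finite penalties, and a
  simulation failure returns a large finite objective with a flag rather
  than aborting the search.

## Propulsion zones and reports

The cycle is partitioned into four crank-angle quadrants starting at the
crank frame's +x axis (configurable offset): zones 1 and 4 form the pull
phase, zones 2 and 3 the push phase. Reported quantities per run: net
propulsion power; circularity and shape parameters; per-muscle, per-zone
net mechanical work $\int F_{MT}(-\dot L_{MT})\,dt$ (defined on
musculotendon length so it matches the crank energy balance under the rigid
tendon, with positive/negative components); joint range-of-motion extrema
with ergonomic-range flags; normalized fiber length and velocity with the
20 % activation mask; and peak muscle forces.

## Problem sizes used by the tests

The test suite exercises the full 15-muscle roster for single simulations
and reduced rosters for optimization loops: a four-muscle set (Delt1,
Delt3, BicLong, TriLong) with 5 nodes per muscle and 100 objective
evaluations for the end-to-end run, and a two-muscle shoulder pair with a
closed-form circle-favoring objective for the cheap whole-loop recovery
check. These sizes were chosen as the smallest that still exercise
agonist–antagonist coordination; the packaged defaults (15 muscles,
10 nodes, 200+ evaluations) are the intended scientific configuration.

## What the defaults do and do not show

The default anthropometry, muscle table and geometry emulate a
50th-percentile adult male propelling at 50 rpm, and the model reproduces
the qualitative signatures expected of handle-based propulsion: positive
net power of a few tens of watts under coordinated excitation, near-optimal
fiber operating ranges, and alternating flexor/extensor work across pull
and push zones. They do not reproduce any specific subject or any published
3-D musculoskeletal parameter set: moment arms are constant, the shoulder
girdle is reduced to a planar hinge, the trunk is absent, and drivetrain
inertia, rolling and air resistance are deliberately unmodelled. Passing
tests certify the mechanics, energetics and search machinery — not the
transferability of any particular optimized shape to a human subject,
which requires experimental validation.

## Known limitations

* Rigid tendon and constant moment arms; no wrapping, via points or
  elastic tendon compliance.
* Planar: shoulder elevation-plane/rotation and wrist deviation are fixed;
  out-of-plane penalties are vacuous here and omitted.
* Isokinetic only: no acceleration/deceleration phases, no drivetrain
  dynamics.
* The evolution strategy is a local stochastic search; different seeds can
  settle in different excitation patterns of similar power, and no global
  optimality is claimed.
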