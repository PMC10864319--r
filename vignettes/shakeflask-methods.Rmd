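---
title: "Models and methods behind shakeflask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind shakeflask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shakeflask)
```

shakeflask models the hydrodynamics of orbitally shaken Erlenmeyer-type
culture flasks: where the liquid sits on the wall, how that liquid
distribution responds to shaking frequency, filling volume and viscosity,
and how much mechanical power the shaking dissipates per litre of culture.
The package deliberately contains no flow solver. It implements the pieces
around one: the parametric wall geometry, the inviscid mechanistic model of
the rotating liquid, the probe-based post-processing that turns any
volume-of-fluid (VOF) field into contact lines and film diagnostics, the
dissipation integral that turns resolved flow fields into volumetric power
input, the dimensionless power correlation, and a synthetic field generator
that stands in for solver output with analytic ground truth.

## Flask wall geometry

The inner wall of an unbaffled 250 mL flask is modelled as a partial torus
(the curved lower bowl) capped by a cone (the tapering upper part). The
torus is parameterised by the arc angle $\varphi$ measured from the flat
bottom rim: a wall point sits at radius
$r(\varphi) = R_c + r_t \sin\varphi$ and height
$z(\varphi) = r_t (1 - \cos\varphi)$, where $r_t = 14.5$ mm is the tube
radius and $R_c = d_{max}/2 - r_t = 26.3$ mm the centre-circle radius. This
reproduces every measured dimension of the default flask: flat bottom of
52.6 mm diameter, maximal diameter 81.6 mm at 14.5 mm height, top rim
30.7 mm at 99 mm.

Two transition variants are supported.

* **sharp** — a quarter torus ($\varphi$ ends at exactly 90°) with the cone
  attached at the maximal diameter. The cone half-angle follows from the
  two rim circles, $\arctan\!\big((40.8-15.35)/(99-14.5)\big) = 16.76$°.
  The wall slope is discontinuous at the junction, and that kink imprints
  itself on the predicted contact line.
* **smooth** — the torus is extended past 90° until its tangent is
  collinear with the chord to the fixed top rim. The arc angle is found by
  bracketed root finding on the tangency residual (tolerance $10^{-4}$
  degrees) and evaluates to 107.2° for the default dimensions. The wall is
  then continuously differentiable, which is the property that matters:
  real flask glassware has no kink.

The two printed quantities 107.2° and 16.76° are mutually inconsistent by
about 0.4° if both are held fixed: a cone that remains at exactly 16.76°
cannot be tangent to the extended torus *and* hit the measured top rim. We
anchor the cone at the top rim and let the half-angle float to the
tangency solution (17.18°), because smoothness of the wall is the crucial
property and the top rim is a measured dimension. The quarter-torus
variant keeps the printed 16.76° exactly.

The flat bottom is an idealisation; the slight upward doming of real
flask bottoms (a production artefact) is not modelled. Flask volumes are
computed by adaptive quadrature of $\pi r(z)^2$ split at the junction
(absolute tolerance $10^{-4}$ mL). Geometry lives in millimetres
internally; everything physical is SI, converted at module boundaries.

## Shaking kinematics

Orbital shaking of a stationary flask is modelled as a rotating body force
per unit mass, $F_x = \omega^2 (d_0/2)\cos\omega t$,
$F_y = \omega^2 (d_0/2)\sin\omega t$, with $\omega = 2\pi n$ the angular
velocity, $n$ the shaking frequency and $d_0$ the shaking diameter.
During the first 0.5 s (configurable) the frequency ramps linearly from
standstill. The force phase during the ramp is taken as the time integral
of the ramped angular velocity — physically consistent rather than
stepped, a choice the force-schedule export makes visible
(`write_force_schedule()`).

## The inviscid mechanistic liquid distribution

Reading the orbital motion as a superposition of a translation and an
opposing rotation, the free surface of an inviscid liquid is a symmetric
paraboloid about the shaker rotation axis:
$h(s) = z_0 + \frac{\omega^2}{2g} s^2$, with $s$ the horizontal distance
from that axis. The axis sits at $d_0/2$ from the flask axis; we place it
at azimuth 0° so that the centrifugal direction — and therefore the apex
of the liquid — is at 180°, the plotting convention used throughout.
Gravity is 9.81 m/s². Viscosity, surface tension and contact angle play no
role in this model; the latter two are carried as metadata only.

`solve_fill()` adjusts the apex height $z_0$ by bracketed root finding
until the volume enclosed between wall, bottom and paraboloid matches the
filling volume to 0.1 %. The enclosed volume is a vectorised midpoint
quadrature in plan-view polar coordinates (default 800 radial × 720
azimuthal nodes, verified against Monte-Carlo rejection sampling to
within 0.5 %); columns of liquid trapped under the torus overhang are
handled exactly through a per-radius wall height interval. The contact
line is then the set of heights where the paraboloid crosses the wall,
refined per azimuth by root finding on a 0.05 mm scan; several crossings
per azimuth occur at strong shaking when part of the wall or bottom runs
dry. For the reference conditions (40 mL, 250 rpm, $d_0$ = 2.5 cm, smooth
wall) the model puts the maximal contact height at 42 mm, exactly on the
centrifugal direction, and the line is symmetric about it — the model has
no mechanism for the viscous lag seen in experiments.

## Contact-line extraction from VOF fields

Any field exposing a point-sampling contract (`alpha_field()`), whether
synthetic or read from a legacy VTK file by nearest-cell lookup, can be
probed the same way a solver's post-processing would: vertical scan lines
at every degree of azimuth, sampled every 0.5 mm, offset from the wall
along the inward normal. With the default grids that is roughly 72,000
positions per offset. A sample is water if $\alpha \ge 0.5$ — the
boundary value counts as water, a measure-zero tie-break — and every
air/water change walking down from the top is recorded with its
direction; the first air-to-water crossing is the contact height,
reported at the midpoint of the bracketing samples. Classification only
uses the 0.5 crossing, so any monotone remapping of $\alpha$ that
preserves it leaves results unchanged. Samples outside a field's support
read as air and are counted, not dropped. The offset ladder starts 50 µm
inside the wall (probes exactly on the wall may fall outside a solver's
mesh) and climbs in 200 µm steps to 1050 µm.

Two derived diagnostics:

* **Apex shift** (`apex_shift()`): signed azimuth of the maximal contact
  height relative to the centrifugal direction. Grid quantisation
  flattens the apex into ties, which are resolved by circular mean.
  A flat line has no apex and errors.
* **Film bracket** (`estimate_film_thickness()`): at elevated viscosity a
  wall film of order 50–800 µm covers the whole circumference, so shallow
  offsets report the (nearly constant) film top while offsets beyond the
  film fall through to the bulk line. Within an azimuth window far from
  the bulk's leading edge (default 300°–60°), the largest film-like
  offset and the smallest bulk-like offset bracket the thickness at the
  ladder granularity. A film is recognised by azimuthal flatness
  (range ≤ 3 mm in the window) and agreement with the shallowest offset
  (±1.5 mm). This has one honest ambiguity: a nearly flat free surface
  (vanishing shaking) is indistinguishable from a film thicker than every
  offset, since both give flat lines at all offsets. The tail region of
  the bulk is reported as-is, all crossings included; segmenting leading
  edge from tail is inherently arbitrary and is left to the analyst.

## Volumetric power input

From resolved fields, the power per liquid mass is integrated as
$\varepsilon = \frac{1}{V_L}\int_{V_L} \big(\tfrac{\eta}{\rho}\,|S|
+ \beta^* k \omega\big)\, dV_L$, the mean-flow plus turbulent
decomposition, with the VOF cell weighting $V_{L,i} = V_i \alpha_i$, and
$P/V_L = \varepsilon \rho$. Here $|S|$ is the scalar strain measure
$2(u_x^2 + v_y^2 + w_z^2) + (u_y+v_x)^2 + (v_z+w_y)^2 + (u_z+w_x)^2$.
Note its units: this quantity is quadratic in the gradients
(s$^{-2}$), so $\tfrac{\eta}{\rho}|S|$ already has W/kg; the same symbol
is used elsewhere in the turbulence literature for the s$^{-1}$ measure,
and the dissipation usage is the one implemented. $\beta^* = 0.09$ is the
standard closure coefficient of the k–ω family and is configurable.
Velocity gradients are *supplied*, never computed here: differentiating
fields on unstructured meshes is solver business, and the synthetic
module provides analytic gradients instead.

Without fields, the modified Newton number correlation gives the power
from operating conditions alone:
$Ne' = 70\,Re^{-1} + 25\,Re^{-0.6} + 1.5\,Re^{-0.2}$, with
$Re = \rho n d^2/\eta$ and $Ne' = P/(\rho n^3 d^4 V_L^{1/3})$, where $d$
is the maximum inner flask diameter (81.6 mm for the default flask) —
the standard convention of the source correlation, which omits the
shaking diameter for simplicity and excludes out-of-phase operation. The
density of elevated-viscosity model fluids is rarely stated with their
viscosity; the default is 1000 kg/m³, configurable. Over the classical
comparison grid (180–380 rpm, 25/40 mL, 1/16 mPa·s) the correlation
spans roughly 0.1 to 7 kW/m³.

## The synthetic field generator

The generator emulates what a VOF solver run would hand to the two
post-processing stages, with exact ground truth attached:

* the bulk is the solved mechanistic distribution, optionally rotated by
  a phase shift about the flask axis to mimic the 15–30° viscous lag of
  real bulks behind the centrifugal direction;
* an optional wall film of configurable thickness (order 50–800 µm) up to
  a configurable height, thinning linearly by 10 % (configurable) over
  its top tenth, since a draining film is slightly thinner near the
  maximal liquid height; films thinner than half a cell are generated but
  flagged sub-resolution, as a solver's under-resolved waterlike films
  would be;
* the interface transitions over one nominal cell (configurable 0–2),
  mimicking VOF interface compression.

Flow profiles for dissipation tests are piecewise analytic — quiescent,
rigid rotation (zero strain by construction, uniform $k$, $\omega$), and
uniform shear — with the closed-form bulk dissipation attached. Cells
above the bulk surface (film and gas) carry near-zero gradients: film
motion is gravity-led drainage with gradients far below the bulk's,
which is why a resolved film adds liquid volume but negligible power.

Mesh realisations use a structured cylindrical-shell grid clipped to the
flask rather than a castellated hexahedral mesh: cell volumes are then
analytic (shell volume times a sub-sampled wall-inside fraction), which
is what makes the mass and dissipation oracles exact enough to test
against. The generator is deterministic: identical specifications produce
bit-identical fields, and the recorded seed exists for downstream use.

What the generator does **not** emulate: transient sloshing, the
out-of-phase collapse of the liquid at high viscosity, turbulence
spectra, or solver numerics (numerical diffusion, castellation
artefacts). Tests passing on synthetic fields therefore validate the
*post-processing* — extraction, bracketing, integration — not any flow
physics beyond the inviscid model.

## Numerical choices and problem sizes

* Volume quadratures: 800 × 720 polar nodes for enclosed volume;
  Monte-Carlo cross-checks use 4 × 10⁶ rejection samples.
* Root finding: `stats::uniroot` throughout; 10⁻⁴-degree tolerance on the
  tangency angle, volume matched to 0.1 % of the fill.
* Extraction defaults: 0.5 mm z-step, 1° azimuth step, offsets
  50–1050 µm; synthetic cells 1.5 mm with one-cell smear. Test runs use
  coarser azimuth grids (5–15°) where full resolution adds nothing.
* Junction branch selection carries a 10⁻⁹ mm tolerance so that heights
  exactly at the torus–cone junction are classified stably.
* The degenerate flat surface (zero frequency) is supported end to end:
  volume matching reduces to inverting the flask volume curve, and the
  contact line is constant.

## Limitations

The mechanistic model is inviscid and symmetric by construction; it
cannot produce the viscous apex shift, films, or out-of-phase behaviour
— those require a solver or experiment, and the package's role there is
post-processing and the synthetic stand-ins. The film estimator's
flat-surface ambiguity is documented above. The VTK layer reads and
writes legacy ASCII point-cloud and cell data only; binary and XML VTK
variants are out of scope.
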