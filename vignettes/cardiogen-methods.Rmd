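---
title: "Parametric cardiac geometry and monodomain electrophysiology: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric cardiac geometry and monodomain electrophysiology: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `cardiogen`: what is computed,
which parameters matter, the conventions and numerical choices, and —
importantly for a synthetic-data package — what the generated geometries do
and do not share with real anatomy.

# Conventions

All lengths are millimetres, times milliseconds, stresses kPa, potentials
millivolts. The long axis is +Z for both organs: the left-ventricle base
and the valve annulus plane sit at `z = 0`, the LV apex at `z = height`.
Meshes are indexed triangle surfaces (`trimesh`), counter-clockwise seen
from outside; watertightness means every undirected edge borders exactly
two consistently oriented faces, and enclosed volumes are computed by the
divergence theorem (sum of signed tetrahedra against the origin,
orientation-corrected to positive).

# Valve geometry

A leaflet is controlled by four scalars. The generating curve in the
meridian plane is

$$z(x) = H\,\frac{\ln\!\big(1 + a(1 - x/R)\big)}{\ln(1+a)},\qquad x\in[0,R],$$

anchored at the free-edge midpoint ($z(0)=H$) and the annulus attachment
($z(R)=0$). The curvature modifier $a$ bends the leaflet belly; the family
degenerates continuously to the straight line $H(1-x/R)$ as $a\to 0$
(implemented exactly below $a < 10^{-8}$). Published descriptions of such
leaflets fix only the qualitative roles of the controls — a logarithmic
belly bent by one parameter, a free edge shaped by another — so the
concrete log family above, and the free-edge height profile

$$f(\theta) = 1 - \left(\frac{|\theta|}{60^\circ}\right)^{k},$$

are this package's definitions. $f$ is 1 at the sector midline and 0 at the
commissures; larger $k$ keeps the edge high toward the commissures
($\partial f/\partial k > 0$ on the open sector, a tested invariant). The
surface is swept about the valve axis over $\theta \in [-60^\circ,
60^\circ]$ (three equal sectors) with local height $H f(\theta)$; the free
edge is the locus $x = 0$. Leaflets are zero-thickness midsurfaces: tissue
thickness and leaflet–leaflet contact (coaptation) belong to the
fluid–structure problem, which is out of scope here.

The aortic root is a revolved cylinder (radius = annulus radius, height =
bulb height) with the outward bulge

$$b(z,\theta) = d\,\sin^2\!\left(\frac{\pi z}{h_s}\right)\max(0,\cos 3\theta)^p,$$

which carves exactly three sinus-of-Valsalva pockets of depth $d$ over the
axial window $[0, h_s]$. The azimuthal sharpness $p$ defaults to 2; the
axial window and its unit peak at $h_s/2$ are package choices (only the
anatomy — three depressions in the bulb — is prescribed by the literature).
Default root parameters are the midpoints of the adult anatomical ranges
(diameter 15–30 mm, bulb height 17–25 mm, sinus height 17–20 mm, sinus
depth 1.5–3 mm; children: 6–20, 6–14, 6–14, 1.5–3 mm). Out-of-range
parameters error unless explicitly overridden, so accidental non-physiology
is loud.

# Left-ventricle geometry

The inner shell is a loft of circular (optionally elliptical) control
sections every 10 mm from base to apex; the outer shell reuses the same
sections with both semi-axes enlarged by the wall offset (default 10 mm,
read as a radius — not diameter — increment). Both shells are capped with
centroid fans, hence watertight. For piecewise-linear radius profiles the
capped loft volume equals the polygon-corrected solid-of-revolution
integral $(n/2)\sin(2\pi/n)\int r(z)^2\,dz$ to machine precision — the
test suite's independent volume oracle.

The shipped baseline profile (inner radii 11, 19, 24, 27, 27.5, 25.5, 22,
17, 11 mm over 80 mm) is a **calibrated stand-in**: the control ellipses
behind the published 22-model cohort are not public, so the profile is
calibrated to reproduce the baseline's height (80 mm) and outer-radius
extremes (21 and 37.5 mm) with a physiological cavity volume (123.6 mL at
the default resolution). Radii are interpreted as outer-surface radii:
with a ~10 mm wall that reading puts the cavity inside the 108–140 mL
patient envelope, whereas an inner-surface reading would give ~250 mL.
Secondary manifest columns (thickness min/max, radius average) are *not*
calibration targets and differ from any particular published table.

Measurement definitions, chosen once and used everywhere:

* **height** — extent of vertex projections on the long axis;
* **radii** — distances of outer-shell lateral vertices from the axis line
  through the vertex centroid; cap fans and a 2 mm apex band are excluded
  so the rounded apex does not drive the minimum to zero (with the
  exclusion, the minimum is attained at the 21 mm base/apex rings);
  the average is area-weighted;
* **thickness** — nearest-point (normal) distance from each lateral
  inner-shell vertex to the lateral outer surface. Distances are measured
  against lateral faces only because both shells are capped in the same
  base/apex planes, where a cap-to-cap distance would be zero by
  construction. Normal distance dips below the radial offset where the
  wall is sloped (7.8 mm near the apex taper of the baseline);
* **cavity volume** — enclosed volume of the inner shell, in mL.

Measurements are invariant under translation and rotation about the long
axis; the long-axis direction itself is a fixed convention (+Z), not
estimated from the mesh, so arbitrary rigid motions require the caller to
re-orient the model first.

# Cohort generation

The default cohort is 1 baseline + 7 height + 7 thickness + 7 shape
models:

* **height family** — z-coordinates affinely rescaled to 73, 75, 77, 79,
  82, 85, 89 mm; radii untouched, so cavity volume scales linearly with
  height (112.7–137.4 mL, all inside the ±15 % soft envelope);
* **thickness family** — wall offsets 8.5–11.5 mm around the 10 mm
  baseline; the inner shell, and hence the cavity, is identical across the
  family;
* **shape family** — x-shifts (±2–4 mm) of mid-ventricular section centers
  plus mild (±1.5 %) equatorial radius rescales, holding height and wall
  offset fixed. The individual edit sets are calibrated stand-ins chosen
  to bracket a realistic spread of outer radii.

Pseudo-random valve cohorts draw each parameter **uniformly** within its
population range. Uniform is a deliberate choice: published anatomy gives
ranges plus "commonly observed" sub-ranges but no distribution, and a
uniform draw maximises design-space coverage for surrogate training. A
mixture that re-weights the common diameter sub-range is available via
`common_weight` (off by default). Sampling uses R's Mersenne–Twister; the
generator name and seed are recorded on the result and in every CLI run
manifest, and identical seeds reproduce draws bit-for-bit.

`validate_physiology()` returns flags, never errors: the design ranges
intentionally exceed the six-patient envelope (heights 73–89 mm vs
patients' 75–85 mm), so boundary family members flag as outside the
patient envelope while remaining valid design points. The hard
physiological requirement tracked across the shipped cohort is the cavity
volume staying within ±15 % of the 108–140 mL patient span
(`volume_soft_ok`), which all 22 models satisfy.

# Electrophysiology

The monodomain model integrates, per node,

$$\frac{\partial\varphi}{\partial t} = \nabla\!\cdot\!\big(\hat D\nabla\varphi\big)
  - \frac{\tilde I_e + \tilde I_m}{\beta_t(Z)} + I_{\text{stim}},\qquad
  \hat D = d_{\text{iso}} I + d_{\text{ani}}\,a_0\!\otimes\!a_0,$$

with the Aliev–Panfilov excitation current
$\tilde I_e = c\varphi(\varphi-\alpha)(\varphi-1) + r\varphi$ and recovery
$\partial r/\partial\tau = (\gamma + \mu_1 r/(\mu_2+\varphi))
(-r - c\varphi(\varphi-b-1))$, $\tau = t/\beta_t$. The dimensional
potential is $\Phi = \beta_\varphi\varphi + \delta_\varphi$; with
$\beta_\varphi = 100$ mV, $\delta_\varphi = -80$ mV the nondimensional
range $[0,1]$ maps exactly onto the physiological $[-80, 20]$ mV — these
two values are forced by the printed resting/peak potentials, everything
else is calibration. The dimensional ionic current
$I_{\text{ion}} = C_m(\beta_\varphi/\beta_t)(\tilde I_e + \tilde I_m)$ is
exposed separately; in the nondimensional update the factors $\chi_m C_m$
cancel, which is why the solver takes $d_{\text{iso}}, d_{\text{ani}}$
directly as effective diffusivities in mm²/ms.

The local clock follows the apex-to-base activation-time law
$t_a = t_\alpha(1 - Z/Z_{\text{apex}})$,
$\beta_t = t_\beta\big(1 - \tau_0 (t_a - t_0)/(t_1 - t_0)\big)$: the apex
($Z=Z_{\text{apex}}$) has $t_a = 0$ and the slowest clock, the base the
fastest, so regions that depolarize last repolarize first. $\beta_t$ must
stay positive over the mesh and the solver errors otherwise.

The stretch-induced current
$\tilde I_m = H(\lambda-1)\,G_s(\lambda-1)(\varphi-\varphi_s)$ uses a
Heaviside tension gate — stretch-activated channels conduct only under
fiber tension, never compression. The stretch field defaults to
$\lambda = 1$ everywhere (mechanics decoupled), making $\tilde I_m$ vanish
unless a stretch field is supplied.

The active stress obeys
$\dot S_a = \varepsilon(\Phi)\big(k_T(\Phi - \Phi_r) - S_a\big)$ with the
Gompertz (double-exponential) delay rate
$\varepsilon(\Phi) = \varepsilon_0 + (\varepsilon_1 -
\varepsilon_0)\exp(-\exp(-\zeta(\Phi - \Phi_t)))$ — smooth, monotone and
bounded in $[\varepsilon_0, \varepsilon_1]$, so $S_a$ relaxes to
$k_T(\Phi-\Phi_r)$ at constant potential (with $k_T = 0.5$ kPa/mV, peak
drive 50 kPa, in line with reported ventricular wall stresses of
~100 ± 50 kPa). The tensor contribution
$S_a(\eta_1 a_0\!\otimes\!a_0 + \eta_2 s_0\!\otimes\!s_0 +
\eta_3 n_0\!\otimes\!n_0)$ adds to a passive second Piola–Kirchhoff stress
along an orthonormal fiber/sheet/normal frame; the passive stress itself
(finite-elasticity mechanics, pressure–volume loops) is outside this
package's scope.

Kinetic defaults are the canonical Aliev–Panfilov set ($c=8$,
$\alpha=b=0.15$, $\gamma=0.002$, $\mu_1=0.2$, $\mu_2=0.3$). The constants
with no published values here — $d_{\text{iso}}, d_{\text{ani}}, G_s,
\varphi_s, t_\alpha, t_\beta, \tau_0, t_{0,1}, \varepsilon_{0,1}, \zeta,
\Phi_t, \eta_{1\text{–}3}, \chi_m, C_m$ — default to literature-standard
magnitudes and should be treated as calibration knobs; all are plain
arguments of `ep_params()`.

# Numerics

* **Spatial discretisation** — mass-lumped linear finite elements: exact
  second differences on the uniform cable; P1 stiffness on surface
  triangles with the fiber direction projected into each triangle plane.
  The assembled stiffness is symmetric, negative semidefinite and
  annihilates constants, which makes the no-flux mass conservation of pure
  diffusion exact to round-off (tested at $10^{-10}$ relative).
* **Time integration** — forward Euler. The stability bound
  $dt < 2/\lambda_{\max}(M^{-1}(-K))$ is estimated by power iteration and
  applied with a 0.9 safety factor (capped at 0.05 ms so reaction kinetics
  stay resolved). Divergence ($|\varphi| > 2$) aborts with a diagnostic
  rather than returning garbage.
* **Degenerate inputs** — lofts reject fewer than two sections or
  non-monotone stacks; revolves reject non-positive radii; metrology
  rejects zero axes, empty and (for volumes) non-watertight meshes;
  disconnected domains are rejected by the operator assembly.
* **Tie-breaks** — ring vertex $j$ always connects to vertex $j$ of the
  next ring (no twist minimisation); caps fan to section centroids; the
  nearest-triangle search prunes to the one-ring of the nearest vertex,
  exact on the smooth meshes generated here.
* **Problem sizes** — geometry tests run at $n_\theta$ 32–256 with
  analytic-volume tolerances of 0.5 % at $n_\theta = 256$; cohort builds
  default to $n_\theta = 64$, 48 axial rings (the full 22-model cohort
  builds and measures in ~20 s); cable studies use 100 mm at 0.5 mm
  spacing, where the measured $\sqrt{d_{\text{iso}}}$ front-speed scaling
  holds to 0.5 %.

# What the synthetic data does and does not capture

The generator emulates gross anatomy — sizes, radii, wall thickness,
cavity volume, three-fold valve symmetry — within published physiological
ranges, which is what a geometry database for surrogate training needs.
It does **not** capture: trabeculae or papillary muscles; the aortic
orifice cut and LV–valve alignment; elliptical asymmetry beyond the
supported section edits; leaflet thickness and coaptation; patient-specific
fiber architecture (the default fiber field is a generic circumferential
map with all its known limitations); or any flow or tissue mechanics.
Passing the test suite therefore demonstrates correctness of the stated
constructions and measurements, not anatomical fidelity of any individual
synthetic patient.
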