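# cardiogen

Synthetic cohorts of aortic-valve and left-ventricle geometries for
cardiovascular modelling, plus a monodomain Aliev–Panfilov
electrophysiology solver to exercise them.

Fluid–structure simulations of the aortic valve are too expensive to run
across the thousands of anatomies a machine-learning surrogate needs for
training, and patient imaging cannot be scaled to cohorts of that size.
`cardiogen` addresses this by generating anatomically plausible geometries
algorithmically, from a handful of control parameters, and validating every
model against physiological ranges. It is aimed at cardiovascular
biomechanics groups building simulation databases and ML training sets.

## The models

**Valve.** Each leaflet is swept from a planar generating curve

    z(x) = H · ln(1 + a(1 − x/R)) / ln(1 + a),   x ∈ [0, R]

where `R` is the aortic (annulus) radius, `H` the leaflet height and `a`
bends the leaflet belly (`a → 0` recovers the straight line). Across its
120° sector the local height is scaled by the free-edge profile
`f(θ) = 1 − (|θ|/60°)^k`, so `k` controls the free-edge shape; commissures
sit at `θ = ±60°`. The aortic root is a surface of revolution with an
outward bulge `d · sin²(πz/h_s) · max(0, cos 3θ)²` carving the three
sinuses of Valsalva (depth `d`, height `h_s`).

**Left ventricle.** The inner (endocardial) shell is lofted from a stack of
control ellipses along the long axis (base `z = 0`, apex `z = height`); the
outer shell uses the same ellipses with both semi-axes enlarged by the wall
offset (default 10 mm). The shipped baseline profile is calibrated to a
height of 80 mm and outer radii running 21 → 37.5 → 21 mm, with a cavity
volume of ~124 mL, inside the 108–140 mL patient envelope. Systematic
families vary height (73–89 mm), wall offset and shape (x-shifts and
rescales of the control sections); together with the baseline they form the
default 22-model cohort. Seeded pseudo-random valve cohorts draw uniformly
within published adult/child anatomical ranges.

**Electrophysiology.** Excitation on a mesh or 1D cable follows the
monodomain reaction–diffusion model with conductivity
`D = d_iso I + d_ani a₀⊗a₀` along the fiber field, Aliev–Panfilov kinetics

    I_e = c φ (φ − α)(φ − 1) + r φ,
    ∂r/∂τ = (γ + μ₁ r/(μ₂ + φ)) (−r − c φ (φ − b − 1)),

the affine dimensionalization `Φ = β_φ φ + δ_φ` mapping `[0, 1]` onto
`[−80, 20]` mV, an apex-to-base activation-time rescaling of the local
clock `β_t`, a stretch-activated current gated by fiber tension
(`λ > 1`), and an active stress `S_a` relaxing toward `k_T (Φ − Φ_r)` that
is distributed along the fiber/sheet/normal frame of a second
Piola–Kirchhoff tensor. See `vignette("cardiogen-methods")` for every
symbol, unit and default.

## Worked example

```r
library(cardiogen)

lv <- build_lv(default_profile())
measure_lv(lv)
#> LV measurements: height 80.0 mm; thickness 7.81/9.99/9.14 mm (min/max/avg);
#>   radius 21.0/37.5/31.7 mm (min/max/avg); cavity volume 123.6 mL

sample_valve_cohort(3, seed = 42)[, c("aortic_diameter", "sinus_depth")]
#>   aortic_diameter sinus_depth
#> 1           28.72        2.56
#> 2           29.06        2.19
#> 3           19.29        2.58

cab <- cable_mesh(100, 0.5)
s <- simulate_monodomain(cab, ep_params(t_alpha = 0),
                         stimulus = list(nodes = 1:5, amplitude = 1,
                                         duration = 1),
                         T_end = 400, sample_dt = 1)
s
#> <ep_series: 201 nodes, 401 samples over 400 ms (dt = 0.05 ms)>
#>   potential range -80.0 .. 20.3 mV
```

The measurements are the manifest columns of the cohort: long-axis height,
normal-to-surface wall thickness, outer-surface radii about the long axis
(caps and a 2 mm apex band excluded) and the enclosed endocardial volume.
The cable run shows a propagating action potential spanning the full
physiological −80 to +20 mV range (conduction speed ≈ 0.39 mm/ms at
`d_iso = 1 mm²/ms`).

A command-line interface wraps the same functions:

```sh
./exec/cardiogen generate-cohort --default --out cohort/
./exec/cardiogen generate-valve --R 11 --H 11 --out valve/ --format stl
./exec/cardiogen simulate-ep --cable 100,0.5 --stimulus "z<5,1" --T 400 --out run
```

Every run writes a `run_manifest.yaml` (full configuration, seed, package
version) and is byte-for-byte reproducible.

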