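Package: cardiogen
Title: Parametric Aortic Valve and Left Ventricle Geometry Generation with
    Monodomain Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Algorithmic generation of synthetic cohorts of aortic-valve and
    left-ventricle surface geometries for cardiovascular modelling.  Leaflets
    are swept from a logarithmic generating curve controlled by the aortic
    radius, leaflet height, a curvature modifier and a free-edge shape
    exponent; the aortic root is a surface of revolution with three sinuses of
    Valsalva; the left ventricle is lofted from a stack of control ellipses
    with a radial wall offset.  Systematic families (height, wall thickness,
    shape) and seeded pseudo-random cohorts are measured (height, radii, wall
    thickness, cavity volume) and validated against physiological ranges.  A
    monodomain Aliev-Panfilov reaction-diffusion model with anisotropic fiber
    conductivity, apex-to-base activation-time rescaling, stretch-induced
    current and active-stress dynamics simulates excitation on the generated
    meshes or on a 1D cable.  Meshes export to STL, OBJ, PLY and legacy VTK;
    cohort manifests to CSV; a command-line interface drives reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
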