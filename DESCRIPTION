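Package: neurotransport
Title: Regulated Molecular-Motor Transport in Branched Neuron Geometries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates regulated motor-assisted intracellular transport in
    planar branched neuron geometries. Neuron skeletons (SWC morphologies or
    synthetic pipes, bifurcations and trees) are swept into quadrilateral tube
    meshes carrying a quadratic spline Galerkin basis. On that basis the
    package discretises an advection-diffusion-reaction model of free and
    microtubule-bound cargo together with a traffic-flow velocity equation,
    and solves the associated optimal-control problem (velocity tracking,
    concentration-gradient penalty and control-effort penalty) all-at-once
    from its first-order optimality conditions with Newton iterations and
    preconditioned GMRES. Built-in scenarios reproduce traffic jams caused by
    local microtubule reduction and by microtubule swirls with local swelling,
    and provide centerline concentration profiles, vorticity diagnostics,
    parameter sweeps and VTK/CSV exporters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
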