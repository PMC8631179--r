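Package: gitr
Title: Generalized Inter-State Transformation Rates for Self-Assembly Networks
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic analysis of multi-state self-assembly networks in which
    stable cluster states are connected through transition states in a
    bipartite topology. Provides transition-state-theory path and state
    rates, equilibrium monomer distributions, linking-fraction matrices,
    and an eigendecomposition solution of the linear kinetics, together
    with the supporting free-energy bookkeeping: MM-PBSA component
    recombination, Jarzynski-equality potential-of-mean-force estimation
    from nonequilibrium pulling work, and trajectory metrics (RMSD, RMSF,
    cross-correlation matrices, geometric hydrogen-bond occupancy). Ships
    a worked example analysing the dimerization-mode transformations of
    the immune-checkpoint protein PD-L1 with a small-molecule inhibitor.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    Matrix,
    bio3d,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
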