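Package: hbpsim
Title: Forward Dynamic Simulation and Optimization of Handle-Based Wheelchair Propulsion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Muscle-driven forward dynamic simulation and optimization of a
    handle-based isokinetic wheelchair propulsion mechanism. A parametric
    closed handle path (two scale factors, a shape exponent and a tilt angle)
    is coupled to a crank-slider mechanism rotating at constant cadence; a
    planar upper-extremity model actuated by 15 Hill-type musculotendon units
    is closed-chained to the handle. The package evaluates and characterizes
    candidate handle paths (circularity, effective-crank-length profiles),
    integrates muscle activation dynamics under spline-parameterized
    excitations, computes crank torque and net propulsion power by virtual
    work, and jointly optimizes the path shape and per-muscle excitation
    trajectories to maximize net propulsion power under joint-range and
    mechanism-bound penalties. Post-processing reports per-zone muscle work,
    joint ranges of motion, normalized fiber mechanics and peak forces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
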