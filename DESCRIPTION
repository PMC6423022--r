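Package: nanorsa
Title: Random Sequential Adsorption of Globular Proteins on Nanostructured Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of irreversible protein adsorption
    (random sequential adsorption, RSA) on nanostructured substrates.
    Substrates are described as single-valued height fields: periodic
    arrays of truncated Gaussian pillars, spikes and holes, or gridded
    AFM-like height maps.  Hard spheres are deposited at area-weighted
    uniform random positions and accepted under steric exclusion,
    yielding blocking functions B(theta), jamming limits, and vertical
    adsorption profiles.  Downstream tools solve the adsorption kinetics
    ODE d(theta)/dt = k_a*n*B(theta) - k_d*theta with a fitted blocking
    polynomial, compare RSA and Langmuir isotherms, and estimate
    diffusion timescales.  Includes a synthetic generator of rough
    spike-field height maps emulating black-silicon topography.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
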