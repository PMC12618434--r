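Package: stabscape
Title: Stability Landscapes of Ecological ODE Models via Routing Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the positive parameter space of polynomial or rational
    ordinary differential equation models into connected regions on which the
    number and type of stable steady states are constant. Computes the
    singular, Routh-Hurwitz and coordinate boundaries of each component of
    the equilibrium ideal by symbolic elimination, assembles the total
    boundary as a hypersurface arrangement, and enumerates the connected
    components of its complement with routing functions: bounded rational
    functions whose critical points catalogue the regions and whose gradient
    flow connects them. Includes steady-state solving with Routh-Hurwitz
    stability classification, stability-landscape slices, a grid/roadmap
    component-counting oracle, and built-in ecological fixtures
    (predator-prey with Allee effect, Levins-Culver competition-colonization,
    coral-bacteria symbiosis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with sympy, on the PATH as 'python'
Config/testthat/edition: 3
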