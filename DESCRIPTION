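Package: bpflip
Title: Free-Energy Surfaces and Pathways for Watson-Crick to Hoogsteen
    Base-Pair Switching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the conformational switch between Watson-Crick
    and Hoogsteen base pairing in duplex DNA on two-dimensional reaction
    coordinates: the purine glycosidic angle (chi) and a centre-of-mass
    pseudodihedral base-flipping coordinate (CPDb). Implements the reaction
    coordinates from atomic structures, a rectangular grid of harmonic umbrella
    windows, self-consistent WHAM reweighting of biased samples into a periodic
    two-dimensional free-energy surface, effective 1D profiles, minimax
    transition-path and transition-state analysis with the six-route
    clockwise/counterclockwise x small/major/minor taxonomy, cumulative-time
    convergence diagnostics, and the equal-K osmotic-coefficient analysis of
    nucleoside aggregation. A synthetic biased-sampling generator (Metropolis
    windows on an analytic model surface, a toy well-tempered metadynamics
    walker, and equal-K aggregation frames) exercises every stage without
    molecular-dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
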