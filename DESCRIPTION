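Package: filotrace
Title: Semi-Automatic Tracing and Tracking of Filopodia in 4D Two-Photon Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless, scriptable reconstruction of axon-terminal filopodia from
    time-lapse 3D fluorescence microscopy. Filopodia are traced from seeded tip
    positions to the axon terminal center with an intensity-weighted Dijkstra
    shortest-path algorithm over the 26-connected voxel lattice, bases are located
    as the change point from Gaussian to non-Gaussian transverse intensity
    profiles, and tips, bases and terminal centers are propagated between time
    steps by normalized cross-correlation template matching. The result is a 4D
    skeleton graph with typed nodes (root, base, branching, tip), labeled
    polyline edges and per-filopodium track identities, from which per-track
    dynamics statistics (lengths, extension and retraction events, velocities,
    lifetimes, growth angles) are computed and exported as spreadsheets. A
    ground-truthed synthetic microscopy simulator supports end-to-end testing,
    and programmatic edit commands replay the proofreading operations of an
    interactive workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
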