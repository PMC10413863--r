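Package: probepocket
Title: Probe-Sphere Pocket Detection and Isolation-Forest Ranking for Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and ranks ligand-binding pockets on protein structures.
    Candidate pockets are assembled by hierarchically clustering solvent-probe
    spheres tangent to atom triplets, generated over a ladder of probe radii
    (1.4 to 3.0 Angstrom). Four clustering event types (bottleneck, radial
    shift, pyramidal and lateral aggregation) grow a cluster tree from which
    pockets, subpockets and entrances are extracted. Each pocket is described
    by 17 geometric/clustering and 22 chemical descriptors and ranked by
    Isolation-Forest anomaly scores trained on hitting pockets only
    (one-class learning). Ligand-coverage and pocket-coverage evaluation
    metrics, ranking protocols (standard, nested, single-pocket), synthetic
    cavity fixtures and a two-probe grid oracle are included so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
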