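Package: gyredyn
Title: Gyre Geometry and Ensemble Dynamics of Nucleosome-Like Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative structural analysis of nucleosome-like particles
    (nucleosomes, octasomes, tetrasome stacks): dyad-relative base-pair
    indexing of the wrapped DNA duplex, gyre-opening ("clamshell") angle and
    gyre-distance metrics, rigid-body superposition and four-helix-bundle
    rotation angles, hydrogen-bond network auditing, and ensemble dynamics
    (iterative alignment, RMSF/B-factor profiles, Cartesian PCA with
    porcupine export, and DNA hinge detection). Includes a synthetic
    superhelix/ensemble generator with ground-truth bookkeeping so every
    analysis stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
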