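Package: ciliaflow
Title: Cilia-Driven Stokes Flow in a Wall-Bounded Ventricle Window
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the planar creeping flow driven by motile cilia beating
    over a no-slip wall, as in the ciliated lining of the zebrafish embryonic
    brain ventricle. Cilia are prescribed moving boundaries: a parametric
    tangent-angle beat generator (tiltable, phase-shiftable, with a tunable
    non-reciprocal stroke) supplies node kinematics, a regularized-Stokeslet
    boundary solver with an exact wall image system converts them into forces
    and velocity fields at each time instant, and flux metrics integrate the
    horizontal velocity across the downstream boundary into per-cycle and
    whole-run pumping rates. Ships the five standard comparison cases (tilt
    30/50/60 degrees, one versus two cilia, in-phase versus out-of-phase
    beating) behind a scenario runner with deterministic, provenance-stamped
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
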