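Package: cadint
Title: Interface, Geometry and Sequence Analysis for Tandem Cadherin Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes adhesive interfaces formed by tandem extracellular
    cadherin (EC) repeats. Provides deterministic Shrake-Rupley
    solvent-accessible surface area, buried-surface decomposition of
    protomer-protomer interfaces with per-repeat-pair attribution, interface
    composition, salt-bridge detection and biological-versus-crystal-contact
    classification, crystallographic symmetry expansion, Kabsch superposition
    and inter-repeat azimuthal geometry, alignment-based conservation scoring
    with nine bins and structure mapping, glycosylation-sequon and
    calcium-binding-motif scanning, quantification of differential scanning
    fluorimetry melt curves and bead-aggregation images, and a synthetic-data
    generator that writes standard-format fixtures with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
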