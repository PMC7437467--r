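Package: aqpflux
Title: Osmotic Permeability and Hydrophobic Mismatch Analysis for
    Water-Channel Membrane Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-simulation analysis chain for aquaporin-lipid membrane
    systems. Reads PDB topologies and multi-model PDB or CHARMM/NAMD DCD
    trajectories, computes the collective coordinate n(t) of water motion
    through a channel, estimates its diffusion constant D_n from windowed
    mean-squared displacements by least squares and converts it to osmotic
    permeabilities (per monomer and per tetramer), quantifies bilayer
    hydrophobic mismatch as the phosphorus-to-phosphorus thickness change of
    the protein-adjacent lipid shell, computes selectivity-filter central
    areas and their relative-frequency histograms, and predicts system-level
    permeability trends from protein density and thickness mismatch.
    Includes synthetic-trajectory generators with analytically known ground
    truth for validating every stage of the chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    optparse
Config/testthat/edition: 3
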