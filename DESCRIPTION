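Package: cgdna
Title: Sequence-Dependent Coarse-Grained Simulation of Duplex B-DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A one-bead-per-nucleotide coarse-grained model of duplex B-DNA.
    Beads sit at the C1' sugar positions and interact through tetramer-dependent
    bonded terms (stacking, pairing, angle and cross-strand fan interactions,
    truncated quartic polynomial potentials), sequence-averaged distant terms,
    and remote Lennard-Jones plus Debye-Hueckel electrostatics. The package
    provides a Langevin (BAOAB velocity-Verlet) dynamics engine with a compiled
    kernel, bottom-up parameter fitting from reference bead ensembles, a
    synthetic ideal-B-DNA reference generator, regression-based back-mapping of
    bead trajectories to all-heavy-atom coordinates, and a DNA-mechanics
    analysis suite (RMSD, essential dynamics, persistence length, end-to-end
    distance, gyration shape, bending profiles, writhe for closed circles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
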