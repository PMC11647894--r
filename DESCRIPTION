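Package: cellenergy
Title: Nonbonded Energy Decomposition and Hydrogen-Bond Scoring for
    Cellulose Nanocrystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds idealized cellulose Ibeta and II nanocrystals, assigns
    GLYCAM-style partial charges and Lennard-Jones parameters, and decomposes
    pairwise nonbonded energies into interchain and intrachain electrostatic
    and van der Waals contributions.  Bulk (per-glucose) energies are
    extracted from crystals of increasing chain length by linear fitting.
    Hydrogen bonds are detected with a distance- and angle-based geometric
    criterion and scored in three modes, including a group-based multipole
    description that pairs the donor C-O-H triple with the near-neutral
    acceptor group.  Ships a synthetic-data module producing analytic
    two-body systems, idealized hydrogen-bond geometries, toy crystals with
    brute-force energy ledgers, and noisy linear size series.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
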