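Package: cyclomem
Title: Coarse-Grained Analytics for Cyclotide-Membrane Binding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds coarse-grained (CG) bead models of head-to-tail cyclic
    peptides such as the cyclotide kalata B1, generates phase-separated
    raft-mimicking bilayers (DPPC/DUPC/cholesterol), synthesises test
    trajectories and umbrella-sampling data with known ground truth, and
    analyses peptide-membrane binding: per-residue membrane-surface
    distances and binding times, residue contact-frequency matrices,
    lipid-domain occupancy, shifted Lennard-Jones/Coulomb interaction-energy
    decompositions, and potential-of-mean-force estimation by the weighted
    histogram analysis method (WHAM) with bootstrap error bars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
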