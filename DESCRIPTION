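Package: poseguide
Title: Knowledge-Guided Rescoring of Docking Poses and Protein Ensemble
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Docking-engine-agnostic machinery for exploiting previously
    solved protein-ligand complexes when predicting bound configurations of
    new ligands. Mines positioned substructural hint fragments from known
    bound ligands with a budgeted depth-first common-subgraph search,
    converts in-site 3D similarity of candidate poses to known ligands into
    probabilistic corrections of docking scores (in pKd units), groups poses
    into Boltzmann-ranked pose families, selects representative protein
    variants from binding-pocket similarity matrices by K-medoids (with
    diverse and random comparison strategies), and evaluates predictions with
    symmetry-corrected RMSD, success-at-top-k, cumulative histograms,
    novelty fractions, and standard distribution tests. Includes SDF (V2000)
    and MOL2 structure I/O, a rooted-subgraph 2D similarity (GSIM-style),
    curation filters with temporal partitioning for benchmark construction,
    and a deterministic synthetic-fixture generator so every analysis runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    ChemmineR,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
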