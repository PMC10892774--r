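Package: alascan
Title: Computational Alanine Scanning of Protein-Peptide Complexes with
    GB/SA Energetics and Interaction Entropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory post-processing for residue-wise computational
    alanine scanning of protein-peptide complexes. Reads multi-model PDB
    ensembles and per-atom force-field parameter tables, truncates interface
    side chains to alanine within the single-trajectory approximation, and
    decomposes per-residue binding free-energy changes into van der Waals,
    electrostatic (residue-class dielectrics), generalized Born polar and
    surface-area nonpolar solvation components, with the entropic term
    estimated from interaction-energy fluctuations via the exponential-
    average interaction-entropy estimator under a 3-sigma noise cutoff.
    Per-residue contributions are assembled into binding free energies by
    receptor-side, ligand-side, averaged, and van der Waals-plus-entropy
    schemes, aggregated over independent trajectories, and scored against
    experimental affinities (ID50 or free energies) with Pearson/Spearman
    statistics and seeded bootstrap confidence intervals. A synthetic-fixture
    generator builds parameterized toy complexes, perturbation ensembles and
    designed variant families so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
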