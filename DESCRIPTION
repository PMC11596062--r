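Package: DockConsensus
Title: Consensus Binding-Region Identification from Multi-Ligand Docking
    Poses and ATPase Kinetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies a consensus ligand-binding region on a receptor from
    multi-ligand docking pose sets. Poses of different ligands sharing one
    receptor frame are compared by scaffold RMSD without superposition, one
    pose per ligand is combined into constellations ranked by mean pairwise
    core RMSD, and among the most congruent constellations the one with the
    highest amino-acid interaction similarity factor is selected. Companion
    tools fit Michaelis-Menten kinetics to vanadate-sensitive ATPase
    dose-response data, compare curves by extra-sum-of-squares F tests, and
    tabulate docking-score differences against Michaelis-constant
    differences across transporters. A synthetic-data module generates pose
    sets with a planted consensus, proximity-consistent interaction tables
    and noisy dose-response data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    pheatmap
Config/testthat/edition: 3
biocViews: StructuralPrediction, Cheminformatics, Pharmacogenomics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'congruence.R'
    'constellation.R'
    'kinetics.R'
    'pose-io.R'
    'scaffold.R'
    'synthetic.R'
    'similarity.R'
    'selection.R'
    'pipeline.R'
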