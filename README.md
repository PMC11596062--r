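# DockConsensus

Consensus binding-region identification from multi-ligand docking pose
sets, with companion Michaelis–Menten kinetics tools — an R/S4 package for
structural bioinformatics workflows on transporter–ligand specificity
(the motivating system: cardenolides docked against insect ABCB /
P-glycoprotein-type efflux transporters).

## The method

A docking screen of L related ligands yields M poses each. If the
receptor has one common binding region for the family, the true poses
should converge there and touch the same residues. DockConsensus selects
that consensus in two steps:

1. **Congruence.** Every *constellation* (one pose per ligand) is ranked
   by the mean pairwise scaffold RMSD of its members, computed over the
   N corresponding core atoms in the shared receptor frame, with no
   superposition:

   RMSD = sqrt( Σᵢ ‖Aᵢ − Bᵢ‖² / N )

   For cardenolides the core is a 25-heavy-atom scaffold (steroid
   nucleus + butenolide ring; sugars excluded). The top k = 15
   constellations become candidates.

2. **Interaction similarity.** Each candidate's similarity factor is

   Sf = B_similar / B_total

   where B_total counts the candidate's protein–ligand interaction
   records and B_similar those whose residue(+class) key occurs in at
   least two distinct ligands' poses. The Sf argmax wins; similarity has
   priority over RMSD rank. Docking scores are reported, never ranked on.

Kinetics side: vanadate-sensitive ATPase activities (±500 µM vanadate,
differenced), Michaelis–Menten fits (Vmax, Km ± SE), extra-sum-of-squares
F tests between curves, and a per-substrate Δ docking score vs Δ Km table
between two transporters.

A synthetic-data module generates pose sets with a planted consensus,
matching interaction tables and noisy dose–response data with known
ground truth — planted poses are deliberately never best-scored, so the
selection must work from geometry and interactions.

## Worked example

```r
library(DockConsensus)
wd <- tempfile("demo-")
cfg <- pipelineConfig(workdir = wd, seed = 4)
runPipeline("all", cfg)
```

which logs

```
[simulate] workspace -> ... (seed 4)
[congruence] 45 poses, 5 ligands
[select] chose constellation #1, Sf = 0.67
[kinetics] 4 Michaelis-Menten fits
[kinetics] delta table over 5 substrates -> .../delta_table.tsv
```

and writes `selection.tsv.txt`:

```
Consensus constellation: #1
  members: ligand_A/model 1, ligand_B/model 4, ligand_C/model 2, ligand_D/model 4, ligand_E/model 3
  mean core RMSD: 0.73 A
  interactions: 30 total, 20 shared, Sf = 0.67
  docking scores [kcal/mol]: ligand_A -8.0, ligand_B -7.7, ligand_C -7.7, ligand_D -8.0, ligand_E -7.8
```

Reading: of the 9⁵ = 59,049 constellations over the 45 synthetic poses,
the selected one is the planted consensus — its members sit within
0.73 Å mean scaffold RMSD of each other, and 20 of their 30 interaction
records recur across ligands (Sf = 0.67). The kinetics stage fits, e.g.,
digoxin/T2 at Km ≈ 11.0 µM against a simulated truth of 9.33 µM and
tabulates Δ score / Δ Km per substrate (`delta_table.tsv`).

The same stages are exposed as a thin CLI:

```sh
Rscript inst/scripts/dockconsensus.R all --workdir /tmp/demo --seed 4
```

Individual pieces are plain functions: `readPoseFile()`,
`cardenolideTemplate()`, `resolveCorrespondence()`, `coreRmsd()`,
`pairwiseMatrix()`, `enumerateConstellations()`,
`constellationSimilarity()`, `selectConstellation()`,
`fitMichaelisMenten()`, `compareCurves()`, `deltaTable()`. See the
vignette (`vignettes/consensus-docking.Rmd`) for the model, parameter
defaults and design rationale.

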