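---
title: "Consensus binding-region selection from multi-ligand docking poses"
author: "DockConsensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus binding-region selection from multi-ligand docking poses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DockConsensus)
```

## The problem

Docking a family of related ligands -- here cardenolides, the steroid
glycoside toxins of milkweed plants, against ABCB (P-glycoprotein-type)
efflux transporters -- produces several plausible poses per ligand, and
docking scores alone rarely single out the biologically meaningful one.
If the transporter has one cardenolide binding region, the true poses of
the different ligands should (a) occupy the same place in the receptor and
(b) touch the same amino acids. DockConsensus turns that idea into a
reproducible two-step selection:

1. **Congruence.** Every combination of one pose per ligand (a
   *constellation*) is ranked by the mean pairwise RMSD of the ligands'
   common scaffold, computed in the shared receptor frame. The most
   congruent `k` constellations (default 15) become candidates.
2. **Interaction similarity.** Each candidate gets a similarity factor
   `Sf = B_similar / B_total`, the fraction of its protein--ligand
   interaction records whose key recurs in at least two distinct ligands'
   poses. The candidate with the highest `Sf` is the consensus; similarity
   has priority over the RMSD rank.

The companion kinetics tools relate such predictions to bench data:
vanadate-sensitive ATPase activities are differenced, fitted with
Michaelis--Menten curves, compared by extra-sum-of-squares F tests, and
docking-score differences are tabulated against Michaelis-constant
differences between two transporters.

## Scaffold RMSD without superposition

For two poses with corresponding scaffold atoms \(A_i\) and \(B_i\),

\[
\mathrm{RMSD} = \sqrt{\frac{1}{N}\sum_{i=1}^{N} \lVert A_i - B_i \rVert^2 },
\]

with **no** prior superposition. This is deliberate: all poses are docked
into one fixed receptor model, so the raw-frame RMSD measures whether two
poses sit in the same binding region. A least-squares superposition would
erase exactly the positional information the method needs; an optional
`superpose = TRUE` exists in `coreRmsd()` for shape-only questions and is
off by default. On fixed-order coordinate lists the quantity is a metric
(symmetry, identity, triangle inequality), which the test suite checks on
random triples.

Comparing *different* cardenolides atom-by-atom requires a shared core.
`cardenolideTemplate()` ships a 25-heavy-atom scaffold: the 17 carbons of
the tetracyclic steroid nucleus, the two angular methyls C18/C19, the four
butenolide carbons C20--C23 and the lactone's two oxygens (ring O21,
carbonyl O23) -- 23 C and 2 O. The exact membership of the 25 atoms is our
reconstruction from the scaffold's chemistry; it is a replaceable
`ScaffoldTemplate` object, not a constant baked into the RMSD code.
Glycone (sugar) residues and aglycone substituents differ between
cardenolides and never enter the core.

```{r template}
tpl <- cardenolideTemplate()
tpl
table(tpl@atoms$element)
```

Atom correspondence between a pose and the template is resolved either
`by_name` (template labels through a per-ligand name map; deterministic
and auditable, the default for curated inputs) or `by_graph` (bond
perception from interatomic distances with covalent radii + 0.45 Å
tolerance, then element-aware subgraph isomorphism). Coordinate-equivalent
multiple embeddings are resolved to the lexicographically smallest pose
serial sequence with a warning; embeddings that disagree in coordinates by
more than 1e-6 Å raise an ambiguity error rather than guessing.

## Constellation enumeration and ranking

With \(L\) ligands and \(M\) poses each there are \(M^L\) constellations
(59,049 for the 5 × 9 screen), each scored by the mean of its
\(\binom{L}{2}\) pairwise core RMSDs -- all pairs, not pairs to a
reference. Full enumeration is the default and entirely cheap at this
size; a cap (10^6 combinations) guards against accidental explosion, and a
beam search with an optimistic completion bound (realized pair sum plus
the minimum possible value of every not-yet-realized pair) exists for
larger pose sets. The beam is validated against full enumeration, both in
the unit tests and in a 100-instance property suite.

The constellation `index` is the rank under the canonical sort (ascending
mean RMSD, ties by lexicographic member tuple). Published analyses of this
kind number constellations by heat-map layout, which is not reproducible
from a text description; our index is therefore this package's own
numbering and is never claimed to coincide with any external one.

## The similarity factor

`constellationSimilarity()` restricts the interaction table to the member
poses. `B_total` is the number of those records; a record is *similar*
when its key occurs in the member poses of **at least two distinct
ligands**, and each record counts once in both tallies. The default key is
residue identity **plus** interaction class (`residue_and_class`), since
both the occurrence and the type of contact should recur at a genuine
common site; `residue_only` is available as a documented coarser option
and can only raise `Sf` (also a tested property). Reports print `Sf` at
two decimals with half-up rounding (so 0.625 prints as 0.63, matching how
such tables are typically typeset); full precision is kept internally.

`bondClassSummary()` tallies records over the closed class vocabulary and
reports the ratio of hydrogen bonds (conventional + carbon) to alkyl-type
contacts (alkyl + pi-alkyl), a coarse polarity signature of a binding
region; it is undefined (NA) without alkyl-type contacts.

Selection (`selectConstellation()`) is strictly rule-based: the `Sf`
argmax among the top-`k` congruent candidates, ties broken by lower mean
RMSD, then lower index. We chose the plain maximum rather than any
`Sf`/RMSD composite because the procedure being reproduced states a
priority, not a weighting. With no interaction records at all the
selection degrades to the congruence rank-1 constellation with a warning.
Docking scores are carried into every report but never used for ranking.

## Kinetics

ATPase assays pair each substrate concentration with and without 500 µM
orthovanadate; the difference is the transporter-attributable activity.
Negative differences are retained -- truncating them would bias the fit --
and flagged. `fitMichaelisMenten()` fits \(v = V_{max} S / (K_m + S)\) by
constrained Levenberg--Marquardt least squares (start values
\(V_{max,0} = \max v\), \(K_{m,0}\) at the first half-maximal activity;
relative tolerance 1e-10), with standard errors from the curvature of the
squared-error surface at the optimum. `compareCurves()` is the
extra-sum-of-squares F test between separate and pooled fits with 2
numerator degrees of freedom (the freed parameters) -- reconstructed from
the reported degrees-of-freedom structure of the original analyses, since
the software used there does not name its method; with identical noiseless
data F is defined as 0. `deltaTable()` reports, per substrate, each
transporter's docking score and fitted \(K_m\) and their differences
(second transporter minus reference), leaving \(K_m\) columns `NA` for
substrates that were only docked, and is antisymmetric under swapping the
transporter labels.

## What the synthetic generator emulates

`generatePoseSet()` plants, for each of `L = 5` ligands, one pose of the
25-atom scaffold at a shared consensus site -- common orientation,
per-atom Gaussian jitter `sigmaIn = 0.5` Å -- and `M - 1 = 8` decoys
rigidly displaced by 5--20 Å in random orientations, mirroring a
5-cardenolide × 9-model screen in one receptor frame. Three glycone-like
atoms per pose exercise core extraction. Two deliberate design points:

* **Scores are decoupled from geometry**, and planted poses are *never*
  the best-scored pose of their ligand. Any implementation shortcut that
  ranks by score instead of geometry + interactions fails the recovery
  tests by construction.
* **Interactions are proximity-consistent**: planted poses share four
  consensus-site residue keys (fixed residue and class per key) plus two
  private keys each; decoys get only private keys. The planted
  constellation's expected `Sf` is 20/30 ≈ 0.67 under defaults.

`generateMmData()` simulates the paired assay on a 0--800 µM grid (10
concentrations, 5 replicates, noise SD 5 % of \(V_{max}\), baseline 2
activity units) with the vanadate arm modelled as complete inhibition, so
the difference recovers the Michaelis--Menten curve exactly in
expectation. Partial inhibition, pipetting drift, replicate-level random
effects and any realistic docking-energy physics are *not* modelled:
passing recovery tests shows the selection and fitting machinery is
correct, not that real screens of real transporters will be this clean.

The demo kinetic truths (e.g. \(V_{max}\) 12.54, \(K_m\) 9.33 µM) are
magnitudes typical of cardenolide-stimulated ABCB ATPase work, chosen once
as realistic defaults. All generators are pure functions of (parameters,
seed); regeneration is byte-identical.

## Numerical choices and degenerate inputs

* Coordinates are Å everywhere; no unit conversion exists anywhere.
* RMSD matrices keep full precision in memory and round to 3 decimals only
  at serialization; `readRmsdMatrix()` re-symmetrizes the 1e-3 rounding.
* `sfFromCounts()` rejects `B_total = 0`; a constellation with no records
  reports `Sf = 0` from its own restriction step, with a message naming
  the empty members.
* The redocking congruence call uses a named 4 Å threshold
  (`congruenceThreshold`), the conventional acceptance bound for
  redocking validation.
* Enumeration ties are broken lexicographically; selection ties by lower
  mean RMSD then lower index -- every path is deterministic, and pipeline
  reruns on identical inputs produce byte-identical artifacts.
* Problem sizes in the test suite (5 × 9 screens, 100-seed recovery and
  beam-vs-full sweeps, 200-replicate Monte-Carlo fit calibration) were
  chosen to exercise the full combinatorial path of the method at the
  scale the procedure targets.

## Known limitations

* No geometric interaction detection: interaction tables are inputs,
  produced upstream by structure-analysis software; the package only
  consumes and fabricates them.
* No symmetry-corrected RMSD and no maximum-common-substructure search
  across unrelated chemotypes; the scaffold template assumes one ligand
  family.
* Published constellation numberings and absolute docking scores are not
  reproducible from text descriptions; only the arithmetic built on them
  (similarity factors, delta tables) is.
* The F-test reconstruction assumes homoscedastic Gaussian residuals, as
  does any extra-sum-of-squares comparison.

## A complete run

```{r pipeline, eval = FALSE}
wd <- tempfile("demo-")
cfg <- pipelineConfig(workdir = wd, seed = 4)
runPipeline("all", cfg)
# artifacts: rmsd_matrix.tsv, selection.tsv(.txt), kinetic_fits.tsv,
#            delta_table.tsv
```
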