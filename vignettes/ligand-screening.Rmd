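---
title: "Ligand-based screening and target repurposing with lbvs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based screening and target repurposing with lbvs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the screening model, the assumptions behind each stage, the tunable
parameters and their defaults, what the synthetic corpora do and do not
emulate, and the numerical choices that make the whole pipeline
deterministic.

## The screening model

The workflow answers a repurposing question: given a small-molecule query
scaffold, which protein targets are supported by catalogued ligands that
resemble it? Resemblance is judged twice, by independent criteria:

1. **2D fingerprint consensus.** Five fingerprints are computed per
   molecule — MACCS substructure keys (166 bits) and four hashed circular
   fingerprints (ECFP4/ECFP6 with element-based atom invariants,
   FCFP4/FCFP6 with pharmacophoric functional-class invariants; the
   numeral is the bond *diameter*, so ECFP4 iterates to radius 2). Each
   is scored with the Tanimoto coefficient, and a reference passes only
   when all five coefficients reach their thresholds (defaults
   0.7 / 0.3 / 0.4 / 0.3 / 0.4). Requiring the conjunction suppresses
   the biases of any single representation: MACCS favours shared
   functional groups, ECFP favours shared connectivity, FCFP tolerates
   atom substitutions that preserve pharmacophoric roles.
2. **3D Gaussian shape and colour.** Each conformer is a sum of atomic
   Gaussians; the overlap volume between two molecules is maximized over
   rigid motions, and similarity is the Tanimoto ratio of overlap
   volumes (`ShapeTanimoto`), plus the analogous ratio over
   pharmacophore "colour" features matched within type
   (`ColorTanimoto`). Their sum, `TanimotoCombo` (range 0–2), must reach
   1.2. For flexible molecules the score is the maximum over all
   conformer pairs.

A reference ligand is a *consensus hit* only if it passes both screens.
Hits are then joined **across corpora by canonical isomeric SMILES**, so
one physical molecule catalogued under a DrugBank accession, a PDB HET
code and a ChEMBL identifier is counted once — molecules found in all
three corpora are the strongest candidates. Finally each target is
summarized by the number of distinct similar ligands per corpus, with
ChEMBL ligands split into actives and inactives, and targets are ranked
by the lexicographic key (corpora spanned, active − inactive, total
ligands, actives), ties broken alphabetically. The ranking is a
documented heuristic: no null model exists for these counts, so no
significance is attached to the order.

## Curation assumptions

- DrugBank-dialect corpora keep only `small_molecule` entries; biologics
  cannot be fingerprinted meaningfully.
- PDB-dialect corpora drop stoplisted HET codes (waters, buffers,
  cryoprotectants; the shipped list is a plain-text file and fully
  configurable), monoatomic ions (at most one heavy atom), and charged
  species with no carbon. A record with a HET code but an unparsable
  structure is kept conservatively; a record with neither is skipped and
  logged.
- ChEMBL-dialect activity rows are kept only from "Single Protein"
  assays with activity types Ki, IC50, Kd, EC50 or Potency, an exact
  `=` relation and units convertible to nM. Qualified values (`>`, `<`)
  are discarded: censored measurements would bias labels near the
  threshold. Potency is treated like IC50 after unit normalization.
- Labels: active iff value ≤ 1000 nM. The boundary is **inclusive**
  (1000 nM is active) and configurable. Replicate rows for one
  (molecule, target) pair are resolved by strict majority; exact ties
  drop the pair, because ambiguous evidence should not seed a
  repurposing claim. Deduplication is per (molecule, target), not per
  molecule: the same ligand may be active on one target and inactive on
  another.

## State enumeration

The query scaffold is not one structure but a state space: tautomer
sites and stereocenters whose combinations are screened independently.
States are declared as a SMILES template with named `{placeholder}`
slots and per-state fragments, and `enumerate_states()` takes the full
Cartesian product in a deterministic order (first site slowest,
stereocenters fastest), canonicalizes every product, and insists all
keys are distinct. Template substitution was chosen over reaction-style
rewrites: it is deterministic, trivially auditable, and sufficient for
Cartesian state spaces; the cost is that each site's chemistry is
spelled out explicitly in the fixture.

The shipped fixture encodes a 3-(pyrazolylmethyl)oxindole scaffold:

- the indolinone ring in lactam ("oxindole", N1H–C2=O) and lactim
  ("hydroxyindole", N1=C2–OH) forms — both keep the C3 methine sp³, so
  the stereocenter survives in every state;
- the pyrazolone ring in five tautomers, named by the protonation of the
  two ring nitrogens and the keto/enol state of the oxygen: the aromatic
  1H-ol (`NH-N-OH`), the 4H-ol (`N-N-OH`), the 2H-ol (`N-NH-OH`), the
  2,4-dihydro-3-one (`N-NH=O`) and the 1,2-dihydro-3-one (`NH-NH=O`);
- both C3 configurations.

5 × 2 × 2 = 20 distinct canonical structures, with aliases
`oxindole_1` … `oxindole_20` attached per the conventional numbering.
The tautomer connectivities are one consistent chemical reading of that
numbering scheme; the alias table in the YAML fixture documents the
mapping. Quantum-mechanical tautomer energetics are out of scope:
`rank_states()` accepts an externally computed energy map (e.g. DFT
single-point energies in kcal/mol) and orders states by it, nothing
more.

## The Gaussian shape engine

Each heavy atom contributes a single Gaussian of amplitude `p = 2√2`
and exponent `α = π (3p / (4π r³))^{2/3}`, the standard choice that
makes an isolated atomic Gaussian integrate to the hard sphere volume
of radius `r` (Bondi radii by element; a radius-uniform mode treats all
heavy atoms as carbon). The pairwise overlap between molecules A and B,

$$ O_{AB} = \sum_{i \in A}\sum_{j \in B} p^2
   \left(\frac{\pi}{\alpha_i+\alpha_j}\right)^{3/2}
   \exp\!\left(-\frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j} d_{ij}^2\right), $$

is the exact integral of the product of the two summed densities — a
first-order approximation that ignores higher-order intersection
corrections; the overestimate largely cancels in the Tanimoto ratio.
`grid_overlap_volume()` integrates the same product numerically and
serves as the test oracle (agreement within 1% on random 1–3 atom
systems).

Colour features are rule-based: donors (N/O bearing H), acceptors (N/O
with a free lone pair), cations/anions (formal charges), hydrophobes
(carbons untouched by heteroatoms, plus heavy halogens) and
aromatic-ring centroids. Each is a unit-weight Gaussian of radius
1.0 Å; only same-type features interact, and colour weight equals shape
weight in the optimization objective. When **neither** molecule has any
feature the colour Tanimoto is defined as 1 (the molecules are
indistinguishable to the colour model), mirroring the both-empty
convention for 2D bitsets; if only one side is featureless it is 0.

**Overlay optimization.** Both molecules are expressed in their
principal-axis frames; the four proper axis-flip combinations give four
starting rotations (three extra fixed-rotation starts are added for
degenerate, e.g. collinear, queries). From each start a Nelder–Mead
simplex over (axis-angle, translation) maximizes the combined
shape + colour overlap, with relative tolerance 1e-4 and at most 300
iterations per start; the best start wins, and the start pose itself is
kept when optimization fails to improve it (this guarantees self-overlay
scores of exactly 1). Scores from this engine are internally consistent
but are **not** expected to match any other shape-overlay software
numerically.

**Conformers.** A deterministic base geometry comes from seeded ETKDG
distance-geometry embedding with MMFF94 relaxation (through a small
Python/RDKit adapter — the only non-R component, chosen because the
embedding must be reproducible bit-for-bit under a seed). Additional
conformers are enumerated by driving every rotatable bond through
staggered offsets (0, ±120°), rejecting candidates with non-bonded
heavy-atom contacts below 1.6 Å, and deduplicating at 0.5 Å heavy-atom
RMSD (Kabsch-aligned). When the torsion grid exceeds the requested
count, a seeded subset is drawn. This sampling is coarser than a
torsion-library search: it will miss correlated ring/backbone motions,
which is acceptable for consensus screening where the 2D filter has
already restricted pairs to close analogs.

Conformer caps default to the screening policy of 5 per query state, 50
per ChEMBL reference, 600 per DrugBank reference and 50 query conformers
against crystallographic PDB ligands (which contribute only their
deposited conformer, in `ref_crystal_vs_query_confs` mode).

## The synthetic corpora

`generate_corpora()` emulates the *statistical structure* of public
database extracts so the full pipeline is testable offline:

- DrugBank dialect: drug-like decoys plus peptide "biologic" entries
  that the type filter must remove;
- PDB dialect: decoy HET groups plus stoplisted solvents and ions, and
  crystal-like SDF conformers for the planted analogs;
- ChEMBL dialect: Single-Protein and non-Single-Protein assays, all
  five retained activity types plus others, `=`/`>`/`<` relations,
  nM and µM units, log-uniform values over [1, 10⁵] nM (straddling the
  1000 nM threshold), duplicate rows and label conflicts at configured
  rates.

Planted signal: analogs of the query scaffold built by single
substituent swaps (aromatic H or lactam N–H → F, Cl, methyl, methoxy) —
high 2D similarity by construction — are assigned to one designated
target with replicated active-range values ([10, 800] nM). The manifest
records every planted fact, and `ground_truth_eval()` scores a pipeline
run against it (planted-target rank, hit precision/recall, contaminant
filtering). Decoys come from a shipped 200-molecule drug-like
vocabulary, so no stage ever downloads anything.

What the generator does **not** emulate: realistic binding-mode
geometry in the mock PDB conformers (they are embedded, not curated),
correlated assay noise, target promiscuity structure, or the sheer
scale of real extracts. Passing the end-to-end test therefore shows the
machinery is correct and deterministic — not that the thresholds would
retrieve the same hit lists from the real October-2020 databases, whose
headline counts depend on those snapshots.

## Problem sizes and determinism

The demonstration scale used by the shipped synthetic runs (and by the
package's end-to-end tests) is 60 decoys per corpus, 8 planted analogs,
6 biologics, 8 solvent/ion records, 12 decoy targets, and conformer
caps of 3 per query state, 8 per reference and 6 query conformers
against PDB crystals — small enough that a full run completes in a few
minutes on one core while exercising every filter. The screening
thresholds themselves are never scaled.

Determinism is end-to-end: one seed drives corpus generation, 3D
embedding, torsion-subset selection and the run snapshot, and two runs
with the same inputs and seed produce byte-identical ranking tables.
Within a run, 3D scores for identical molecule pairs encountered in
several corpora are memoized by canonical-key pair (pure caching; the
scores are unchanged). Every output table carries the parameter
snapshot hash of the configuration it was computed under.

## Known limitations

- Canonicalization joins structures at the stereoisomer level and
  deliberately not at the tautomer level — the enumerated query states
  must stay distinct — so a reference catalogued in a different tautomer
  than its database sibling will not join across corpora.
- No salt stripping or charge standardization beyond canonicalization;
  an optional pre-canonicalization hook is left disabled because the
  upstream curation conventions of the emulated databases are unknown.
- The first-order Gaussian model overestimates absolute volumes;
  Tanimoto ratios are comparable only within this engine.
- The target ranking is a fixed lexicographic heuristic; treat the
  order, not the margins, as the result.
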