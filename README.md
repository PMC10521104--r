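# lbvs — ligand-based virtual screening and target repurposing

`lbvs` implements a ligand-based drug-repurposing workflow for
cheminformaticians who want to ask: *given a query scaffold, which protein
targets are supported by known ligands that look like it?* The package
curates three database-style ligand corpora (DrugBank-, PDB- and
ChEMBL-dialect tables), enumerates the tautomer/stereoisomer states of the
query scaffold, screens every corpus by a five-fingerprint 2D similarity
consensus and a Gaussian-overlap 3D shape filter, joins the surviving hits
across corpora by canonical structure keys, and ranks candidate targets by
the activity profile of their similar ligands.

## The methods at the core

**2D consensus screen.** For each (query state, reference ligand) pair the
package computes five fingerprints — MACCS keys (166 substructure bits,
via OpenBabel's key set), ECFP4, ECFP6, FCFP4 and FCFP6 (hashed circular
fingerprints of diameter 4/6 bonds; the FCFP variants use pharmacophoric
functional-class atom invariants) — and scores each with the Tanimoto
coefficient

```
Tc(A, B) = |A ∩ B| / |A ∪ B|  ∈ [0, 1].
```

A pair passes the 2D screen only if **all five** coefficients reach their
activity-relevant thresholds: Tc_MACCS ≥ 0.7, Tc_ECFP4 ≥ 0.3,
Tc_ECFP6 ≥ 0.4, Tc_FCFP4 ≥ 0.3, Tc_FCFP6 ≥ 0.4.

**3D shape screen.** Molecules are represented as sums of atomic
Gaussians (amplitude `p = 2√2`, exponents set by Bondi van der Waals
radii). After rigid-body overlay optimization (inertial-frame starts over
the four proper axis flips, then a derivative-free simplex over rotation
and translation) the package reports

```
ShapeTanimoto = O_AB / (O_AA + O_BB − O_AB)
ColorTanimoto = the same ratio over matching pharmacophore features
TanimotoCombo = ShapeTanimoto + ColorTanimoto  ∈ [0, 2]
```

with the consensus cut TanimotoCombo ≥ 1.2, taking for every molecule
pair the maximum over conformer pairs (ETKDG-embedded base geometry plus
deterministic staggered torsion sampling).

**Curation and ranking.** ChEMBL-dialect activity rows are reduced to
per-ligand-per-target active/inactive labels: only "Single Protein"
assays with Ki/IC50/Kd/EC50/Potency values, exact ("=") relations and
nM-convertible units are kept; a ligand is *active* at ≤ 1000 nM; replicate
labels are resolved by strict majority (ties dropped). Targets are ranked
lexicographically by (number of corpora with hits, active − inactive count,
total ligand count, active count), so multi-database evidence and potent
inhibitor support come first.

## Worked example

Generate the synthetic corpora (mock DrugBank/PDB/ChEMBL extracts with
biologics, solvents, ions, assay noise and eight planted analogs of the
query scaffold concentrated on one target), run the full pipeline, and
evaluate recovery:

```r
library(lbvs)

generate_corpora(synthetic_config(seed = 1), "corpora")
cfg <- synthetic_pipeline_config("corpora", seed = 1)
out <- run_pipeline(cfg, "run1")
out$ranking
#>   target_id                                   target_name     organism
#> 1    P35968 Vascular endothelial growth factor receptor 2 Homo sapiens
#>   pdb_count db_count chembl_active chembl_inactive n_corpora
#> 1         4        6             8               0         3
#>   active_minus_inactive rank
#> 1                     8    1

ground_truth_eval("run1", "corpora/manifest.json")
#> $planted_target_rank    : 1
#> $precision              : 1
#> $recall                 : 1
#> $contaminant_filter_score: 1
#> $counts_match           : TRUE
```

The planted target is recovered at rank 1: its 4 PDB, 6 DrugBank and
8 active ChEMBL ligands are exactly the planted analogs (every biologic,
solvent and ion contaminant was filtered out), and the cross-corpus join
recognizes the analogs present in all three corpora as single molecules
with best TanimotoCombo scores of 1.67–1.87:

```r
out$cross_corpus_hits[, c("canonical_key", "n_corpora", "best_tanimoto_combo")]
#>                        canonical_key n_corpora best_tanimoto_combo
#> 1 O=C1NN=C(C1)CC1C(=O)Nc2c1cc(Cl)cc2         3            1.872287
#> 2 COc1cc2C(CC3=NNC(=O)C3)C(=O)Nc2cc1         3            1.762161
#> 3  O=C1NN=C(C1)CC1C(=O)Nc2c1cc(F)cc2         3            1.738784
#> 4  O=C1NN=C(C1)CC1C(=O)Nc2c1cc(C)cc2         3            1.674254
```

The query state library itself comes from the shipped oxindole state
space: `enumerate_states(oxindole_state_space())` yields 20 distinct
canonical structures (5 pyrazolone tautomers × 2 indolinone forms ×
2 enantiomers).

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/lbvs-pipeline.R simulate --outdir corpora --seed 1
Rscript inst/scripts/lbvs-pipeline.R run --synthetic corpora --outdir run1
Rscript inst/scripts/lbvs-pipeline.R eval --run run1 --manifest corpora/manifest.json
```

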