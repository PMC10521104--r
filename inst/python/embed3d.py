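"""Deterministic 3D embedding adapter.

Reads a SMILES file (one "SMILES<space>id" per line), builds one 3D
conformer per molecule with the ETKDG distance-geometry method followed
by MMFF94 (fallback UFF) relaxation, and writes a multi-record SDF.
Atom order follows the input SMILES parse order; hydrogens are appended
at the end. Embedding failures are skipped; the record simply does not
appear in the output.

Usage: python embed3d.py input.smi output.sdf seed
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")


def main(inp, outp, seed):
    writer = Chem.SDWriter(outp)
    with open(inp) as fh:
        for line in fh:
            parts = line.split()
            if not parts:
                continue
            smi = parts[0]
            name = parts[1] if len(parts) > 1 else smi
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                continue
            mol = Chem.AddHs(mol)
            params = AllChem.ETKDGv3()
            params.randomSeed = seed
            if AllChem.EmbedMolecule(mol, params) != 0:
                params.useRandomCoords = True
                if AllChem.EmbedMolecule(mol, params) != 0:
                    continue
            try:
                if AllChem.MMFFOptimizeMolecule(mol, maxIters=500) == -1:
                    AllChem.UFFOptimizeMolecule(mol, maxIters=500)
            except Exception:
                try:
                    AllChem.UFFOptimizeMolecule(mol, maxIters=500)
                except Exception:
                    pass
            mol.SetProp("_Name", name)
            writer.write(mol)
    writer.close()


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2], int(sys.argv[3]))
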