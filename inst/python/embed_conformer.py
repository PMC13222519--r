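"""Seeded distance-geometry conformer generation (ETKDG + optional MMFF).

Usage: python embed_conformer.py SMILES SEED OPTIMIZE(0|1)
Prints "SEED_USED <n>" followed by a V2000 molblock on success.
Exit codes: 2 = unparseable SMILES, 3 = embedding failed after retries.
"""
import sys

from rdkit import Chem
from rdkit.Chem import AllChem
from rdkit import RDLogger

RDLogger.DisableLog("rdApp.*")

MAX_ATTEMPTS = 3


def main() -> int:
    smiles, seed, optimize = sys.argv[1], int(sys.argv[2]), sys.argv[3] == "1"
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return 2
    mol = Chem.AddHs(mol)
    seed_used = -1
    for attempt in range(MAX_ATTEMPTS):
        params = AllChem.ETKDGv3()
        params.randomSeed = seed + attempt
        if AllChem.EmbedMolecule(mol, params) == 0:
            seed_used = seed + attempt
            break
    if seed_used < 0:
        return 3
    if optimize:
        try:
            if AllChem.MMFFOptimizeMolecule(mol) != 0:
                AllChem.UFFOptimizeMolecule(mol)
        except Exception:
            AllChem.UFFOptimizeMolecule(mol)
    sys.stdout.write("SEED_USED %d\n" % seed_used)
    sys.stdout.write(Chem.MolToMolBlock(mol))
    return 0


if __name__ == "__main__":
    sys.exit(main())
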