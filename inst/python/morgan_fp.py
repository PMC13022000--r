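"""Compute radius-2 circular (Morgan/ECFP4) fingerprints with RDKit.

Reads a TSV of (id, smiles) on stdin or as argv[1]; writes per-molecule
lines "id<TAB>canonical_smiles<TAB>comma-joined 1-based on-bit indices".
Invalid SMILES produce a line "ERROR<TAB>id<TAB>smiles" and exit code 1
after processing all rows, so the caller can name every offender.
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main() -> int:
    radius = int(sys.argv[2]) if len(sys.argv) > 2 else 2
    nbits = int(sys.argv[3]) if len(sys.argv) > 3 else 2048
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    src = open(sys.argv[1]) if len(sys.argv) > 1 and sys.argv[1] != "-" else sys.stdin
    status = 0
    for line in src:
        line = line.rstrip("\n")
        if not line:
            continue
        mol_id, smiles = line.split("\t", 1)
        mol = Chem.MolFromSmiles(smiles)
        if mol is None:
            print(f"ERROR\t{mol_id}\t{smiles}")
            status = 1
            continue
        fp = gen.GetFingerprint(mol)
        bits = ",".join(str(b + 1) for b in fp.GetOnBits())
        print(f"{mol_id}\t{Chem.MolToSmiles(mol)}\t{bits}")
    return status


if __name__ == "__main__":
    sys.exit(main())
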