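"""Compute the RDKit 2D descriptor panel for a list of SMILES.

Usage: python rdkit_panel.py <smiles.txt> <out.csv>
One SMILES per input line; unparseable lines yield all-empty rows.
"""
import csv
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors

RDLogger.DisableLog("rdApp.*")


def main(fin, fout):
    with open(fin) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    names = [n for n, _ in Descriptors._descList]
    with open(fout, "w", newline="") as fh:
        writer = csv.writer(fh)
        writer.writerow(names)
        for smi in smiles:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                writer.writerow([""] * len(names))
                continue
            vals = Descriptors.CalcMolDescriptors(mol)
            writer.writerow([vals.get(n, "") for n in names])


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
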