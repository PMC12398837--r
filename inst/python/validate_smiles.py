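"""SMILES validity filter for the whalescreen synthetic-library generator.

Reads  SMILES <TAB> id  lines and writes back the ids of entries that
parse and sanitize (valence check included) as a single molecule.
"""

import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")

with open(sys.argv[1]) as fin, open(sys.argv[2], "w") as fout:
    for line in fin:
        parts = line.rstrip("\n").split("\t")
        if len(parts) < 2:
            continue
        mol = Chem.MolFromSmiles(parts[0])
        if mol is not None and len(Chem.GetMolFrags(mol)) == 1:
            fout.write(parts[1] + "\n")
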