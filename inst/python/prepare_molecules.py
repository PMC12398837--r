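"""Batch 3D preparation backend for the whalescreen R package.

Reads a TSV of  SMILES <TAB> id <TAB> seed <TAB> minimize_steps <TAB>
num_confs  lines, and for each molecule: keeps the largest fragment, adds
explicit hydrogens, embeds num_confs conformations with ETKDGv3 under the
given random seed, minimizes them with MMFF94 (falling back to UFF when
MMFF94 lacks parameters for an atom type), keeps the lowest-energy
conformer, and assigns Gasteiger-Marsili partial charges.

Output is a plain-text block stream:
  MOL <id> <n_atoms> <n_bonds> <forcefield>
  A <element> <x> <y> <z> <charge>     (one per atom)
  B <i> <j>                            (one per bond, 1-based)
or, for failures:
  ERR <id> <reason>
"""

import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdPartialCharges

RDLogger.DisableLog("rdApp.*")


def prepare(smiles, seed, steps, num_confs):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparseable SMILES")
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=True)
    if len(frags) > 1:
        mol = max(frags, key=lambda m: m.GetNumAtoms())
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed) % (2**31 - 1)
    cids = list(AllChem.EmbedMultipleConfs(mol, numConfs=int(num_confs),
                                           params=params))
    if not cids:
        # retry budget: random-coordinate fallback under the same seed
        params.useRandomCoords = True
        cids = list(AllChem.EmbedMultipleConfs(mol, numConfs=int(num_confs),
                                               params=params))
        if not cids:
            raise ValueError("3D embedding failed")
    if AllChem.MMFFHasAllMoleculeParams(mol):
        ff = "MMFF94"
        res = AllChem.MMFFOptimizeMoleculeConfs(mol, maxIters=int(steps))
    else:
        ff = "UFF"
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=int(steps))
    # keep the lowest-energy minimized conformer
    energies = [e for _, e in res]
    best = cids[min(range(len(cids)), key=lambda k: energies[k])]
    keep = Chem.Conformer(mol.GetConformer(best))
    keep.SetId(0)
    mol.RemoveAllConformers()
    mol.AddConformer(keep, assignId=True)
    rdPartialCharges.ComputeGasteigerCharges(mol)
    charges = [a.GetDoubleProp("_GasteigerCharge") for a in mol.GetAtoms()]
    if any(math.isnan(q) or math.isinf(q) for q in charges):
        raise ValueError("Gasteiger charge scheme did not converge")
    return mol, charges, ff


def main(inp, out):
    with open(inp) as fin, open(out, "w") as fout:
        for line in fin:
            parts = line.rstrip("\n").split("\t")
            if len(parts) < 3:
                continue
            smiles, mid, seed = parts[0], parts[1], parts[2]
            steps = parts[3] if len(parts) > 3 else "500"
            num_confs = parts[4] if len(parts) > 4 else "1"
            try:
                mol, charges, ff = prepare(smiles, seed, steps, num_confs)
            except Exception as exc:  # reported per molecule, not fatal
                fout.write("ERR\t%s\t%s\n" % (mid, str(exc).replace("\t", " ")))
                continue
            conf = mol.GetConformer()
            fout.write("MOL\t%s\t%d\t%d\t%s\n"
                       % (mid, mol.GetNumAtoms(), mol.GetNumBonds(), ff))
            for atom in mol.GetAtoms():
                pos = conf.GetAtomPosition(atom.GetIdx())
                fout.write("A\t%s\t%.6f\t%.6f\t%.6f\t%.6f\n"
                           % (atom.GetSymbol(), pos.x, pos.y, pos.z,
                              charges[atom.GetIdx()]))
            for bond in mol.GetBonds():
                fout.write("B\t%d\t%d\n" % (bond.GetBeginAtomIdx() + 1,
                                            bond.GetEndAtomIdx() + 1))


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
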