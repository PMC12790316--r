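"""SMILES -> molecular graph + 3D conformer batch helper.

Reads a JSON request on stdin:
    {"molecules": [{"smiles": str, "id": str}, ...],
     "n_confs": int, "seed": int}
and writes a JSON response on stdout:
    {"results": [{"id": str, "ok": bool, "error": str|None,
                  "canonical_smiles": str, "elements": [str],
                  "formal_charges": [int],
                  "bonds": [[i, j, order]],            # 1-based
                  "conformers": [{"coords": [[x,y,z]], "energy_kcal": f}]}]}

Embedding is ETKDGv3 distance geometry with a fixed random seed (fully
deterministic); conformers are relaxed and ranked with UFF. Failed UFF
setups fall back to unrelaxed distance-geometry energies of zero.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

BOND_ORDER = {Chem.BondType.SINGLE: 1, Chem.BondType.DOUBLE: 2,
              Chem.BondType.TRIPLE: 3, Chem.BondType.AROMATIC: 4}


def process(entry, n_confs, seed):
    out = {"id": entry.get("id", "mol"), "ok": False, "error": None}
    mol = Chem.MolFromSmiles(entry["smiles"])
    if mol is None:
        out["error"] = "unparseable SMILES"
        return out
    out["canonical_smiles"] = Chem.MolToSmiles(mol)
    mol = Chem.AddHs(mol)
    if int(n_confs) == 0:  # graph-only request, no embedding
        out["elements"] = [a.GetSymbol() for a in mol.GetAtoms()]
        out["formal_charges"] = [a.GetFormalCharge() for a in mol.GetAtoms()]
        out["bonds"] = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                         BOND_ORDER.get(b.GetBondType(), 1)]
                        for b in mol.GetBonds()]
        out["conformers"] = []
        out["ok"] = True
        return out
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    params.useRandomCoords = False
    conf_ids = list(AllChem.EmbedMultipleConfs(mol, numConfs=int(n_confs),
                                               params=params))
    if not conf_ids:
        # fall back to random-coordinate initialization, still seeded
        params.useRandomCoords = True
        conf_ids = list(AllChem.EmbedMultipleConfs(mol, numConfs=int(n_confs),
                                                   params=params))
    if not conf_ids:
        out["error"] = "3D embedding failed"
        return out
    try:
        res = AllChem.UFFOptimizeMoleculeConfs(mol, maxIters=1000)
        energies = [e for _, e in res]
    except Exception:
        energies = [0.0] * len(conf_ids)
    out["elements"] = [a.GetSymbol() for a in mol.GetAtoms()]
    out["formal_charges"] = [a.GetFormalCharge() for a in mol.GetAtoms()]
    out["bonds"] = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
                     BOND_ORDER.get(b.GetBondType(), 1)]
                    for b in mol.GetBonds()]
    out["conformers"] = [
        {"coords": [list(p) for p in mol.GetConformer(cid).GetPositions()],
         "energy_kcal": energies[k]}
        for k, cid in enumerate(conf_ids)]
    out["ok"] = True
    return out


def main():
    req = json.load(sys.stdin)
    n_confs = req.get("n_confs", 1)
    seed = req.get("seed", 42)
    results = [process(m, n_confs, seed) for m in req["molecules"]]
    json.dump({"results": results}, sys.stdout)


if __name__ == "__main__":
    main()
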