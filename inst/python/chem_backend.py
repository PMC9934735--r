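"""Batch RDKit backend for the gcdiff R package.

Usage: python chem_backend.py <mode> <in.json> <out.json>

Modes:
  sanitize      — build each molecule from explicit atoms + inferred bonds,
                  run RDKit sanitization, return validity and the canonical
                  SMILES of the largest fragment.
  energy_ratio  — UFF energy of the supplied conformation divided by the
                  mean UFF energy of freshly ETKDGv3-embedded conformers of
                  the same molecular graph.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Geometry import Point3D

RDLogger.DisableLog("rdApp.*")

BOND_TYPES = {1: Chem.BondType.SINGLE, 2: Chem.BondType.DOUBLE,
              3: Chem.BondType.TRIPLE}


def build_mol(rec, with_coords=False):
    mol = Chem.RWMol()
    for i, el in enumerate(rec["types"]):
        atom = Chem.Atom(el)
        charges = rec.get("charges") or []
        if i < len(charges) and charges[i]:
            atom.SetFormalCharge(int(charges[i]))
        atom.SetNoImplicit(True)
        mol.AddAtom(atom)
    for b in rec.get("bonds") or []:
        mol.AddBond(int(b[0]), int(b[1]), BOND_TYPES[int(b[2])])
    m = mol.GetMol()
    if with_coords:
        conf = Chem.Conformer(m.GetNumAtoms())
        for i, xyz in enumerate(rec["coords"]):
            conf.SetAtomPosition(i, Point3D(*[float(v) for v in xyz]))
        m.AddConformer(conf, assignId=True)
    return m


def sanitize_one(rec):
    try:
        m = build_mol(rec)
        Chem.SanitizeMol(m)
        frags = Chem.GetMolFrags(m, asMols=True, sanitizeFrags=False)
        largest = max(frags, key=lambda f: f.GetNumAtoms())
        try:
            smiles = Chem.MolToSmiles(Chem.RemoveHs(largest))
        except Exception:
            smiles = Chem.MolToSmiles(largest)
        return {"valid": True, "smiles": smiles}
    except Exception as exc:  # sanitization failure == invalid molecule
        return {"valid": False, "smiles": None, "reason": str(exc)}


def energy_ratio_one(rec):
    try:
        m = build_mol(rec, with_coords=True)
        Chem.SanitizeMol(m)
    except Exception as exc:
        return {"ratio": None, "reason": "sanitization failed: %s" % exc}
    try:
        ff = AllChem.UFFGetMoleculeForceField(m, confId=0)
        e_pose = ff.CalcEnergy()
        params = AllChem.ETKDGv3()
        params.randomSeed = int(rec.get("seed", 0))
        ref = Chem.Mol(m)
        ref.RemoveAllConformers()
        cids = AllChem.EmbedMultipleConfs(ref, int(rec["n_conformers"]),
                                          params)
        if not len(cids):
            return {"ratio": None, "reason": "conformer embedding failed"}
        energies = []
        for cid in cids:
            f = AllChem.UFFGetMoleculeForceField(ref, confId=cid)
            energies.append(f.CalcEnergy())
        mean_e = sum(energies) / len(energies)
        if mean_e == 0:
            return {"ratio": None, "reason": "zero ensemble energy"}
        return {"ratio": e_pose / mean_e, "reason": None}
    except Exception as exc:
        return {"ratio": None, "reason": str(exc)}


def main():
    mode, fin, fout = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(fin) as fh:
        records = json.load(fh)
    fn = {"sanitize": sanitize_one, "energy_ratio": energy_ratio_one}[mode]
    with open(fout, "w") as fh:
        json.dump([fn(rec) for rec in records], fh)


if __name__ == "__main__":
    main()
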