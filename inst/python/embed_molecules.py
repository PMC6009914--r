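"""Batch conformer embedding for qsar3d.

Input is either a JSON array [{"id": ..., "smiles": ...}, ...] for
independent embeddings, or an object

    {"series": [{"id":..., "smiles":...,
                 "constraints": [{"ref": <earlier id>,
                                  "map": [[mol_atom, ref_atom], ...]}]},
                ...]}

for a congeneric series.  Molecules are embedded in order; a molecule
with constraints gets every mapped atom (0-based heavy-atom indices)
coordinate-mapped onto the already-embedded reference molecule's
conformer and position-restrained during minimisation.  Chaining
references (template -> scaffold parent -> member) reproduces how a
shared-scaffold series is sketched from one template for lattice-field
QSAR: one common geometry for every shared fragment, only genuinely new
atoms relax freely.

Every molecule gets one explicit-H 3D conformer (ETKDGv3, fixed random
seed, MMFF94 minimisation falling back to UFF), Gasteiger partial charges
and per-atom pharmacophoric flags.  Output is byte-identical across runs
for a fixed --seed.

With --descriptors the script instead computes 2D screening descriptors
(molecular weight, Wildman-Crippen logP, Ertl TPSA, Lipinski donor/
acceptor counts, strict rotatable bonds, primary-sulfonamide flag) for a
JSON array of {"id", "smiles"} records.

Usage: python embed_molecules.py [--descriptors] --seed 1 in.json out.json
"""

import argparse
import json
import math
import sys

from rdkit import Chem, Geometry, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, Lipinski, rdMolAlign
from rdkit.Chem import rdMolDescriptors

RDLogger.DisableLog("rdApp.*")

# Donor: N or O carrying at least one hydrogen.
DONOR = Chem.MolFromSmarts("[#7,#8;!H0]")
# Acceptor: any O; N with an available lone pair -- excludes quaternary N,
# amide/sulfonamide N and trisubstituted aromatic N (pyrrole/pyrazole N1).
ACCEPTOR = Chem.MolFromSmarts(
    "[$([#8]),$([#7;!X4;!$([#7][C,S]=[O,S,N]);!$([#7]S=O);!$([nX3])])]"
)


def _minimise(molh, restrain=None):
    """MMFF94 (UFF fallback) minimisation; `restrain` = atom indices held
    by stiff position restraints."""
    try:
        props = AllChem.MMFFGetMoleculeProperties(molh)
        ff = AllChem.MMFFGetMoleculeForceField(molh, props) if props else None
    except Exception:
        ff = None
    if ff is None:
        try:
            ff = AllChem.UFFGetMoleculeForceField(molh)
        except Exception:
            return
    if restrain:
        for idx in restrain:
            ff.MMFFAddPositionConstraint(idx, 0.0, 1.0e4) \
                if hasattr(ff, "MMFFAddPositionConstraint") \
                else ff.UFFAddPositionConstraint(idx, 0.0, 1.0e4)
    ff.Initialize()
    ff.Minimize(maxIts=2000)


def embed_one(rec, seed, refs=None):
    smiles = rec["smiles"]
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"id": rec["id"], "smiles": smiles, "ok": False,
                "error": "unparsable SMILES"}
    n_heavy = mol.GetNumAtoms()
    donors = {a[0] for a in mol.GetSubstructMatches(DONOR)}
    acceptors = {a[0] for a in mol.GetSubstructMatches(ACCEPTOR)}
    molh = Chem.AddHs(mol)
    constraints = rec.get("constraints") or []
    coord_map = {}
    for con in constraints:
        ref = (refs or {}).get(con["ref"])
        if ref is None:
            return {"id": rec["id"], "smiles": smiles, "ok": False,
                    "error": "constraint references unembedded molecule %r"
                             % con["ref"]}
        rconf = ref.GetConformer()
        for mi, ti in con["map"]:
            p = rconf.GetAtomPosition(int(ti))
            coord_map[int(mi)] = Geometry.Point3D(p.x, p.y, p.z)
    if coord_map:
        ok = AllChem.EmbedMolecule(molh, coordMap=coord_map, randomSeed=int(seed),
                                   useBasicKnowledge=True) == 0
        if not ok:
            # distance-geometry cannot always honour a large coordinate
            # map; fall back to a free seeded embed, place the mapped
            # atoms at their target coordinates directly and let the
            # restrained minimisation relax the remaining atoms around
            # the fixed fragment geometry.
            params = AllChem.ETKDGv3()
            params.randomSeed = int(seed)
            if AllChem.EmbedMolecule(molh, params) != 0:
                params.useRandomCoords = True
                if AllChem.EmbedMolecule(molh, params) != 0:
                    return {"id": rec["id"], "smiles": smiles, "ok": False,
                            "error": "constrained 3D embedding failed"}
        # snap the mapped atoms onto their exact target coordinates --
        # embedding only honours the coordinate map approximately -- and
        # relax the remaining atoms around the frozen shared fragment,
        # so the conformer lands exactly in the series frame.
        conf = molh.GetConformer()
        for mi, pos in coord_map.items():
            conf.SetAtomPosition(mi, pos)
        _minimise(molh, restrain=sorted(coord_map))
        for mi, pos in coord_map.items():
            conf.SetAtomPosition(mi, pos)
        _minimise(molh, restrain=sorted(coord_map))
    else:
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed)
        if AllChem.EmbedMolecule(molh, params) != 0:
            params.useRandomCoords = True
            if AllChem.EmbedMolecule(molh, params) != 0:
                return {"id": rec["id"], "smiles": smiles, "ok": False,
                        "error": "3D embedding failed"}
        try:
            status = AllChem.MMFFOptimizeMolecule(molh, maxIters=2000)
            if status == -1:  # MMFF setup failure -> UFF
                AllChem.UFFOptimizeMolecule(molh, maxIters=2000)
        except Exception:
            AllChem.UFFOptimizeMolecule(molh, maxIters=2000)
    AllChem.ComputeGasteigerCharges(molh)
    conf = molh.GetConformer()
    element, xs, ys, zs, charge, aromatic, hbd, hba = ([] for _ in range(8))
    for atom in molh.GetAtoms():
        idx = atom.GetIdx()
        pos = conf.GetAtomPosition(idx)
        q = float(atom.GetProp("_GasteigerCharge"))
        if math.isnan(q) or math.isinf(q):
            q = 0.0
        element.append(atom.GetSymbol())
        xs.append(round(pos.x, 6))
        ys.append(round(pos.y, 6))
        zs.append(round(pos.z, 6))
        charge.append(round(q, 6))
        aromatic.append(1 if atom.GetIsAromatic() else 0)
        hbd.append(1 if idx in donors else 0)
        hba.append(1 if idx in acceptors else 0)
    bi, bj, border = [], [], []
    for bond in molh.GetBonds():
        bi.append(bond.GetBeginAtomIdx() + 1)  # 1-based for R
        bj.append(bond.GetEndAtomIdx() + 1)
        border.append(bond.GetBondTypeAsDouble())
    return {
        "id": rec["id"], "smiles": smiles, "ok": True,
        "n_heavy": n_heavy,
        "net_charge": Chem.GetFormalCharge(molh),
        "atoms": {"element": element, "x": xs, "y": ys, "z": zs,
                  "charge": charge, "aromatic": aromatic,
                  "hbd": hbd, "hba": hba},
        "bonds": {"i": bi, "j": bj, "order": border},
    }


PRIMARY_SULFONAMIDE = Chem.MolFromSmarts("[SX4](=[OX1])(=[OX1])[NX3;H2]")


def describe_one(rec):
    mol = Chem.MolFromSmiles(rec["smiles"])
    if mol is None:
        return {"id": rec["id"], "smiles": rec["smiles"], "ok": False,
                "error": "unparsable SMILES"}
    return {
        "id": rec["id"], "smiles": rec["smiles"], "ok": True,
        "mw": round(Descriptors.MolWt(mol), 4),
        "logp": round(Crippen.MolLogP(mol), 4),
        "tpsa": round(rdMolDescriptors.CalcTPSA(mol), 2),
        "hbd": Lipinski.NHOHCount(mol),
        "hba": Lipinski.NOCount(mol),
        "rotatable_bonds": Lipinski.NumRotatableBonds(mol),
        "primary_sulfonamide": mol.HasSubstructMatch(PRIMARY_SULFONAMIDE),
    }


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--seed", type=int, default=1)
    ap.add_argument("--descriptors", action="store_true")
    ap.add_argument("infile")
    ap.add_argument("outfile")
    args = ap.parse_args()
    with open(args.infile) as fh:
        payload = json.load(fh)
    if args.descriptors:
        out = [describe_one(rec) for rec in payload]
        with open(args.outfile, "w") as fh:
            json.dump(out, fh)
        return 0
    if isinstance(payload, dict):
        refs = {}
        out = []
        for rec in payload["series"]:
            if "fixed_atoms" in rec:
                # already-embedded reference supplied by the caller: just
                # register its geometry for downstream constraints
                rmol = Chem.AddHs(Chem.MolFromSmiles(rec["smiles"]))
                fa = rec["fixed_atoms"]
                conf = Chem.Conformer(rmol.GetNumAtoms())
                for i in range(rmol.GetNumAtoms()):
                    conf.SetAtomPosition(
                        i, Geometry.Point3D(fa["x"][i], fa["y"][i], fa["z"][i]))
                rmol.AddConformer(conf)
                refs[rec["id"]] = rmol
                continue
            res = embed_one(rec, args.seed, refs)
            out.append(res)
            if res["ok"]:
                rmol = Chem.AddHs(Chem.MolFromSmiles(rec["smiles"]))
                conf = Chem.Conformer(rmol.GetNumAtoms())
                at = res["atoms"]
                for i in range(rmol.GetNumAtoms()):
                    conf.SetAtomPosition(
                        i, Geometry.Point3D(at["x"][i], at["y"][i], at["z"][i]))
                rmol.AddConformer(conf)
                refs[rec["id"]] = rmol
    else:
        out = [embed_one(rec, args.seed) for rec in payload]
    with open(args.outfile, "w") as fh:
        json.dump(out, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main())
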