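"""Batched RDKit worker for the polytag R package.

Reads one JSON object {"ops": [...]} on stdin, writes a JSON list of
per-op results on stdout.  Each op is a dict with an "op" key; anything
unexpected yields {"ok": false, "error": ...} for that op only, so one
bad molecule never kills a batch.

All atom indices exchanged with R are 0-based and refer to the atom
order of the *canonical* SMILES re-parse (mol_info returns that SMILES;
edit ops re-parse it, so indices always line up).
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

BOND_ORDERS = {
    1: Chem.BondType.SINGLE,
    2: Chem.BondType.DOUBLE,
    3: Chem.BondType.TRIPLE,
}


def canonical_mol(smiles):
    """Parse, sanitize and renumber so indices follow canonical SMILES order."""
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None, None
    cs = Chem.MolToSmiles(mol)
    mol2 = Chem.MolFromSmiles(cs)
    if mol2 is None:  # paranoid; canonical SMILES should re-parse
        return None, None
    return mol2, cs


def op_mol_info(op):
    mol, cs = canonical_mol(op["smiles"])
    if mol is None:
        return {"ok": False, "error": "SMILES parse/sanitization failed: %r" % op["smiles"]}
    ri = mol.GetRingInfo()
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "symbol": a.GetSymbol(),
            "atomic_num": a.GetAtomicNum(),
            "charge": a.GetFormalCharge(),
            "n_h": a.GetTotalNumHs(),
            "in_ring": a.IsInRing(),
            "aromatic": a.GetIsAromatic(),
            "heavy_degree": sum(1 for nb in a.GetNeighbors() if nb.GetAtomicNum() > 1),
            "min_ring_size": min((len(r) for r in ri.AtomRings() if a.GetIdx() in r), default=0),
            "n_rings": sum(1 for r in ri.AtomRings() if a.GetIdx() in r),
            "radical_electrons": a.GetNumRadicalElectrons(),
        })
    bonds = [{
        "begin": b.GetBeginAtomIdx(),
        "end": b.GetEndAtomIdx(),
        "order": int(b.GetBondTypeAsDouble()),
        "aromatic": b.GetIsAromatic(),
        "in_ring": b.IsInRing(),
    } for b in mol.GetBonds()]
    patterns = op.get("patterns") or {}
    if not isinstance(patterns, dict):  # empty R named vector serializes as []
        patterns = {}
    matches = {}
    for name, smarts in patterns.items():
        patt = Chem.MolFromSmarts(smarts)
        if patt is None:
            return {"ok": False, "error": "SMARTS failed to compile: %r (%s)" % (smarts, name)}
        hits = mol.GetSubstructMatches(patt, uniquify=True)
        # dedupe by sorted atom set, keep first occurrence order
        seen, kept = set(), []
        for h in hits:
            key = tuple(sorted(h))
            if key not in seen:
                seen.add(key)
                kept.append(list(h))
        matches[name] = kept
    n_el = sum(a.GetAtomicNum() + a.GetTotalNumHs() for a in mol.GetAtoms()) \
        - Chem.GetFormalCharge(mol)
    return {
        "ok": True,
        "canonical_smiles": cs,
        "atoms": atoms,
        "bonds": bonds,
        "matches": matches,
        "n_heavy": mol.GetNumHeavyAtoms(),
        "net_charge": Chem.GetFormalCharge(mol),
        "n_electrons": n_el,
        "n_radical_electrons": sum(a.GetNumRadicalElectrons() for a in mol.GetAtoms()),
    }


def op_fingerprint(op):
    out = []
    for smi in op["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            out.append(None)
        else:
            fp = Chem.RDKFingerprint(mol)
            out.append({"n_bits": fp.GetNumBits(), "on_bits": list(fp.GetOnBits())})
    return {"ok": True, "fingerprints": out}


def op_embed(op):
    mol, cs = canonical_mol(op["smiles"])
    if mol is None:
        return {"ok": False, "error": "SMILES parse failed: %r" % op["smiles"]}
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(op.get("seed", 42))
    params.useRandomCoords = False
    conf_id = AllChem.EmbedMolecule(molh, params)
    if conf_id < 0:  # retry with random coords, same seed family
        params.useRandomCoords = True
        conf_id = AllChem.EmbedMolecule(molh, params)
    if conf_id < 0:
        return {"ok": False, "error": "3D embedding failed for %r" % op["smiles"]}
    AllChem.UFFOptimizeMolecule(molh, maxIters=int(op.get("max_iters", 5000)))
    conf = molh.GetConformer()
    coords = [[conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y,
               conf.GetAtomPosition(i).z] for i in range(molh.GetNumAtoms())]
    symbols = [a.GetSymbol() for a in molh.GetAtoms()]
    # heavy atoms of molh keep the indices of the canonical-order parse
    return {"ok": True, "canonical_smiles": cs, "symbols": symbols,
            "coordinates": coords,
            "heavy_indices": [a.GetIdx() for a in molh.GetAtoms()
                              if a.GetAtomicNum() > 1]}


def op_edit(op):
    """Apply graph edits to the canonical-order parse of `smiles`.

    Edit vocabulary (indices refer to pre-edit canonical order):
      set_bonds:    [[i, j, order], ...]    change bond order
      remove_bonds: [[i, j], ...]           delete bond
      remove_atoms: [i, ...]                delete atom (and its implicit Hs)
      add_tags:     [[i, mapnum], ...]      bond a new [*:mapnum] to atom i
    Implicit hydrogen counts re-derive during sanitization, which is what
    drops an H from a heteroatom that gains a tag bond and checks valence.
    """
    mol, _cs = canonical_mol(op["smiles"])
    if mol is None:
        return {"ok": False, "valid": False,
                "error": "SMILES parse failed: %r" % op["smiles"]}
    rw = Chem.RWMol(mol)
    try:
        for (i, j, order) in op.get("set_bonds", []):
            b = rw.GetBondBetweenAtoms(int(i), int(j))
            if b is None:
                raise ValueError("no bond %d-%d to modify" % (i, j))
            b.SetBondType(BOND_ORDERS[int(order)])
            b.SetIsAromatic(False)
        for (i, j) in op.get("remove_bonds", []):
            if rw.GetBondBetweenAtoms(int(i), int(j)) is None:
                raise ValueError("no bond %d-%d to remove" % (i, j))
            rw.RemoveBond(int(i), int(j))
        for (i, mapnum) in op.get("add_tags", []):
            rw.GetAtomWithIdx(int(i)).SetIntProp("_polytag_map", int(mapnum))
        for i in sorted(set(int(i) for i in op.get("remove_atoms", [])),
                        reverse=True):
            rw.RemoveAtom(i)
        for atom in list(rw.GetAtoms()):
            if atom.HasProp("_polytag_map"):
                mapnum = atom.GetIntProp("_polytag_map")
                atom.ClearProp("_polytag_map")
                star = Chem.Atom(0)
                star.SetAtomMapNum(mapnum)
                star_idx = rw.AddAtom(star)
                rw.AddBond(atom.GetIdx(), star_idx, Chem.BondType.SINGLE)
        edited = rw.GetMol()
        Chem.SanitizeMol(edited)
        tagged = Chem.MolToSmiles(edited)
        return {"ok": True, "valid": True, "tagged_smiles": tagged,
                "n_heavy": sum(1 for a in edited.GetAtoms()
                               if a.GetAtomicNum() > 1)}
    except Exception as exc:  # sanitization/valence failures are data, not crashes
        return {"ok": True, "valid": False, "error": str(exc)}


def op_canonicalize(op):
    out = []
    for smi in op["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        out.append(None if mol is None else Chem.MolToSmiles(mol))
    return {"ok": True, "canonical": out}


HANDLERS = {
    "mol_info": op_mol_info,
    "fingerprint": op_fingerprint,
    "embed": op_embed,
    "edit": op_edit,
    "canonicalize": op_canonicalize,
}


def main():
    req = json.load(sys.stdin)
    results = []
    for op in req.get("ops", []):
        handler = HANDLERS.get(op.get("op"))
        if handler is None:
            results.append({"ok": False, "error": "unknown op %r" % op.get("op")})
            continue
        try:
            results.append(handler(op))
        except Exception as exc:
            results.append({"ok": False, "error": str(exc)})
    json.dump(results, sys.stdout)


if __name__ == "__main__":
    main()
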