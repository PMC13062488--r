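"""Batch chemistry backend for the hypermol R package.

Reads one JSON request on stdin and writes one JSON response on stdout.
All heavy-atom indices in the response are 0-based (RDKit order, which
follows the order atoms appear in the input SMILES).

Request:
  {
    "smiles":   [ "...", ... ],
    "patterns": { "<set name>": [ {"name": ..., "smarts": ...}, ... ], ... },
    "scaffold": true/false
  }

Response:
  {
    "pattern_errors": { "<set name>": [ names that failed to compile ] },
    "molecules": [ { ...per molecule... } | {"error": "..."} ]
  }
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

BOND_ORDER = {
    Chem.BondType.SINGLE: "single",
    Chem.BondType.DOUBLE: "double",
    Chem.BondType.TRIPLE: "triple",
    Chem.BondType.AROMATIC: "aromatic",
}


def compile_patterns(sets):
    compiled = {}
    errors = {}
    for set_name, entries in sets.items():
        out = []
        bad = []
        for entry in entries:
            patt = Chem.MolFromSmarts(entry["smarts"])
            if patt is None:
                bad.append(entry["name"])
            else:
                out.append((entry["name"], patt))
        compiled[set_name] = out
        errors[set_name] = bad
    return compiled, errors


def unique_matches(mol, patt):
    """Distinct matched atom sets, each sorted, list sorted lexicographically."""
    seen = set()
    out = []
    for match in mol.GetSubstructMatches(patt, uniquify=True, maxMatches=10000):
        key = tuple(sorted(match))
        if key not in seen:
            seen.add(key)
            out.append(list(key))
    out.sort()
    return out


def describe(smiles, compiled, want_scaffold):
    if not isinstance(smiles, str):
        return {"error": "not a string", "smiles": ""}
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return {"error": "unparseable SMILES", "smiles": smiles}
    AllChem.ComputeGasteigerCharges(mol)

    atoms = {
        "symbol": [], "z": [], "degree": [], "formal_charge": [],
        "aromatic": [], "in_ring": [], "num_h": [], "radicals": [],
        "gasteiger": [],
    }
    for atom in mol.GetAtoms():
        atoms["symbol"].append(atom.GetSymbol())
        atoms["z"].append(atom.GetAtomicNum())
        atoms["degree"].append(atom.GetDegree())
        atoms["formal_charge"].append(atom.GetFormalCharge())
        atoms["aromatic"].append(bool(atom.GetIsAromatic()))
        atoms["in_ring"].append(bool(atom.IsInRing()))
        atoms["num_h"].append(atom.GetTotalNumHs())
        atoms["radicals"].append(atom.GetNumRadicalElectrons())
        charge = atom.GetDoubleProp("_GasteigerCharge")
        atoms["gasteiger"].append(charge if math.isfinite(charge) else None)

    bonds = [
        [b.GetBeginAtomIdx(), b.GetEndAtomIdx(),
         BOND_ORDER.get(b.GetBondType(), "single")]
        for b in mol.GetBonds()
    ]

    ring_info = mol.GetRingInfo()
    rings = [sorted(r) for r in ring_info.AtomRings()]

    out = {
        "smiles": smiles,
        "canonical_smiles": Chem.MolToSmiles(mol),
        "num_atoms": mol.GetNumAtoms(),
        "atoms": atoms,
        "bonds": bonds,
        "rings": rings,
        "mw": Descriptors.MolWt(mol),
        "logp": Crippen.MolLogP(mol),
        "tpsa": Descriptors.TPSA(mol),
        "matches": {
            set_name: {name: unique_matches(mol, patt) for name, patt in patts}
            for set_name, patts in compiled.items()
        },
    }
    if want_scaffold:
        try:
            out["scaffold"] = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
        except Exception:
            out["scaffold"] = ""
    return out


def main():
    request = json.load(sys.stdin)
    compiled, pattern_errors = compile_patterns(request.get("patterns", {}))
    want_scaffold = bool(request.get("scaffold", False))
    molecules = [
        describe(s, compiled, want_scaffold)
        for s in request.get("smiles", [])
    ]
    json.dump({"pattern_errors": pattern_errors, "molecules": molecules},
              sys.stdout)


if __name__ == "__main__":
    main()
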