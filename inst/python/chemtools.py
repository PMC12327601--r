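#!/usr/bin/env python
"""Batched cheminformatics backend.

Reads one JSON request object on stdin, writes one JSON response on stdout.
All structure-aware operations of the R package funnel through here so that
a single RDKit process handles an entire batch.

Request:  {"op": <name>, ...op-specific fields...}
Response: {"ok": true, ...} or {"ok": false, "error": <message>}
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors
from rdkit.Chem import rdFMCS

RDLogger.DisableLog("rdApp.*")


def _mol(smiles):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles)


def op_validate(req):
    """SMILES validity, canonical form, monoisotopic mass, heavy atom count."""
    ok, canonical, mass, natoms = [], [], [], []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            ok.append(False)
            canonical.append(None)
            mass.append(None)
            natoms.append(None)
        else:
            ok.append(True)
            canonical.append(Chem.MolToSmiles(m))
            mass.append(rdMolDescriptors.CalcExactMolWt(m))
            natoms.append(m.GetNumAtoms())
    return {"valid": ok, "canonical": canonical, "mass": mass,
            "n_atoms": natoms}


def op_match(req):
    """Substructure matrix: rows = structures, cols = SMARTS patterns."""
    pats = []
    pat_ok = []
    for s in req["smarts"]:
        p = Chem.MolFromSmarts(s)
        pats.append(p)
        pat_ok.append(p is not None)
    rows = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            rows.append([None] * len(pats))
            continue
        rows.append([bool(m.HasSubstructMatch(p)) if p is not None else None
                     for p in pats])
    return {"matrix": rows, "pattern_ok": pat_ok}


def op_validate_rxn(req):
    """Check reaction SMARTS parse and count reactant templates."""
    ok, n_react = [], []
    for s in req["smarts"]:
        try:
            rxn = AllChem.ReactionFromSmarts(s)
        except Exception:
            rxn = None
        if rxn is None:
            ok.append(False)
            n_react.append(None)
        else:
            ok.append(True)
            n_react.append(rxn.GetNumReactantTemplates())
    return {"valid": ok, "n_reactants": n_react}


def _run_rule(smiles, rxn_smarts):
    m = _mol(smiles)
    if m is None:
        return None, "unparseable substrate SMILES"
    try:
        rxn = AllChem.ReactionFromSmarts(rxn_smarts)
    except Exception as exc:
        return None, "unparseable reaction SMARTS: %s" % exc
    if rxn is None:
        return None, "unparseable reaction SMARTS"
    if rxn.GetNumReactantTemplates() != 1:
        return None, "rule is not single-substrate"
    products = []
    for prod_set in rxn.RunReactants((m,)):
        for p in prod_set:
            try:
                Chem.SanitizeMol(p)
            except Exception:
                continue
            products.append(p)
    return products, None


def op_apply_rule(req):
    """Apply one single-reactant reaction SMARTS to each substrate.

    Returns canonical, deduplicated product SMILES with monoisotopic masses.
    """
    out = []
    for smi in req["smiles"]:
        products, err = _run_rule(smi, req["rxn_smarts"])
        if products is None:
            out.append({"error": err, "products": [], "masses": []})
            continue
        seen = {}
        for p in products:
            can = Chem.MolToSmiles(p)
            if can not in seen:
                seen[can] = rdMolDescriptors.CalcExactMolWt(p)
        out.append({"error": None,
                    "products": list(seen.keys()),
                    "masses": [seen[k] for k in seen]})
    return {"results": out}


def _template_changed_mapnos(rxn):
    """Map numbers whose bonding environment differs between the reactant
    and product templates of a mapped single-reactant reaction."""
    react = rxn.GetReactantTemplate(0)

    def env(tmpl):
        by_map = {}
        for at in tmpl.GetAtoms():
            if at.GetAtomMapNum():
                by_map[at.GetAtomMapNum()] = at
        info = {}
        for mapno, at in by_map.items():
            bonds = []
            unmapped_nbrs = 0
            for nb in at.GetNeighbors():
                if nb.GetAtomMapNum():
                    b = tmpl.GetBondBetweenAtoms(at.GetIdx(), nb.GetIdx())
                    bonds.append((nb.GetAtomMapNum(), str(b.GetBondType())))
                else:
                    unmapped_nbrs += 1
            info[mapno] = (frozenset(bonds), unmapped_nbrs,
                           at.GetFormalCharge())
        return info

    r_env = env(react)
    p_env = {}
    for i in range(rxn.GetNumProductTemplates()):
        p_env.update(env(rxn.GetProductTemplate(i)))

    changed = set()
    for mapno, e in r_env.items():
        if mapno not in p_env or p_env[mapno] != e:
            changed.add(mapno)
    if not changed:
        # conservative fallback: every mapped atom
        changed = set(r_env.keys())
    return changed


def op_reaction_center(req):
    """Substrate atom indices whose bonding changes in substrate -> product.

    Primary route: the rule's own atom-mapped template; the product of
    RunReactants matching the given product identifies which substrate atoms
    the template consumed (react_atom_idx). Fallback: maximum common
    substructure difference.
    """
    sub = _mol(req["substrate"])
    prod = _mol(req["product"])
    if sub is None or prod is None:
        return {"error": "unparseable SMILES", "atoms": None, "method": None}
    can_prod = Chem.MolToSmiles(prod)
    if Chem.MolToSmiles(sub) == can_prod:
        return {"error": "empty center: substrate equals product",
                "atoms": None, "method": None}

    rxn_smarts = req.get("rxn_smarts")
    if rxn_smarts:
        try:
            rxn = AllChem.ReactionFromSmarts(rxn_smarts)
        except Exception:
            rxn = None
        if rxn is not None and rxn.GetNumReactantTemplates() == 1:
            changed = _template_changed_mapnos(rxn)
            for prod_set in rxn.RunReactants((sub,)):
                for p in prod_set:
                    try:
                        Chem.SanitizeMol(p)
                    except Exception:
                        continue
                    if Chem.MolToSmiles(p) != can_prod:
                        continue
                    atoms = set()
                    for at in p.GetAtoms():
                        mapno = at.GetPropsAsDict().get("old_mapno")
                        ridx = at.GetPropsAsDict().get("react_atom_idx")
                        if mapno in changed and ridx is not None:
                            atoms.add(int(ridx))
                    if atoms:
                        return {"error": None, "atoms": sorted(atoms),
                                "method": "template"}

    # MCS fallback
    res = rdFMCS.FindMCS([sub, prod], timeout=10)
    atoms = set()
    if res.smartsString:
        patt = Chem.MolFromSmarts(res.smartsString)
        ms = sub.GetSubstructMatch(patt)
        mp = prod.GetSubstructMatch(patt)
        in_sub = set(ms)
        # substrate atoms lost in the product, plus their attachment atoms
        for at in sub.GetAtoms():
            if at.GetIdx() not in in_sub:
                atoms.add(at.GetIdx())
                for nb in at.GetNeighbors():
                    atoms.add(nb.GetIdx())
        # atoms gained in the product map back through their MCS neighbours
        pos_of = {pi: i for i, pi in enumerate(mp)}
        in_prod = set(mp)
        for at in prod.GetAtoms():
            if at.GetIdx() not in in_prod:
                for nb in at.GetNeighbors():
                    if nb.GetIdx() in pos_of:
                        atoms.add(ms[pos_of[nb.GetIdx()]])
    if not atoms:
        return {"error": "empty center", "atoms": None, "method": None}
    return {"error": None, "atoms": sorted(atoms), "method": "mcs"}


def op_atom_scores(req):
    """Heuristic per-heavy-atom scores for pipeline testing only:
    'degree' = degree / max degree; 'uniform' = 0.5 everywhere."""
    out = []
    for smi in req["smiles"]:
        m = _mol(smi)
        if m is None:
            out.append(None)
            continue
        if req.get("method", "degree") == "uniform":
            out.append([0.5] * m.GetNumAtoms())
        else:
            degs = [a.GetDegree() for a in m.GetAtoms()]
            mx = max(degs) if degs else 1
            out.append([d / mx for d in degs])
    return {"scores": out}


OPS = {
    "validate": op_validate,
    "match": op_match,
    "validate_rxn": op_validate_rxn,
    "apply_rule": op_apply_rule,
    "reaction_center": op_reaction_center,
    "atom_scores": op_atom_scores,
}


def main():
    req = json.load(sys.stdin)
    op = req.get("op")
    if op not in OPS:
        json.dump({"ok": False, "error": "unknown op: %r" % op}, sys.stdout)
        return
    try:
        res = OPS[op](req)
    except Exception as exc:  # surface, don't crash the R session
        json.dump({"ok": False, "error": str(exc)}, sys.stdout)
        return
    res["ok"] = True
    json.dump(res, sys.stdout)


if __name__ == "__main__":
    main()
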