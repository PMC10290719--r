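"""Chemistry engine for the kinprof R package.

Invoked as:  python chem_bridge.py <op> <in.json> <out.json>

Thin, stateless batch worker around RDKit.  All scientific policy
(descriptor registry membership, signature-space layout, averaging rules)
lives on the R side; this script only evaluates standard toolkit
primitives and reports per-molecule errors instead of aborting the batch.
"""

import json
import math
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, MACCSkeys
from rdkit.Chem import rdFingerprintGenerator, rdDistGeom

RDLogger.DisableLog("rdApp.*")

MORGAN_WIDTHS = {2: 256, 3: 512, 4: 1024}


def _smiles_list(payload):
    smi = payload["smiles"]
    return [smi] if isinstance(smi, str) else smi


def _mol(smiles):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles)


def op_canonicalize(payload):
    out = []
    for smi in _smiles_list(payload):
        m = _mol(smi)
        if m is None:
            out.append({"input": smi, "canonical": None,
                        "error": "unparseable SMILES"})
        else:
            out.append({"input": smi,
                        "canonical": Chem.MolToSmiles(m),  # isomeric by default
                        "error": None})
    return {"molecules": out}


def op_descriptor_names(_payload):
    return {"names": [name for name, _ in Descriptors._descList]}


def op_descriptors_2d(payload):
    registry = payload["registry"]
    funcs = dict(Descriptors._descList)
    missing = [n for n in registry if n not in funcs]
    if missing:
        raise ValueError("unknown descriptors in registry: %s" % missing)
    gens = {r: rdFingerprintGenerator.GetMorganGenerator(radius=r, fpSize=w)
            for r, w in MORGAN_WIDTHS.items()}
    out = []
    for smi in _smiles_list(payload):
        m = _mol(smi)
        if m is None:
            out.append({"input": smi, "error": "unparseable SMILES"})
            continue
        pcpp, nonfinite = [], []
        for name in registry:
            try:
                v = float(funcs[name](m))
            except Exception:
                v = float("nan")
            if not math.isfinite(v):
                nonfinite.append(name)
                v = 0.0
            pcpp.append(v)
        maccs = [int(b) for b in MACCSkeys.GenMACCSKeys(m).ToBitString()]
        morgan = []
        for r in sorted(MORGAN_WIDTHS):
            morgan.extend(int(b) for b in gens[r].GetFingerprint(m).ToBitString())
        out.append({"input": smi,
                    "canonical": Chem.MolToSmiles(m),
                    "error": None,
                    "pcpp": pcpp,
                    "nonfinite": nonfinite,
                    "maccs": maccs,
                    "morgan": morgan})
    return {"molecules": out}


def _embed_params(seed, prune_rms):
    params = rdDistGeom.ETKDGv3()
    params.randomSeed = int(seed)
    params.pruneRmsThresh = float(prune_rms)
    params.onlyHeavyAtomsForRMS = True
    params.useRandomCoords = False
    return params


def op_conformers(payload):
    max_n = int(payload.get("max_n", 16))
    seed = int(payload.get("seed", 1))
    prune_rms = float(payload.get("prune_rms", 0.5))
    families = payload.get("families", [])
    patt = []
    for fam in families:
        p = Chem.MolFromSmarts(fam["smarts"])
        if p is None:
            raise ValueError("bad SMARTS for family %s: %s"
                             % (fam["family"], fam["smarts"]))
        patt.append((fam["family"], p))
    out = []
    for smi in _smiles_list(payload):
        m = _mol(smi)
        if m is None:
            out.append({"input": smi, "error": "unparseable SMILES"})
            continue
        # perceive feature sites on the heavy-atom graph; indices are stable
        # because AddHs only appends hydrogens
        sites = []  # (family, atom index tuple), deduplicated per family
        seen = set()
        for fam, p in patt:
            for match in m.GetSubstructMatches(p):
                key = (fam, tuple(sorted(match)))
                if key not in seen:
                    seen.add(key)
                    sites.append(key)
        mh = Chem.AddHs(m)
        params = _embed_params(seed, prune_rms)
        cids = rdDistGeom.EmbedMultipleConfs(mh, numConfs=max_n, params=params)
        if len(cids) == 0:  # fall back to random coordinates for hard cases
            params = _embed_params(seed, prune_rms)
            params.useRandomCoords = True
            cids = rdDistGeom.EmbedMultipleConfs(mh, numConfs=max_n,
                                                 params=params)
        if len(cids) == 0:
            out.append({"input": smi, "error": "conformer embedding failed"})
            continue
        n_heavy = m.GetNumAtoms()
        confs = []
        for cid in cids:
            conf = mh.GetConformer(cid)
            coords = [[conf.GetAtomPosition(i).x,
                       conf.GetAtomPosition(i).y,
                       conf.GetAtomPosition(i).z] for i in range(n_heavy)]
            site_rows = []
            for fam, atoms in sites:
                cx = [sum(coords[a][d] for a in atoms) / len(atoms)
                      for d in range(3)]
                site_rows.append({"family": fam, "atoms": list(atoms),
                                  "center": cx})
            confs.append({"coords": coords, "sites": site_rows})
        out.append({"input": smi,
                    "canonical": Chem.MolToSmiles(m),
                    "error": None,
                    "n_atoms": n_heavy,
                    "conformers": confs})
    return {"molecules": out}


OPS = {
    "canonicalize": op_canonicalize,
    "descriptor_names": op_descriptor_names,
    "descriptors_2d": op_descriptors_2d,
    "conformers": op_conformers,
}


def main(argv):
    if len(argv) != 4:
        sys.stderr.write("usage: chem_bridge.py <op> <in.json> <out.json>\n")
        return 2
    op, fin, fout = argv[1], argv[2], argv[3]
    if op not in OPS:
        sys.stderr.write("unknown op: %s\n" % op)
        return 2
    with open(fin) as fh:
        payload = json.load(fh)
    result = OPS[op](payload)
    with open(fout, "w") as fh:
        json.dump(result, fh)
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
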