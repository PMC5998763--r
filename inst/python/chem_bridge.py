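"""Batch cheminformatics bridge for the npmatch R package.

Reads a TSV of (row_id, smiles) on --in, writes a TSV of
(row_id, canonical_smiles, on_bits) on --out, where on_bits is a
space-separated list of 1-based set-bit positions of the hashed path
fingerprint (RDKFingerprint), or empty when the SMILES does not parse.
With --sdf, the input is an SDF file instead and row ids are taken from
the molecule title line (fallback: running index).
"""

import argparse
import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")


def fingerprint_row(mol, fp_size):
    # Implicit-H graph (hydrogens removed), bond-order sensitive path hashing.
    fp = Chem.RDKFingerprint(mol, fpSize=fp_size)
    bits = " ".join(str(b + 1) for b in fp.GetOnBits())
    return Chem.MolToSmiles(mol), bits


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    ap.add_argument("--fp-size", dest="fp_size", type=int, default=1024)
    ap.add_argument("--sdf", action="store_true")
    args = ap.parse_args()

    rows = []
    if args.sdf:
        supplier = Chem.SDMolSupplier(args.infile, sanitize=True)
        for i, mol in enumerate(supplier):
            if mol is None:
                rows.append((f"_mol{i + 1}", "", ""))
                continue
            name = mol.GetProp("_Name").strip() if mol.HasProp("_Name") else ""
            rid = name or f"_mol{i + 1}"
            canon, bits = fingerprint_row(mol, args.fp_size)
            rows.append((rid, canon, bits))
    else:
        with open(args.infile) as fh:
            for line in fh:
                line = line.rstrip("\n")
                if not line:
                    continue
                rid, smi = line.split("\t", 1)
                mol = Chem.MolFromSmiles(smi)
                if mol is None:
                    rows.append((rid, "", ""))
                else:
                    canon, bits = fingerprint_row(mol, args.fp_size)
                    rows.append((rid, canon, bits))

    with open(args.outfile, "w") as fh:
        for rid, canon, bits in rows:
            fh.write(f"{rid}\t{canon}\t{bits}\n")
    return 0


if __name__ == "__main__":
    sys.exit(main())
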