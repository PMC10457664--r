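"""Compute Morgan (ECFP-style circular) fingerprints with RDKit.

Reads SMILES one per line on stdin; writes one 0/1 bitstring per line.
Usage: python morgan_fp.py <radius> <n_bits>
Unparseable SMILES yield the line "ERROR<TAB><smiles>".
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def main():
    radius, n_bits = int(sys.argv[1]), int(sys.argv[2])
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=radius, fpSize=n_bits)
    for line in sys.stdin:
        smi = line.strip()
        if not smi:
            continue
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            sys.stdout.write("ERROR\t%s\n" % smi)
            continue
        fp = gen.GetFingerprint(mol)
        sys.stdout.write(fp.ToBitString() + "\n")


if __name__ == "__main__":
    main()
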