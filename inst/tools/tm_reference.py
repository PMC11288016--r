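#!/usr/bin/env python
"""Independent nearest-neighbor Tm reference.

Reads oligo sequences (one per line) from the input file and writes one
melting temperature per line, computed with Biopython's MeltingTemp using
the unified SantaLucia-1998 NN table (DNA_NN3) and the Owczarzy-2008
divalent salt correction (saltcorr=7). dnac1/dnac2 are chosen so the
duplex-fraction term (dnac1 - dnac2/2) equals CT/4 at the given oligo
concentration.

usage: tm_reference.py in.txt out.txt [Na_mM Mg_mM dNTP_mM oligo_nM]
"""
import sys

from Bio.SeqUtils import MeltingTemp as mt


def main(argv):
    inp, out = argv[1], argv[2]
    na, mg, dntp, ct = 50.0, 1.5, 0.6, 250.0
    if len(argv) > 3:
        na, mg, dntp, ct = map(float, argv[3:7])
    dnac = ct / 2.0
    with open(inp) as fh:
        seqs = [line.strip() for line in fh if line.strip()]
    with open(out, "w") as fh:
        for s in seqs:
            tm = mt.Tm_NN(s, nn_table=mt.DNA_NN3, Na=na, Mg=mg, dNTPs=dntp,
                          dnac1=dnac, dnac2=dnac, saltcorr=7)
            fh.write("%.10f\n" % tm)


if __name__ == "__main__":
    main(sys.argv)
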