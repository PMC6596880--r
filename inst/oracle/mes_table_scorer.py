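#!/usr/bin/env python
"""Independent scorer for MaxEntScan-style splice score tables.

Reads a donor or acceptor table file (consensus/background frequency headers
plus 4^7-entry ratio blocks with explicit position subsets) and scores k-mers
from a file or stdin as log2 likelihood ratios:

    score(x) = sum_cons log2(f_cons(x_p)/b_cons(x_p))
             + sum_blocks sign * log2(ratio_block(x[positions]))

This is a deliberately separate implementation (own parsing, own indexing)
used as a cross-check against the R package.
"""

import argparse
import math
import re
import sys

BASE_INDEX = {"A": 0, "C": 1, "G": 2, "T": 3}
FLOOR = 1e-9


def parse_freqs(line):
    pairs = re.findall(r"([ACGT])=([0-9.eE+-]+)", line)
    if len(pairs) != 4:
        raise ValueError("malformed frequency header: " + line)
    return {b: float(v) for b, v in pairs}


def parse_table(path):
    cons, bgd, blocks = {}, {}, []
    with open(path) as fh:
        lines = fh.read().splitlines()
    if not lines or not lines[0].startswith("#%mes-"):
        raise ValueError(path + ": missing table header")
    for ln in lines[1:]:
        if ln.startswith("#%cons"):
            pos = int(re.search(r"pos=(\d+)", ln).group(1))
            cons[pos] = parse_freqs(ln)
        elif ln.startswith("#%bgd"):
            pos = int(re.search(r"pos=(\d+)", ln).group(1))
            bgd[pos] = parse_freqs(ln)
        elif ln.startswith("#%rest") or ln.startswith("#%block"):
            positions = [int(p) for p in
                         re.search(r"positions=([0-9,]+)", ln).group(1).split(",")]
            sign = -1 if "sign=-1" in ln else 1
            blocks.append({"positions": positions, "sign": sign, "values": []})
        elif ln.strip():
            if not blocks:
                raise ValueError(path + ": values before any block header")
            blocks[-1]["values"].append(float(ln))
    for blk in blocks:
        expected = 4 ** len(blk["positions"])
        if len(blk["values"]) != expected:
            raise ValueError("%s: block has %d values, expected %d"
                             % (path, len(blk["values"]), expected))
    return cons, bgd, blocks


def score_kmer(kmer, cons, bgd, blocks):
    kmer = kmer.upper()
    if any(c not in BASE_INDEX for c in kmer):
        raise ValueError("non-ACGT base in " + kmer)
    s = 0.0
    for pos, freqs in cons.items():
        base = kmer[pos - 1]
        s += math.log2(max(freqs[base], FLOOR) / max(bgd[pos][base], FLOOR))
    for blk in blocks:
        idx = 0
        for p in blk["positions"]:
            idx = idx * 4 + BASE_INDEX[kmer[p - 1]]
        s += blk["sign"] * math.log2(max(blk["values"][idx], FLOOR))
    return s


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--table", required=True)
    ap.add_argument("--kmers", default="-",
                    help="file of one k-mer per line, or - for stdin")
    args = ap.parse_args()
    cons, bgd, blocks = parse_table(args.table)
    fh = sys.stdin if args.kmers == "-" else open(args.kmers)
    for line in fh:
        kmer = line.strip()
        if kmer:
            print("%.10f" % score_kmer(kmer, cons, bgd, blocks))


if __name__ == "__main__":
    main()
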