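---
title: "Splice-site models and spliceogenicity assessment in mesplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-site models and spliceogenicity assessment in mesplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesplice)
```

## The scoring model

`mesplice` scores candidate splice motifs as log2 likelihood ratios of a
signal model over a background model. The donor motif is a 9-mer spanning
the last 3 exonic and first 6 intronic nucleotides, with the near-invariant
GT at intron positions +1/+2 (motif offsets 4–5); the acceptor motif is a
23-mer spanning the last 20 intronic and first 3 exonic nucleotides, with AG
at offsets 19–20. Scores are kept at full precision internally and rendered
to two decimals in reports.

The signal component is a maximum-entropy distribution: the distribution of
largest entropy whose marginals on a chosen set of position subsets match
the empirical marginals of the training sequences. With only first-order
(per-position) constraints this is the familiar product-of-marginals
position weight model; adding adjacent-pair constraints captures
nearest-neighbour dependence. Two constraint regimes are supported, chosen
by motif length:

* **Donor (9 nt).** The joint distribution over 4^9 = 262,144 motifs is held
  explicitly, so constraints may be arbitrary position subsets (including
  the selected second-order subsets a user may care about). Iterative
  proportional fitting multiplies the joint by the ratio of empirical to
  current marginals, constraint by constraint, until the largest absolute
  marginal deviation falls below the tolerance.
* **Acceptor (23 nt).** 4^23 is not enumerable, so constraints are
  restricted to single positions and adjacent pairs and the same
  multiplicative updates run on chain factor potentials, with exact
  forward–backward marginals. The fixed point is the first-order Markov
  chain — the closed-form maximum-entropy solution for that constraint set —
  which the unit tests exploit as an independent check.

Defaults: tolerance `1e-6`, `max_iter` 1000, uniform initialization.
Convergence is reported on the fitted model; failing to reach tolerance is a
warning (with the achieved deviation), not an error, because a nearly
converged model is still usable. Empirical cells of zero are floored at
`1e-9` and renormalized before ratios are taken, so scores remain finite on
unseen k-mers; model-derived probabilities below that floor are legitimate
and are not distorted (only exact zeros are guarded). The background is
fitted with first-order constraints (or uniform when no background
sequences are supplied): a positionwise background keeps every ratio factor
well-defined and is the standard choice for likelihood-ratio motif scoring.

The bundled `default_models()` are **synthetic** consensus-like profiles
written directly in code: near-invariant GT/AG (0.995), an A/G-rich donor
intron consensus, a pyrimidine tract upstream of the acceptor AG, and a
background of 27% A/T, 23% C/G. They are not the published human tables;
they were chosen once so that a consensus donor scores ≈ 12.4 log2 units,
which places the 6.2/8.5 classification cut-offs in the same working range
they occupy for the human models. Models fitted from user sequences, or
external tables in the supported layout, can be substituted everywhere.

## Score tables

`write_mes_tables()` / `load_reference_tables()` exchange models in a
MaxEntScan-style layout: the consensus dinucleotide is scored by per-position
frequency ratios carried in the file header, and the remaining positions by
4^7-entry ratio tables — one table over positions 1–3,6–9 for the donor,
and nine sub-model tables for the acceptor (five "included" blocks over
7-position windows of the 21 non-consensus positions, divided by four
"correction" blocks over their overlaps). Block position subsets are written
explicitly in the headers and read back from them, never hard-coded in the
readers. For a chain (or independent) acceptor model this
included/correction quotient is the exact junction-tree factorization of the
marginalized chain, so the file reproduces the source model closely; the
consensus-independence assumption of the layout is the only approximation.
An independent Python implementation of the same file algebra ships in
`inst/oracle/mes_table_scorer.py` and is used as a cross-language oracle in
the tests.

## The three score sets

For each (variant, transcript) pair the package computes:

1. **Native-site scores.** Every native site whose motif span the variant
   overlaps is scored on both haplotypes; `diff = ref − alt`, so positive
   diff means the reference motif is fitter (loss direction). For
   length-changing variants the alternate motif is re-anchored at the
   exon/intron boundary projected through the edit; if a deletion removes
   the boundary itself, the alternate score falls back to the best
   sliding-window score over the former site and the record is flagged.
2. **MES-SWA.** All k-mer windows in which the allele (for a pure deletion,
   the junction base immediately 3' of the deleted span) occupies a window
   position are scored on both haplotypes, the allele's first base sliding
   from window position k down to 1. An SNV yields exactly k windows per
   site type. The best alternate window is reported with a reference
   comparison score: for SNVs, the reference window in the same frame as the
   best alternate window; for all other variants, the best reference window,
   compared against the alternate window whose 5' end is the reference
   frame's start projected through the edit (positions 3' of an insertion
   shift by its length, of a deletion by minus its length; positions inside
   a deleted span collapse to its 5' edge). Both raw maxima are always
   retained so the projection can be audited. Ties between equal-scoring
   windows resolve to the 5'-most frame, for deterministic output.
3. **MES-NCSS.** The nearest native donor and acceptor entirely upstream and
   entirely downstream of the variant — in transcript orientation, so the
   semantics match donor/acceptor directionality on minus-strand genes —
   scored on the reference haplotype. Absence is a value, not an error.

All sequence work happens on the transcript sense strand: one reverse
complement at extraction for minus-strand transcripts, nowhere else. Windows
containing ambiguous bases (N) are skipped and flagged rather than scored;
windows running off a chromosome end raise a typed `truncated_windows`
condition that the assessment layer converts into an
assessment-unavailable result.

## Classification

Variants overlapping a native splice-site motif are assessed for loss
(SNVs via the native-site scores; indels via the sliding-window result);
variants outside all native motifs are assessed for gain. Both donor and
acceptor channels are evaluated and the higher-priority call is reported,
ties going to the donor channel.

* **Loss** requires `diff > 0`. Tier by alt: `< 6.2` high, `6.2 ≤ alt ≤ 8.5`
  moderate (boundaries inclusive), `> 8.5` low; when `diff < 1.15` high
  drops to moderate and moderate to low (`diff` exactly 1.15 does not
  downgrade).
* **Gain** requires `diff < 0`. Tier by the best alternate window score:
  `> 8.5` high, `6.2–8.5` moderate, `< 6.2` low. A moderate candidate must
  strictly outcompete the nearest native site of the same type (donor
  candidates against donors, acceptors against acceptors, nearest by
  genomic distance over both directions); failing the competition demotes
  it to low — it stays in the classified set rather than vanishing. High
  candidates are not subjected to the competition test. When no same-type
  native site exists the test passes vacuously and the call is flagged
  `no_native_competitor`.

The three cut-offs live in a `splice_thresholds` object and can be replaced
wholesale; the decision tree itself never hard-codes them. Design choices
worth knowing: the competition comparator (same-type nearest site) and the
vacuous-pass behaviour were genuinely open — same-type comparison keeps the
donor/acceptor channels independent and is the variant most defensible
biologically, since a nascent donor competes for the spliceosome against
donors. A variant inside a native motif is not additionally reported as a
gain in its primary call, but all gain evidence is still present in the
output columns.

## Annotation outputs

`annotate_variants()` checks contig-name consistency across VCF, annotation
and FASTA first (a hard error listing offenders), decomposes multi-allelic
records, left-aligns and trims indels against the genome (verified against
`bcftools norm` in the tests), and assesses every overlapping transcript
independently — one row per (variant, transcript). The annotated VCF
preserves input records byte-for-byte apart from the appended `MES_*` INFO
keys (per-transcript values pipe-delimited parallel to `MES_TX`), which
makes re-annotation idempotent; the TSV report carries the full score panel
with missing values rendered as `.`, distinct from zero.

## The synthetic fixture generator

`generate_fixture()` builds, deterministically from a seed, a multi-gene
genome on both strands: exon/intron bodies are background sequence and every
junction carries a donor 9-mer and acceptor 23-mer sampled from the signal
models, with the GT/AG consensus enforced and a minimum motif score of 7 so
that implanted sites are credible competitors. Six variant recipes produce
construction-guaranteed truth labels:

* **Dinucleotide loss** (donor GT, acceptor AG substitutions) — labelled
  aberrant by construction; destroying the consensus costs ≈ 9 log2 units
  under the default models, far past every threshold.
* **Near-site weakening** — a non-consensus motif position is mutated to the
  signal model's least-probable base; the label (aberrant or normal) is
  derived at generation time by direct motif scoring through the same
  tiering rules, so borderline weakenings legitimately become normal-truth
  records.
* **Planted gains** (deep-intronic and exonic) — a strong sampled motif
  (score ≥ 9.5) is written into the genome with its consensus dinucleotide
  broken; the variant restores it. Each plant is verified at generation time
  by direct scoring: the restored window must beat every reference window
  and clear the high-gain cut, and the opposite site type must stay quiet.
  Plants keep ≥ 26 nt clearance from native motifs so scoring windows never
  interact.
* **Neutral** — random substitutions accepted only where every donor and
  acceptor window on both haplotypes scores below 6.2, verified by direct
  scoring at generation time.

The generator emulates the *structure* the assessment needs — genes on both
strands, realistic motif strength variation, variants stratified across
dinucleotide/motif/exonic/intronic regions — but not several features of
real data: no ambiguous bases, no overlapping genes or alternative
transcripts, intron/exon lengths in a narrow synthetic range (introns
90–160 nt against a human median in the kilobases), and truth labels that
are model-consistent by construction rather than assay-derived. Passing the
end-to-end fixture check therefore demonstrates that the pipeline's
coordinate arithmetic, strand handling, window enumeration and
classification are faithful to the scoring model — not that the model
predicts real mRNA assay outcomes; with generator and assessor sharing the
models, misclassifications can only come from pipeline defects, which is
exactly what the check isolates. Sensitivity/specificity of 0.9 rather than
1.0 is promised because window competition near borderline plants can in
principle reclassify them.

Default problem sizes — 30 genes, 5 chromosomes, 500 variants across the six
recipes, a 200-variant sliding-window cross-check, 100-k-mer oracle panels —
were chosen so the whole suite exercises every code path in about a minute
on a laptop while keeping every count large enough that a systematic defect
cannot hide in sampling noise.

## Evaluation

`evaluate_calls()` joins calls to truth on (chrom, pos, ref, alt,
transcript_id) — the transcript is part of the key to avoid cross-transcript
ambiguity — counts the confusion matrix per region label and overall, and
reports sensitivity TP/(TP+FN) and specificity TN/(TN+FP). A positive
prediction is a high or moderate call of either mechanism. Empty
denominators yield `NA` ("undefined"), never zero: a region whose truth set
contains no normal-splicing variants has no true-negative rate. Region
labels are taken from the truth table, so externally curated datasets with
their own stratification drop in unchanged.

## Numerical choices and limitations

* Log base 2 everywhere; two-decimal rendering only at output boundaries.
* Probability floor `1e-9` on empirical cells; `1e-30` guard on exact zeros
  in model-derived joints.
* Window ties resolve 5'-most; the donor channel wins priority ties.
* Variants are assessed one at a time; co-occurring variants on one
  haplotype are out of scope, as are branch-point and exonic
  enhancer/silencer models.
* Assessment requires overlap with the transcript span (first exon start to
  last exon end); variants entirely outside, however close, are passed
  through unannotated.
* The non-SNV reference-comparison frame projection is a documented
  convention, not a community standard; both raw maxima are emitted so any
  alternative contrast can be recomputed from the output.
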