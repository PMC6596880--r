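Package: mesplice
Title: Maximum-Entropy Splice-Site Scoring and Variant Spliceogenicity Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores donor (9-mer) and acceptor (23-mer) splice-site motifs with
    maximum-entropy sequence models, assesses variants for native splice-site
    loss and de novo or cryptic splice-site gain using a sliding-window search
    (MES-SWA) and nearest-canonical-splice-site competition scores (MES-NCSS),
    and classifies spliceogenic potential with configurable high/moderate/low
    thresholds. Includes model fitting by iterative scaling, MaxEntScan-style
    score table reading and writing, end-to-end VCF annotation against a
    transcript annotation and reference genome, a seeded synthetic fixture
    generator with construction-guaranteed truth labels, and a
    sensitivity/specificity evaluator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
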