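# Transcript parsing, native-site geometry, window enumeration, variant
# normalization.

write_toy_gtf <- function(path, strand = "+") {
  attrs <- 'gene_id "G1"; transcript_id "T1";'
  lines <- c(
    sprintf("chrT\ttest\ttranscript\t101\t400\t.\t%s\t.\t%s", strand, attrs),
    sprintf("chrT\ttest\texon\t101\t200\t.\t%s\t.\t%s", strand, attrs),
    sprintf("chrT\ttest\texon\t301\t400\t.\t%s\t.\t%s", strand, attrs))
  writeLines(lines, path)
  path
}

test_that("GTF parsing applies the 1-based inclusive to 0-based half-open conversion", {
  p <- write_toy_gtf(file.path(tempdir(), "toy.gtf"))
  txs <- parse_transcripts(p)
  expect_length(txs, 1)
  tx <- txs$T1
  expect_identical(unname(tx$exons[, 1]), c(100L, 300L))
  expect_identical(unname(tx$exons[, 2]), c(200L, 400L))
  expect_identical(unname(mesplice:::tx_introns(tx)[1, ]), c(200L, 300L))
})

test_that("minus-strand transcripts iterate exons 5'->3' in genomically descending order", {
  p <- write_toy_gtf(file.path(tempdir(), "toy-minus.gtf"), strand = "-")
  tx <- parse_transcripts(p)$T1
  expect_identical(tx$strand, "-")
  ord <- mesplice:::tx_exon_order(tx)
  expect_identical(unname(tx$exons[ord, 1]), c(300L, 100L))
})

test_that("exonless transcripts are skipped with a warning", {
  p <- file.path(tempdir(), "orphan.gtf")
  writeLines(c(
    'chrT\ttest\ttranscript\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\ttest\texon\t101\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrT\ttest\ttranscript\t500\t600\t.\t+\t.\tgene_id "G2"; transcript_id "T2";'),
    p)
  expect_warning(txs <- parse_transcripts(p), "exonless.*T2")
  expect_named(txs, "T1")
})

test_that("native sites follow the 3+6 / 20+3 geometry and flag short introns", {
  toy <- toy_genome_tx()
  sites <- native_sites(toy$tx)
  expect_length(sites, 4)
  donor1 <- sites[[1]]
  expect_identical(donor1$site_type, "donor")
  # exon ends at 1-based 200 -> motif 198-206 (1-based) = [197, 206) 0-based
  expect_identical(donor1$span0, c(197L, 206L))
  acc1 <- sites[[2]]
  expect_identical(acc1$span0, c(280L, 303L))
  # single exon: no sites
  single <- transcript_model("S1", "chrT", "+", rbind(c(10L, 60L)))
  expect_length(native_sites(single), 0)
  # short intron: donor omitted below 6 nt, acceptor below 20 nt
  short <- transcript_model("S2", "chrT", "+", rbind(c(10L, 60L), c(70L, 120L)))
  ss <- native_sites(short)
  expect_identical(vapply(ss, `[[`, character(1), "site_type"), "donor")
  expect_identical(attr(ss, "omitted"), 1L)
})

test_that("native motifs carry GT/AG on the sense strand, both strands", {
  fx <- small_fixture()
  for (tx in fx$transcripts) {
    for (site in native_sites(tx)) {
      s <- mesplice:::site_sequence(fx$genome, site)
      if (site$site_type == "donor") {
        expect_identical(substr(s, 4, 5), "GT")
      } else {
        expect_identical(substr(s, 19, 20), "AG")
      }
    }
  }
})

test_that("minus-strand native motifs equal the reverse complement of the plus span", {
  fx <- small_fixture()
  minus_tx <- Filter(function(t) t$strand == "-", fx$transcripts)[[1]]
  site <- native_sites(minus_tx)[[1]]
  plus_seq <- substr(fx$genome[[site$chrom]], site$span0[1] + 1, site$span0[2])
  expect_identical(mesplice:::site_sequence(fx$genome, site),
                   mesplice:::revcomp(plus_seq))
})

test_that("SNV windows: exactly k frames, allele walks from position k to 1", {
  toy <- toy_genome_tx()
  v <- normalize_variant("chrT", 250, substr(toy$genome[["chrT"]], 250, 250),
                         setdiff(c("A", "C", "G", "T"),
                                 substr(toy$genome[["chrT"]], 250, 250))[1],
                         toy$genome)
  for (k in c(9L, 23L)) {
    w <- window_sequences(toy$genome, toy$tx, v, k, "alt")
    expect_identical(nrow(w), as.integer(k))
    expect_identical(w$frame, seq(k, 1L))
    for (i in seq_len(nrow(w))) {
      expect_identical(substr(w$seq[i], w$frame[i], w$frame[i]), v$alt)
    }
  }
  # the reference-haplotype window set shares the frames one-to-one
  wr <- window_sequences(toy$genome, toy$tx, v, 9L, "ref")
  expect_identical(wr$frame, seq(9L, 1L))
  for (i in seq_len(nrow(wr))) {
    expect_identical(substr(wr$seq[i], wr$frame[i], wr$frame[i]), v$ref)
  }
})

test_that("insertion windows are exactly the brute-force set containing the insert", {
  toy <- toy_genome_tx()
  g <- toy$genome[["chrT"]]
  anchor <- substr(g, 250, 250)
  v <- normalize_variant("chrT", 250, anchor, paste0(anchor, "GTAA"), toy$genome)
  k <- 9L
  w <- window_sequences(toy$genome, toy$tx, v, k, "alt")
  expect_identical(nrow(w), k + 4L - 1L)  # k + insert_length - 1 frames
  # brute force: all 9-mers of the alt haplotype containing >= 1 inserted base
  althap <- paste0(substr(g, 1, 250), "GTAA", substr(g, 251, nchar(g)))
  ins0 <- 250  # first inserted base, 0-based in alt hap
  starts <- (ins0 - k + 1):(ins0 + 3)
  expected <- substring(althap, starts + 1, starts + k)
  expect_setequal(w$seq, expected)
})

test_that("minus-strand windows equal the reverse complement of plus-strand windows", {
  fx <- small_fixture()
  minus_tx <- Filter(function(t) t$strand == "-", fx$transcripts)[[1]]
  g <- fx$genome[[minus_tx$chrom]]
  sp <- mesplice:::tx_span0(minus_tx)
  pos <- sp[1] + 50L
  ref <- substr(g, pos + 1, pos + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- normalize_variant(minus_tx$chrom, pos + 1, ref, alt, fx$genome)
  w <- window_sequences(fx$genome, minus_tx, v, 9L, "alt")
  # independent construction: plus-strand windows of the alt haplotype, then
  # reverse complement and reverse order
  althap <- paste0(substr(g, 1, pos), alt, substr(g, pos + 2, nchar(g)))
  starts <- (pos - 8):pos
  plus_windows <- substring(althap, starts + 1, starts + 9)
  expect_identical(w$seq, rev(mesplice:::revcomp(plus_windows)))
})

test_that("windows at the chromosome edge raise a truncated-windows error", {
  g <- c(chrE = paste(rep("ACGT", 10), collapse = ""))
  tx <- transcript_model("E1", "chrE", "+", rbind(c(0L, 40L)))
  v <- normalize_variant("chrE", 2, "C", "T", g)
  expect_error(window_sequences(g, tx, v, 9L, "alt"),
               class = "truncated_windows")
})

test_that("variant normalization trims, left-aligns and classifies", {
  toy <- toy_genome_tx()
  g <- toy$genome[["chrT"]]
  # parsimony trim: REF=AT ALT=AG at p -> SNV T>G at p+1
  p <- 150L
  ref2 <- substr(g, p, p + 1)
  alt2 <- paste0(substr(g, p, p), "G")
  if (substr(ref2, 2, 2) != "G") {
    v <- normalize_variant("chrT", p, ref2, alt2, toy$genome)
    expect_identical(v$pos, p + 1L)
    expect_identical(v$ref, substr(ref2, 2, 2))
    expect_identical(v$alt, "G")
    expect_identical(v$variant_class, "SNV")
  }
  # identity is rejected
  expect_error(normalize_variant("chrT", p, substr(g, p, p), substr(g, p, p),
                                 toy$genome), "identical")
  # symbolic alleles raise the skippable condition class
  expect_error(normalize_variant("chrT", p, substr(g, p, p), "<DEL>", toy$genome),
               class = "unsupported_variant")
  # REF must match the genome (alt chosen different from the bogus ref)
  wrong <- setdiff(c("A", "C", "G", "T"), substr(g, p, p))[1]
  alt_ok <- setdiff(c("A", "C", "G", "T"), wrong)[1]
  expect_error(normalize_variant("chrT", p, wrong, alt_ok, toy$genome),
               "REF mismatch")
})

test_that("indel left-alignment agrees with bcftools norm", {
  fx <- small_fixture()
  g1 <- names(fx$genome)[1]
  g <- fx$genome[[g1]]
  set.seed(404)
  recs <- list()
  for (i in 1:150) {
    pos0 <- sample(100:(nchar(g) - 100), 1)
    if (runif(1) < 0.5) {
      len <- sample(1:4, 1)  # deletion written un-left-aligned
      ref <- substr(g, pos0 + 1, pos0 + 1 + len)
      alt <- substr(g, pos0 + 1, pos0 + 1)
    } else {
      ref <- substr(g, pos0 + 1, pos0 + 1)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:4, 1), TRUE), collapse = "")
      alt <- paste0(ref, ins)
    }
    recs[[i]] <- list(pos = pos0 + 1L, ref = ref, alt = alt)
  }
  vcf_in <- file.path(tempdir(), "norm-in.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", g1, nchar(g)),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               vapply(recs, function(r) sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                                                g1, r$pos, r$ref, r$alt),
                      character(1))), vcf_in)
  ours <- lapply(recs, function(r) {
    normalize_variant(g1, r$pos, r$ref, r$alt, fx$genome)
  })
  out <- system2("bcftools", c("norm", "-f", fx$paths$fasta, vcf_in),
                 stdout = TRUE, stderr = FALSE)
  body <- out[!startsWith(out, "#")]
  flds <- do.call(rbind, strsplit(body, "\t"))
  # bcftools norm re-sorts records whose position moved; compare as sorted sets
  ours_key <- sort(vapply(ours, function(v) {
    sprintf("%09d:%s:%s", v$pos, v$ref, v$alt)
  }, character(1)))
  bcf_key <- sort(sprintf("%09d:%s:%s", as.integer(flds[, 2]), flds[, 4], flds[, 5]))
  expect_identical(ours_key, bcf_key)
})
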