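# Native-site scoring, MES-SWA, MES-NCSS.

test_that("native reference scores are recomputable through the model layer", {
  toy <- toy_genome_tx()
  site <- native_sites(toy$tx)[[1]]
  # donor dinucleotide SNV: G of GT -> A
  gpos0 <- mesplice:::site_offset_pos0(site, 3L)
  g <- toy$genome[["chrT"]]
  v <- normalize_variant("chrT", gpos0 + 1, substr(g, gpos0 + 1, gpos0 + 1), "A",
                         toy$genome)
  ns <- score_native_sites(v, toy$tx, toy$genome, toy$models)
  expect_length(ns, 1)
  expect_equal(ns[[1]]$ref_score,
               score_motif(toy$models$donor,
                           mesplice:::site_sequence(toy$genome, site)))
  expect_equal(ns[[1]]$ref_score, score_motif(toy$models$donor, toy$donors[1]))
})

test_that("destroying the donor GT drops the alternate score (diff > 0)", {
  toy <- toy_genome_tx()
  site <- native_sites(toy$tx)[[1]]
  gpos0 <- mesplice:::site_offset_pos0(site, 3L)
  v <- normalize_variant("chrT", gpos0 + 1, "G", "A", toy$genome)
  ns <- score_native_sites(v, toy$tx, toy$genome, toy$models)
  expect_lt(ns[[1]]$alt_score, ns[[1]]$ref_score)
  expect_gt(ns[[1]]$diff, 1.15)
  expect_equal(ns[[1]]$diff, ns[[1]]$ref_score - ns[[1]]$alt_score)
})

test_that("variants outside all native sites yield an empty native score list", {
  toy <- toy_genome_tx()
  g <- toy$genome[["chrT"]]
  v <- normalize_variant("chrT", 250, substr(g, 250, 250),
                         setdiff(c("A", "C", "G", "T"), substr(g, 250, 250))[1],
                         toy$genome)
  expect_length(score_native_sites(v, toy$tx, toy$genome, toy$models), 0)
})

test_that("SWA on a native-site SNV finds the native frame when it stays best", {
  toy <- toy_genome_tx()
  site <- native_sites(toy$tx)[[1]]
  # benign-ish change at motif offset 8 (last intronic position)
  gpos0 <- mesplice:::site_offset_pos0(site, 8L)
  g <- toy$genome[["chrT"]]
  ref <- substr(g, gpos0 + 1, gpos0 + 1)
  v <- normalize_variant("chrT", gpos0 + 1, ref,
                         setdiff(c("A", "C", "G", "T"), ref)[1], toy$genome)
  swa <- run_swa(v, toy$tx, toy$genome, toy$models, "donor")
  # brute force over the 9 windows
  wa <- window_sequences(toy$genome, toy$tx, v, 9L, "alt")
  scores <- score_motif(toy$models$donor, wa$seq)
  expect_equal(swa$alt_best$score, max(scores))
  expect_identical(swa$alt_best$frame, wa$frame[which.max(scores)])
  # the variant sits at motif offset 8, i.e. window frame 9 holds the native motif
  if (which.max(scores) == 1L) {
    expect_identical(swa$alt_best$frame, 9L)
  }
  expect_equal(swa$diff, swa$ref_comp - swa$alt_best$score)
})

test_that("an SNV completing a planted strong donor deep in an intron is a gain", {
  fx <- small_fixture()
  plants <- fx$variants[fx$variants$category == "deep_intronic_gain", ]
  expect_gt(nrow(plants), 0)
  r <- plants[1, ]
  v <- normalize_variant(r$chrom, r$pos, r$ref, r$alt, fx$genome)
  tx <- fx$transcripts[[r$transcript_id]]
  models <- test_models()
  swa_d <- run_swa(v, tx, fx$genome, models, "donor")
  swa_a <- run_swa(v, tx, fx$genome, models, "acceptor")
  best <- if (swa_d$alt_best$score >= swa_a$alt_best$score) swa_d else swa_a
  expect_lt(best$diff, 0)
  expect_gt(best$alt_best$score, 8.5)
})

test_that("NCSS slots follow transcript-orientation geometry", {
  toy <- toy_genome_tx()
  g <- toy$genome[["chrT"]]
  # variant in intron 1 (middle, away from motifs): 0-based 240
  v <- normalize_variant("chrT", 241, substr(g, 241, 241),
                         setdiff(c("A", "C", "G", "T"), substr(g, 241, 241))[1],
                         toy$genome)
  ncss <- run_ncss(v, toy$tx, toy$genome, toy$models)
  expect_identical(ncss$upstream_donor$site$exon_index, 1L)
  expect_identical(ncss$downstream_acceptor$site$exon_index, 2L)
  expect_identical(ncss$downstream_donor$site$exon_index, 2L)
  expect_null(ncss$upstream_acceptor)
  # scores equal direct recomputation
  expect_equal(ncss$upstream_donor$score,
               score_motif(toy$models$donor, toy$donors[1]))
  expect_equal(ncss$downstream_acceptor$score,
               score_motif(toy$models$acceptor, toy$acceptors[1]))
  # single-exon transcript: all four slots absent
  single <- transcript_model("S1", "chrT", "+", rbind(c(100L, 400L)))
  n2 <- run_ncss(v, single, toy$genome, toy$models)
  expect_true(all(vapply(n2[1:4], is.null, logical(1))))
})

test_that("NCSS orientation flips with the strand", {
  fx <- small_fixture()
  minus_tx <- Filter(function(t) t$strand == "-", fx$transcripts)[[1]]
  sites <- native_sites(minus_tx)
  donor1 <- sites[[1]]  # first junction donor, genomically highest
  g <- fx$genome[[minus_tx$chrom]]
  # variant genomically below the first-junction donor => transcript-downstream
  pos0 <- donor1$span0[1] - 40L
  ref <- substr(g, pos0 + 1, pos0 + 1)
  v <- normalize_variant(minus_tx$chrom, pos0 + 1, ref,
                         setdiff(c("A", "C", "G", "T"), ref)[1], fx$genome)
  ncss <- run_ncss(v, minus_tx, fx$genome, test_models())
  if (!is.null(ncss$upstream_donor)) {
    expect_gte(ncss$upstream_donor$site$span0[1], pos0)
  }
  if (!is.null(ncss$downstream_donor)) {
    expect_lte(ncss$downstream_donor$site$span0[2], pos0 + 1L)
  }
})

test_that("indel SWA carries both raw maxima and the projected comparison", {
  toy <- toy_genome_tx()
  g <- toy$genome[["chrT"]]
  anchor <- substr(g, 250, 250)
  v <- normalize_variant("chrT", 250, anchor, paste0(anchor, "TTG"), toy$genome)
  swa <- run_swa(v, toy$tx, toy$genome, toy$models, "donor")
  expect_false(is.na(swa$alt_best$score))
  expect_false(is.na(swa$ref_best$score))
  expect_identical(swa$ref_comp, swa$ref_best$score)
  expect_equal(swa$diff, swa$ref_comp - swa$alt_comp)
})
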