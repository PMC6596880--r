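# Fixture generator determinism and construction guarantees; evaluator
# correctness against a brute-force tally.

test_that("generation is byte-identical for a fixed seed", {
  spec <- fixture_spec(seed = 77L, n_genes = 3L, n_chroms = 1L,
                       counts = list(donor_dinucleotide_loss = 3L,
                                     deep_intronic_gain = 2L, neutral = 2L))
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  for (f in c("genome.fa", "annotation.gtf", "variants.vcf", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(9); a <- runif(1)
  set.seed(9)
  generate_fixture(fixture_spec(seed = 3L, n_genes = 2L, n_chroms = 1L,
                                counts = list(neutral = 1L)),
                   file.path(tempdir(), "rngcheck"))
  expect_identical(runif(1), a)
})

test_that("a donor-dinucleotide-only recipe yields only aberrant in-motif variants", {
  spec <- fixture_spec(seed = 11L, n_genes = 3L, n_chroms = 1L,
                       counts = list(donor_dinucleotide_loss = 6L))
  fx <- generate_fixture(spec, file.path(tempdir(), "donly"))
  expect_identical(nrow(fx$variants), 6L)
  expect_true(all(fx$variants$assay_outcome == "aberrant"))
  expect_true(all(fx$variants$region_label == "donor_dinucleotide"))
  for (i in seq_len(nrow(fx$variants))) {
    r <- fx$variants[i, ]
    tx <- fx$transcripts[[r$transcript_id]]
    donors <- Filter(function(s) s$site_type == "donor", native_sites(tx))
    pos0 <- r$pos - 1L
    inside <- any(vapply(donors, function(s) {
      pos0 >= s$span0[1] && pos0 < s$span0[2]
    }, logical(1)))
    expect_true(inside)
  }
})

test_that("planted-gain variants satisfy their score conditions by construction", {
  fx <- small_fixture()
  models <- test_models()
  plants <- fx$variants[fx$variants$category %in%
                          c("deep_intronic_gain", "exonic_gain"), ]
  for (i in seq_len(nrow(plants))) {
    r <- plants[i, ]
    v <- normalize_variant(r$chrom, r$pos, r$ref, r$alt, fx$genome)
    tx <- fx$transcripts[[r$transcript_id]]
    swa_d <- run_swa(v, tx, fx$genome, models, "donor")
    swa_a <- run_swa(v, tx, fx$genome, models, "acceptor")
    best <- if (swa_d$alt_best$score >= swa_a$alt_best$score) swa_d else swa_a
    expect_gt(best$alt_best$score, 8.5)
    expect_lt(best$diff, 0)
  }
})

test_that("infeasible recipes fail with an error naming the category", {
  spec <- fixture_spec(seed = 5L, n_genes = 1L, exons_per_gene = c(2L, 2L),
                       n_chroms = 1L,
                       counts = list(donor_dinucleotide_loss = 50L))
  expect_error(generate_fixture(spec, file.path(tempdir(), "infeasible")),
               "infeasible|ran out")
})

test_that("the evaluator matches a brute-force confusion tally", {
  set.seed(31)
  n <- 1000L
  truth <- data.frame(
    chrom = "chr1", pos = seq_len(n), ref = "A", alt = "C",
    transcript_id = sprintf("TX%02d", sample(1:5, n, TRUE)),
    region_label = sample(c("exonic", "intronic_other", "donor_other"), n, TRUE),
    assay_outcome = sample(c("aberrant", "normal"), n, TRUE),
    stringsAsFactors = FALSE)
  calls <- truth[, c("chrom", "pos", "ref", "alt", "transcript_id")]
  calls$priority <- sample(c("high", "moderate", "low", "none"), n, TRUE)
  rep <- evaluate_calls(calls, truth)
  pred <- calls$priority %in% c("high", "moderate")
  act <- truth$assay_outcome == "aberrant"
  ov <- rep[rep$region == "overall", ]
  expect_identical(ov$tp, sum(pred & act))
  expect_identical(ov$fp, sum(pred & !act))
  expect_identical(ov$tn, sum(!pred & !act))
  expect_identical(ov$fn, sum(!pred & act))
  expect_equal(ov$sensitivity, sum(pred & act) / sum(act))
  # per-region counts add up to the total
  regs <- rep[rep$region != "overall", ]
  expect_identical(sum(regs$tp + regs$fp + regs$tn + regs$fn), n)
})

test_that("the evaluator is permutation-invariant and flags unmatched records", {
  set.seed(8)
  n <- 50L
  truth <- data.frame(chrom = "c", pos = 1:n, ref = "A", alt = "G",
                      transcript_id = "T1",
                      region_label = "exonic",
                      assay_outcome = rep(c("aberrant", "normal"), length.out = n),
                      stringsAsFactors = FALSE)
  calls <- truth[, 1:5]
  calls$priority <- rep(c("high", "none"), length.out = n)
  r1 <- evaluate_calls(calls, truth)
  r2 <- evaluate_calls(calls[sample(n), ], truth[sample(n), ])
  expect_identical(r1$tp, r2$tp)
  expect_identical(r1$sensitivity, r2$sensitivity)
  # unmatched rows are excluded with a warning
  # one call re-keyed: both its old truth key and its new call key go unmatched,
  # leaving n-1 evaluable pairs
  calls2 <- calls
  calls2$pos[1] <- 9999L
  expect_warning(r3 <- evaluate_calls(calls2, truth), "unmatched")
  ov <- r3[r3$region == "overall", ]
  expect_identical(ov$tp + ov$fp + ov$tn + ov$fn, n - 1L)
  expect_length(attr(r3, "excluded"), 2L)
})

test_that("degenerate truth gives undefined (not zero) specificity", {
  truth <- data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "G",
                      transcript_id = "T1", region_label = "exonic",
                      assay_outcome = "aberrant", stringsAsFactors = FALSE)
  calls <- truth[, 1:5]
  calls$priority <- "high"
  rep <- evaluate_calls(calls, truth)
  ov <- rep[rep$region == "overall", ]
  expect_identical(ov$sensitivity, 1)
  expect_true(is.na(ov$specificity))
})
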