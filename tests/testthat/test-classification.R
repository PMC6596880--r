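# Decision-tree classification: worked examples, boundary semantics,
# monotonicity, threshold configurability.

t_default <- splice_thresholds()

test_that("loss classification follows the tiering and downgrade rules", {
  # clear high: large diff, very low alt
  c1 <- classify_loss(diff = 7, alt = 3, t = t_default)
  expect_identical(c1$priority, "high")
  expect_false(c1$downgraded)
  expect_identical(c1$mechanism, "native_loss")
  # small diff: base moderate downgraded to low
  c2 <- classify_loss(diff = 0.5, alt = 6.5, t = t_default)
  expect_identical(c2$priority, "low")
  expect_true(c2$downgraded)
  # diff = 0 is not loss
  c3 <- classify_loss(diff = 0, alt = 5, t = t_default)
  expect_identical(c3$priority, "none")
  expect_identical(c3$mechanism, "none")
})

test_that("gain classification applies the competition test to moderate only", {
  mk_swa <- function(alt, diff) {
    structure(list(site_type = "donor",
                   alt_best = list(frame = 5L, seq = NA_character_, score = alt),
                   ref_best = list(frame = 5L, seq = NA_character_,
                                   score = alt + diff),
                   ref_comp = alt + diff, alt_comp = alt, diff = diff,
                   flags = character(0)),
              class = "swa_result")
  }
  mk_ncss <- function(score) {
    structure(list(upstream_donor = list(site = NULL, score = score, distance = 10L),
                   upstream_acceptor = NULL, downstream_donor = NULL,
                   downstream_acceptor = NULL),
              class = "ncss_result")
  }
  # high gain: no competition test
  g1 <- classify_gain(mk_swa(9.1, -4), mk_ncss(12), t_default)
  expect_identical(g1$priority, "high")
  # moderate candidate failing competition is demoted to low, not none
  g2 <- classify_gain(mk_swa(7.0, -2), mk_ncss(9.0), t_default)
  expect_identical(g2$priority, "low")
  expect_identical(g2$mechanism, "de_novo_gain")
  # moderate candidate outcompeting the native site stays moderate
  g3 <- classify_gain(mk_swa(7.0, -2), mk_ncss(6.0), t_default)
  expect_identical(g3$priority, "moderate")
  # no gain without diff < 0
  g4 <- classify_gain(mk_swa(9.0, +1), mk_ncss(5), t_default)
  expect_identical(g4$priority, "none")
  # absent competitor: vacuous pass, flagged
  g5 <- classify_gain(mk_swa(7.0, -2),
                      structure(list(upstream_donor = NULL, upstream_acceptor = NULL,
                                     downstream_donor = NULL,
                                     downstream_acceptor = NULL),
                                class = "ncss_result"), t_default)
  expect_identical(g5$priority, "moderate")
  expect_true("no_native_competitor" %in% g5$flags)
})

test_that("priority none and mechanism none imply each other", {
  lattice <- expand.grid(diff = c(-1, 0, 0.5, 2), alt = c(3, 7, 9))
  for (i in seq_len(nrow(lattice))) {
    cl <- classify_loss(diff = lattice$diff[i], alt = lattice$alt[i], t = t_default)
    expect_identical(cl$priority == "none", cl$mechanism == "none")
  }
})

test_that("loss priority is monotone as alt decreases, holding diff fixed", {
  lv <- c(none = 0, low = 1, moderate = 2, high = 3)
  for (diff in c(0.3, 1.2, 4)) {
    alts <- seq(10, 2, by = -0.5)
    pr <- vapply(alts, function(a) {
      classify_loss(diff = diff, alt = a, t = t_default)$priority
    }, character(1))
    expect_true(all(diff(lv[pr]) >= 0))
  }
})

test_that("gain priority is monotone as alt increases, with a fixed competitor", {
  lv <- c(none = 0, low = 1, moderate = 2, high = 3)
  mk_swa <- function(alt) {
    structure(list(site_type = "donor",
                   alt_best = list(frame = 1L, seq = NA_character_, score = alt),
                   ref_best = list(frame = 1L, seq = NA_character_, score = 0),
                   ref_comp = alt - 1, alt_comp = alt, diff = -1,
                   flags = character(0)), class = "swa_result")
  }
  ncss <- structure(list(upstream_donor = list(site = NULL, score = 5, distance = 5L),
                         upstream_acceptor = NULL, downstream_donor = NULL,
                         downstream_acceptor = NULL), class = "ncss_result")
  pr <- vapply(seq(2, 10, by = 0.5), function(a) {
    classify_gain(mk_swa(a), ncss, t_default)$priority
  }, character(1))
  expect_true(all(diff(lv[pr]) >= 0))
})

test_that("user-defined thresholds shift the calls consistently", {
  loose <- splice_thresholds(high_alt_cut = 4, low_alt_cut = 10,
                             downgrade_diff_cut = 0.5)
  # alt = 5: high under defaults, moderate under the loose cuts
  expect_identical(classify_loss(diff = 3, alt = 5, t = t_default)$priority, "high")
  expect_identical(classify_loss(diff = 3, alt = 5, t = loose)$priority, "moderate")
  # diff = 0.8: downgrade under defaults (< 1.15), not under loose (>= 0.5)
  expect_true(classify_loss(diff = 0.8, alt = 5, t = t_default)$downgraded)
  expect_false(classify_loss(diff = 0.8, alt = 5, t = loose)$downgraded)
  expect_error(splice_thresholds(high_alt_cut = 9, low_alt_cut = 8), "below")
  expect_error(splice_thresholds(downgrade_diff_cut = -1), "positive")
})

test_that("assess_variant routes by native-site overlap and labels regions", {
  fx <- small_fixture()
  models <- test_models()
  by_cat <- split(seq_len(nrow(fx$variants)), fx$variants$category)
  pick <- function(cat) fx$variants[by_cat[[cat]][1], ]
  run1 <- function(r) {
    v <- normalize_variant(r$chrom, r$pos, r$ref, r$alt, fx$genome)
    assess_variant(v, fx$transcripts[[r$transcript_id]], fx$genome, models)
  }
  r <- pick("donor_dinucleotide_loss")
  cl <- run1(r)
  expect_identical(cl$mechanism, "native_loss")
  expect_identical(cl$region_label, "donor_dinucleotide")
  r <- pick("deep_intronic_gain")
  cl <- run1(r)
  expect_identical(cl$mechanism, "de_novo_gain")
  expect_identical(cl$region_label, "intronic_other")
  expect_identical(cl$priority, "high")
  r <- pick("neutral")
  cl <- run1(r)
  expect_true(cl$priority %in% c("none", "low"))
})
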