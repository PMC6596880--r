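# Shared lazily-built fixtures: the default models and a small generated
# genome, cached per test run.

test_models <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_models()
    cache
  }
})

# A compact mixed-recipe fixture (24 variants, 4 genes, both strands).
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(
        seed = 21L, n_genes = 4L, n_chroms = 1L,
        counts = list(donor_dinucleotide_loss = 4L,
                      acceptor_dinucleotide_loss = 4L,
                      near_site_weakening = 4L,
                      deep_intronic_gain = 4L,
                      exonic_gain = 4L,
                      neutral = 4L))
      cache <<- generate_fixture(spec, file.path(tempdir(), "mesplice-small-fx"))
    }
    cache
  }
})

# A plain 3-exon plus-strand toy: exon1 101-200, exon2 301-400, exon3 501-600
# (1-based inclusive), native motifs implanted so all four sites score well.
toy_genome_tx <- function(seed = 5L) {
  m <- test_models()
  withr::with_seed(seed, {
    g <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE,
                      prob = c(.27, .23, .23, .27)), collapse = "")
    donors <- vapply(1:2, function(i) mesplice:::sample_site_motif(m$donor, 7),
                     character(1))
    acceptors <- vapply(1:2, function(i) mesplice:::sample_site_motif(m$acceptor, 7),
                        character(1))
    substr(g, 198, 206) <- donors[1]          # junction 1 donor, 0-based [197,206)
    substr(g, 281, 303) <- acceptors[1]       # junction 1 acceptor, [280,303)
    substr(g, 398, 406) <- donors[2]          # junction 2 donor
    substr(g, 481, 503) <- acceptors[2]       # junction 2 acceptor
    tx <- transcript_model("TOY1", "chrT", "+",
                           rbind(c(100L, 200L), c(300L, 400L), c(500L, 600L)))
    list(genome = c(chrT = g), tx = tx, donors = donors, acceptors = acceptors,
         models = m)
  })
}
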