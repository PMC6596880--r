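# Seeded synthetic genome/variant generator with construction-guaranteed
# spliceogenicity truth.
#
# Genes are assembled in transcript-sense space: exon and intron bodies are
# background sequence, every junction carries a donor 9-mer and an acceptor
# 23-mer sampled from the signal models (GT/AG enforced, minimum motif score
# enforced), then minus-strand genes are reverse-complemented into the
# genome. Variant recipes either hit native motifs (dinucleotide loss,
# near-site weakening), restore a planted one-mismatch-from-strong motif
# (deep-intronic and exonic gain) or are verified neutral (every window on
# both haplotypes scores below the high-priority cut). Planted-gain and
# neutral variants are verified at generation time by direct scoring through
# the model layer; truth labels are therefore guaranteed by construction.

#' Specification for a synthetic fixture
#'
#' @param seed integer seed; generation is fully reproducible from it.
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene,exon_len,intron_len,gene_gap integer ranges
#'   (min, max). Introns must be at least 30 nt.
#' @param strand_mix strands cycled over genes.
#' @param counts named list of variant counts per recipe:
#'   donor_dinucleotide_loss, acceptor_dinucleotide_loss, near_site_weakening,
#'   deep_intronic_gain, exonic_gain, neutral.
#' @param n_chroms number of chromosomes genes are distributed over.
#' @param min_native_score minimum model score for implanted native motifs.
#' @param gain_motif_min minimum model score for planted-gain target motifs.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 30L, exons_per_gene = c(5L, 8L),
                         exon_len = c(70L, 130L), intron_len = c(90L, 160L),
                         strand_mix = c("+", "-"),
                         counts = list(donor_dinucleotide_loss = 80L,
                                       acceptor_dinucleotide_loss = 80L,
                                       near_site_weakening = 90L,
                                       deep_intronic_gain = 90L,
                                       exonic_gain = 80L,
                                       neutral = 80L),
                         n_chroms = 5L, gene_gap = c(250L, 400L),
                         min_native_score = 7, gain_motif_min = 9.5) {
  if (intron_len[1L] < 30L) stop("intron lengths must be >= 30", call. = FALSE)
  if (exon_len[1L] < 60L) stop("exon lengths must be >= 60 for gain placement",
                               call. = FALSE)
  if (any(unlist(counts) < 0L)) stop("variant counts must be >= 0", call. = FALSE)
  known <- c("donor_dinucleotide_loss", "acceptor_dinucleotide_loss",
             "near_site_weakening", "deep_intronic_gain", "exonic_gain",
             "neutral")
  if (!all(names(counts) %in% known)) {
    stop("unknown recipe(s): ", paste(setdiff(names(counts), known), collapse = ", "),
         call. = FALSE)
  }
  for (k in setdiff(known, names(counts))) counts[[k]] <- 0L
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 strand_mix = strand_mix, counts = counts,
                 n_chroms = as.integer(n_chroms),
                 gene_gap = as.integer(gene_gap),
                 min_native_score = min_native_score,
                 gain_motif_min = gain_motif_min),
            class = "fixture_spec")
}

rand_range <- function(r) if (r[1L] >= r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)

sample_bg <- function(n, probs = c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

# Sample a motif from the signal model with the consensus dinucleotide forced
# and a minimum score; returns the best candidate if none passes.
sample_site_motif <- function(model, min_score, batch = 64L, max_batches = 20L) {
  co <- model$consensus_offsets + 1L
  cons <- if (model$site_type == "donor") c("G", "T") else c("A", "G")
  best <- NULL; best_score <- -Inf
  for (b in seq_len(max_batches)) {
    s <- sample_motifs(model, batch)
    substr(s, co[1L], co[1L]) <- cons[1L]
    substr(s, co[2L], co[2L]) <- cons[2L]
    sc <- score_motif(model, s)
    i <- which.max(sc)
    if (sc[i] > best_score) { best <- s[i]; best_score <- sc[i] }
    ok <- which(sc >= min_score)
    if (length(ok) > 0L) return(s[ok[1L]])
  }
  best
}

# Least-probable base at a motif position under the signal model, excluding
# the current base.
weakest_base <- function(model, position, exclude) {
  p <- component_marginal(model$signal, position, model$motif_length)
  names(p) <- DNA_BASES
  p <- p[setdiff(DNA_BASES, exclude)]
  names(p)[which.min(p)]
}

# Max model score over all k-mers of `seq` covering 0-based position range
# [p0, p1) (clamped to the sequence).
local_window_max <- function(model, seq, p0, p1 = p0 + 1L) {
  k <- model$motif_length
  n <- nchar(seq)
  starts <- max(0L, p0 - k + 1L):min(n - k, p1 - 1L)
  starts <- starts[starts >= 0L & starts + k <= n]
  if (length(starts) == 0L) return(-Inf)
  kmers <- substring(seq, starts + 1L, starts + k)
  kmers <- kmers[!has_ambiguous(kmers)]
  if (length(kmers) == 0L) return(-Inf)
  max(score_motif(model, kmers))
}

# Loss-priority emulation on raw motif scores (generation-time truth; the
# same tiering rules the classifier applies, computed directly from strings).
loss_priority_direct <- function(ref_score, alt_score, t) {
  diff <- ref_score - alt_score
  if (diff <= 0) return("none")
  base <- if (alt_score < t$high_alt_cut) "high"
    else if (alt_score <= t$low_alt_cut) "moderate"
    else "low"
  if (diff < t$downgrade_diff_cut && base %in% c("high", "moderate")) {
    base <- if (base == "high") "moderate" else "low"
  }
  base
}

#' Generate a synthetic splice fixture
#'
#' Produces a genome FASTA, transcript GTF, variant VCF and a truth TSV
#' (columns chrom, pos, ref, alt, transcript_id, region_label,
#' assay_outcome), all deterministic for a given spec seed. See the package
#' source header of this file for the construction rules.
#'
#' @param spec a [fixture_spec].
#' @param dir output directory (created if needed).
#' @param models donor/acceptor [splice_model]s used for sampling and for the
#'   generation-time self-checks.
#' @param thresholds [splice_thresholds] used to derive construction truth.
#' @return list with file `paths`, plus in-memory `genome`, `transcripts`,
#'   `variants` and `truth` data.frames and the native-site registry.
#' @export
generate_fixture <- function(spec, dir, models = default_models(),
                             thresholds = splice_thresholds()) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, generate_fixture_impl(spec, dir, models, thresholds))
}

generate_fixture_impl <- function(spec, dir, models, thresholds) {
  t <- thresholds
  genes <- list()

  # ---- gene construction in sense space ------------------------------------
  for (gi in seq_len(spec$n_genes)) {
    strand <- spec$strand_mix[((gi - 1L) %% length(spec$strand_mix)) + 1L]
    n_ex <- rand_range(spec$exons_per_gene)
    exon_lens <- vapply(seq_len(n_ex), function(i) rand_range(spec$exon_len),
                        integer(1))
    intron_lens <- vapply(seq_len(n_ex - 1L), function(i) rand_range(spec$intron_len),
                          integer(1))
    donors <- character(n_ex - 1L); acceptors <- character(n_ex - 1L)
    for (j in seq_len(n_ex - 1L)) {
      donors[j] <- sample_site_motif(models$donor, spec$min_native_score)
      acceptors[j] <- sample_site_motif(models$acceptor, spec$min_native_score)
    }
    seq_parts <- character(0)
    exon_iv <- matrix(0L, nrow = n_ex, ncol = 2L)
    cursor <- 0L
    for (j in seq_len(n_ex)) {
      body <- sample_bg(exon_lens[j])
      if (j > 1L) substr(body, 1L, 3L) <- substr(acceptors[j - 1L], 21L, 23L)
      if (j < n_ex) {
        substr(body, exon_lens[j] - 2L, exon_lens[j]) <- substr(donors[j], 1L, 3L)
      }
      exon_iv[j, ] <- c(cursor, cursor + exon_lens[j])
      seq_parts <- c(seq_parts, body)
      cursor <- cursor + exon_lens[j]
      if (j < n_ex) {
        ibody <- sample_bg(intron_lens[j])
        substr(ibody, 1L, 6L) <- substr(donors[j], 4L, 9L)
        substr(ibody, intron_lens[j] - 19L, intron_lens[j]) <-
          substr(acceptors[j], 1L, 20L)
        seq_parts <- c(seq_parts, ibody)
        cursor <- cursor + intron_lens[j]
      }
    }
    genes[[gi]] <- list(
      id = sprintf("G%03d", gi), tx = sprintf("TX%03d", gi), strand = strand,
      sense = paste(seq_parts, collapse = ""), length = cursor,
      exon_iv = exon_iv, intron_lens = intron_lens, n_ex = n_ex,
      donors = donors, acceptors = acceptors,
      used = matrix(integer(0), ncol = 2L)  # reserved sense intervals
    )
  }

  # sense-coordinate motif spans per junction
  gene_sites <- function(g) {
    out <- list()
    for (j in seq_len(g$n_ex - 1L)) {
      ee <- g$exon_iv[j, 2L]                      # exon end = junction
      is_ <- ee; ie <- g$exon_iv[j + 1L, 1L]      # intron sense interval
      out[[length(out) + 1L]] <- list(junction = j, type = "donor",
                                      span = c(ee - 3L, ee + 6L), motif = g$donors[j])
      out[[length(out) + 1L]] <- list(junction = j, type = "acceptor",
                                      span = c(ie - 20L, ie + 3L), motif = g$acceptors[j])
    }
    out
  }

  reserve <- function(g, span, pad = 25L) {
    g$used <- rbind(g$used, c(span[1L] - pad, span[2L] + pad))
    g
  }
  # reserved intervals already carry their pad; queries use the bare span
  is_free <- function(g, span) {
    if (nrow(g$used) == 0L) return(TRUE)
    !any(g$used[, 1L] < span[2L] & g$used[, 2L] > span[1L])
  }

  variants <- list()
  add_variant <- function(gene_idx, sense_pos0, sense_ref, sense_alt, category,
                          region_label, outcome) {
    list(gene_idx = gene_idx, sense_pos0 = sense_pos0, sense_ref = sense_ref,
         sense_alt = sense_alt, category = category, region_label = region_label,
         outcome = outcome)
  }

  # ---- planted-gain recipes (modify gene sequence, then add restoring SNV) --
  plant_gain <- function(gene_idx, where = c("intron", "exon")) {
    where <- match.arg(where)
    g <- genes[[gene_idx]]
    for (try in 1:25) {
      site_type <- sample(c("donor", "acceptor"), 1L)
      model <- models[[site_type]]
      k <- model$motif_length
      slots <- list()
      # clearance 26 keeps the plant's padded reservation and its scoring
      # windows away from the junction motifs
      if (where == "intron") {
        for (j in seq_len(g$n_ex - 1L)) {
          is_ <- g$exon_iv[j, 2L]; ie <- g$exon_iv[j + 1L, 1L]
          lo <- is_ + 6L + 26L; hi <- ie - 20L - 26L - k
          if (hi >= lo) slots[[length(slots) + 1L]] <- c(lo, hi)
        }
      } else {
        for (j in seq_len(g$n_ex)) {
          lo <- g$exon_iv[j, 1L] + 3L + 26L; hi <- g$exon_iv[j, 2L] - 3L - 26L - k
          if (hi >= lo) slots[[length(slots) + 1L]] <- c(lo, hi)
        }
      }
      if (length(slots) == 0L) next
      slot <- slots[[sample.int(length(slots), 1L)]]
      p <- if (slot[1L] >= slot[2L]) slot[1L] else sample(slot[1L]:slot[2L], 1L)
      if (!is_free(g, c(p, p + k))) next
      target <- sample_site_motif(model, spec$gain_motif_min)
      if (score_motif(model, target) < spec$gain_motif_min) next
      co <- model$consensus_offsets + 1L
      jm <- sample(co, 1L)                # break the consensus dinucleotide
      cur <- substr(target, jm, jm)
      planted <- target
      substr(planted, jm, jm) <- sample(setdiff(DNA_BASES, cur), 1L)
      sense <- g$sense
      substr(sense, p + 1L, p + k) <- planted
      vpos <- p + jm - 1L                 # 0-based sense position of the SNV
      # self-check by direct scoring: the restoring SNV must create a window
      # that beats everything on the reference haplotype and clears the high
      # gain cut; the other site type must not already fire on either strand.
      alt_sense <- sense
      substr(alt_sense, vpos + 1L, vpos + 1L) <- cur
      ref_max <- local_window_max(model, sense, vpos)
      alt_max <- local_window_max(model, alt_sense, vpos)
      other <- models[[setdiff(c("donor", "acceptor"), site_type)]]
      other_max <- max(local_window_max(other, sense, vpos),
                       local_window_max(other, alt_sense, vpos))
      if (alt_max > t$low_alt_cut && ref_max < alt_max && other_max <= t$low_alt_cut) {
        g$sense <- sense
        g <- reserve(g, c(p, p + k))
        genes[[gene_idx]] <<- g
        return(add_variant(gene_idx, vpos, substr(planted, jm, jm), cur,
                           if (where == "intron") "deep_intronic_gain" else "exonic_gain",
                           if (where == "intron") "intronic_other" else "exonic",
                           "aberrant"))
      }
    }
    NULL
  }

  n_int <- spec$counts$deep_intronic_gain
  n_exo <- spec$counts$exonic_gain
  gain_specs <- c(rep("intron", n_int), rep("exon", n_exo))
  gene_cycle <- rep(seq_len(spec$n_genes), length.out = length(gain_specs) * 3L)
  ci <- 0L
  for (w in gain_specs) {
    v <- NULL
    while (is.null(v) && ci < length(gene_cycle)) {
      ci <- ci + 1L
      v <- plant_gain(gene_cycle[ci], w)
    }
    if (is.null(v)) {
      stop("gain recipe infeasible for category ",
           if (w == "intron") "deep_intronic_gain" else "exonic_gain",
           " with the given length ranges", call. = FALSE)
    }
    variants[[length(variants) + 1L]] <- v
  }

  # ---- native-site recipes --------------------------------------------------
  site_pool <- list()
  for (gi in seq_len(spec$n_genes)) {
    for (s in gene_sites(genes[[gi]])) {
      s$gene_idx <- gi
      site_pool[[length(site_pool) + 1L]] <- s
    }
  }
  site_pool <- site_pool[sample.int(length(site_pool))]
  pool_take <- function(type) {
    for (i in seq_along(site_pool)) {
      s <- site_pool[[i]]
      if (!is.null(s) && s$type == type && is_free(genes[[s$gene_idx]], s$span)) {
        site_pool[[i]] <<- NULL
        return(s)
      }
    }
    stop("recipe infeasible: ran out of unused ", type, " sites", call. = FALSE)
  }

  native_recipe <- function(type, dinuc) {
    s <- pool_take(type)
    g <- genes[[s$gene_idx]]
    model <- models[[type]]
    offsets <- if (dinuc) model$consensus_offsets else {
      setdiff(0:(model$motif_length - 1L), model$consensus_offsets)
    }
    o <- if (length(offsets) == 1L) offsets else sample(offsets, 1L)
    motif <- substr(g$sense, s$span[1L] + 1L, s$span[2L])
    cur <- substr(motif, o + 1L, o + 1L)
    alt_base <- if (dinuc) sample(setdiff(DNA_BASES, cur), 1L)
                else weakest_base(model, o + 1L, cur)
    altmotif <- motif
    substr(altmotif, o + 1L, o + 1L) <- alt_base
    ref_score <- score_motif(model, motif)
    alt_score <- score_motif(model, altmotif)
    outcome <- if (dinuc) "aberrant" else {
      if (loss_priority_direct(ref_score, alt_score, t) %in% c("high", "moderate"))
        "aberrant" else "normal"
    }
    region <- paste0(type, if (dinuc) "_dinucleotide" else "_other")
    genes[[s$gene_idx]] <<- reserve(g, s$span)
    add_variant(s$gene_idx, s$span[1L] + o, cur, alt_base,
                if (dinuc) paste0(type, "_dinucleotide_loss") else "near_site_weakening",
                region, outcome)
  }

  for (i in seq_len(spec$counts$donor_dinucleotide_loss)) {
    variants[[length(variants) + 1L]] <- native_recipe("donor", TRUE)
  }
  for (i in seq_len(spec$counts$acceptor_dinucleotide_loss)) {
    variants[[length(variants) + 1L]] <- native_recipe("acceptor", TRUE)
  }
  for (i in seq_len(spec$counts$near_site_weakening)) {
    type <- if (i %% 2L == 1L) "donor" else "acceptor"
    variants[[length(variants) + 1L]] <- native_recipe(type, FALSE)
  }

  # ---- neutral recipe -------------------------------------------------------
  all_motif_spans <- lapply(seq_len(spec$n_genes), function(gi) {
    do.call(rbind, lapply(gene_sites(genes[[gi]]), `[[`, "span"))
  })
  for (i in seq_len(spec$counts$neutral)) {
    placed <- FALSE
    for (try in 1:200) {
      gi <- sample.int(spec$n_genes, 1L)
      g <- genes[[gi]]
      p <- sample(30:(g$length - 31L), 1L)
      spans <- all_motif_spans[[gi]]
      in_motif <- !is.null(spans) &&
        any(spans[, 1L] - 4L <= p & p < spans[, 2L] + 4L)
      if (in_motif || !is_free(g, c(p, p + 1L))) next
      cur <- substr(g$sense, p + 1L, p + 1L)
      alt_base <- sample(setdiff(DNA_BASES, cur), 1L)
      alt_sense <- g$sense
      substr(alt_sense, p + 1L, p + 1L) <- alt_base
      ok <- TRUE
      for (m in models) {
        if (local_window_max(m, g$sense, p) >= t$high_alt_cut ||
            local_window_max(m, alt_sense, p) >= t$high_alt_cut) { ok <- FALSE; break }
      }
      if (!ok) next
      in_exon <- any(g$exon_iv[, 1L] <= p & p < g$exon_iv[, 2L])
      genes[[gi]] <- reserve(g, c(p, p + 1L))
      variants[[length(variants) + 1L]] <-
        add_variant(gi, p, cur, alt_base, "neutral",
                    if (in_exon) "exonic" else "intronic_other", "normal")
      placed <- TRUE
      break
    }
    if (!placed) stop("recipe infeasible: could not place a neutral variant",
                      call. = FALSE)
  }

  # ---- genomic placement ----------------------------------------------------
  chrom_names <- sprintf("chr%d", seq_len(spec$n_chroms))
  chrom_parts <- stats::setNames(rep(list(character(0)), spec$n_chroms), chrom_names)
  chrom_cursor <- stats::setNames(rep(0L, spec$n_chroms), chrom_names)
  for (gi in seq_len(spec$n_genes)) {
    g <- genes[[gi]]
    cn <- chrom_names[((gi - 1L) %% spec$n_chroms) + 1L]
    gap <- rand_range(spec$gene_gap)
    chrom_parts[[cn]] <- c(chrom_parts[[cn]], sample_bg(gap))
    g0 <- chrom_cursor[[cn]] + gap
    gseq <- if (g$strand == "+") g$sense else revcomp(g$sense)
    chrom_parts[[cn]] <- c(chrom_parts[[cn]], gseq)
    chrom_cursor[[cn]] <- g0 + g$length
    genes[[gi]]$chrom <- cn
    genes[[gi]]$g0 <- g0
  }
  for (cn in chrom_names) {
    chrom_parts[[cn]] <- c(chrom_parts[[cn]], sample_bg(300L))
  }
  genome <- vapply(chrom_parts, paste, character(1), collapse = "")

  sense_to_genomic0 <- function(g, sp0) {
    if (g$strand == "+") g$g0 + sp0 else g$g0 + g$length - 1L - sp0
  }
  exon_to_genomic <- function(g, iv) {
    if (g$strand == "+") c(g$g0 + iv[1L], g$g0 + iv[2L])
    else c(g$g0 + g$length - iv[2L], g$g0 + g$length - iv[1L])
  }

  transcripts <- lapply(genes, function(g) {
    ex <- t(apply(g$exon_iv, 1L, function(iv) exon_to_genomic(g, iv)))
    transcript_model(g$tx, g$chrom, g$strand, ex)
  })
  names(transcripts) <- vapply(transcripts, `[[`, character(1), "transcript_id")

  vrows <- lapply(variants, function(v) {
    g <- genes[[v$gene_idx]]
    gpos0 <- sense_to_genomic0(g, v$sense_pos0)
    ref <- if (g$strand == "+") v$sense_ref else complement_seq(v$sense_ref)
    alt <- if (g$strand == "+") v$sense_alt else complement_seq(v$sense_alt)
    data.frame(chrom = g$chrom, pos = gpos0 + 1L, ref = ref, alt = alt,
               transcript_id = g$tx, region_label = v$region_label,
               assay_outcome = v$outcome, category = v$category,
               stringsAsFactors = FALSE)
  })
  vdf <- do.call(rbind, vrows)
  vdf <- vdf[order(match(vdf$chrom, chrom_names), vdf$pos), ]
  rownames(vdf) <- NULL

  # ---- write files ----------------------------------------------------------
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gtf = file.path(dir, "annotation.gtf"),
                vcf = file.path(dir, "variants.vcf"),
                truth = file.path(dir, "truth.tsv"))
  write_fixture_fasta(genome, paths$fasta)
  write_fixture_gtf(genes, paths$gtf)
  write_fixture_vcf(vdf, genome, paths$vcf)
  utils::write.table(vdf[, c("chrom", "pos", "ref", "alt", "transcript_id",
                             "region_label", "assay_outcome")],
                     paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)

  list(paths = paths, genome = genome, transcripts = transcripts,
       variants = vdf, truth = vdf, genes = genes)
}

write_fixture_fasta <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(genome)) {
    writeLines(paste0(">", cn), con)
    s <- genome[[cn]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

write_fixture_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', g$id, g$tx)
    ex <- t(apply(g$exon_iv, 1L, function(iv) {
      if (g$strand == "+") c(g$g0 + iv[1L], g$g0 + iv[2L])
      else c(g$g0 + g$length - iv[2L], g$g0 + g$length - iv[1L])
    }))
    lines <- c(lines, sprintf("%s\tmesplice_fixture\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, min(ex[, 1L]) + 1L, max(ex[, 2L]), g$strand, attrs))
    for (r in seq_len(nrow(ex))) {
      lines <- c(lines, sprintf("%s\tmesplice_fixture\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, ex[r, 1L] + 1L, ex[r, 2L], g$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

write_fixture_vcf <- function(vdf, genome, path) {
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                  vdf$chrom, vdf$pos, vdf$ref, vdf$alt)
  writeLines(c(header, body), path)
  invisible(path)
}
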