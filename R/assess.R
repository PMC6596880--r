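# The three score sets computed per (variant, transcript):
#   1. native-site reference/alternate scores (loss of a native site),
#   2. MES-SWA sliding-window results with frame-matched reference comparison
#      (de novo / cryptic gain, and loss for indels overlapping native sites),
#   3. MES-NCSS nearest-canonical-splice-site scores (competition baseline).
# The diff sign convention is uniform: diff = reference comparison minus
# alternate, so diff > 0 predicts loss and diff < 0 predicts gain.

site_k <- function(site_type) if (site_type == "donor") 9L else 23L

#' Score native splice sites overlapped by a variant
#'
#' For every native site whose motif span intersects the variant's reference
#' span: the reference score comes from the unmutated motif and the alternate
#' score from the motif with the variant applied. For length-changing
#' variants the alternate motif is re-anchored at the exon/intron boundary on
#' the alternate haplotype; if the edit removes the boundary itself, the
#' alternate score falls back to the best sliding-window score over the
#' former site and the record is flagged `native_alt_from_swa`.
#'
#' @param v a [normalize_variant] result.
#' @param tx a [transcript_model].
#' @param genome named character vector from [load_genome].
#' @param models list with `donor` and `acceptor` [splice_model]s.
#' @return list of records: `site`, `ref_score`, `alt_score`,
#'   `diff` (= ref - alt), `flags`. Empty list if no native site is
#'   overlapped (not an error).
#' @export
score_native_sites <- function(v, tx, genome, models) {
  sites <- native_sites(tx)
  sp <- variant_span0(v)
  out <- list()
  for (site in sites) {
    if (!(sp[1L] < site$span0[2L] && sp[2L] > site$span0[1L])) next
    k <- site_k(site$site_type)
    model <- models[[site$site_type]]
    ref_seq <- site_sequence(genome, site)
    ref_score <- score_motif(model, ref_seq)
    flags <- character(0)

    if (nchar(v$ref) == nchar(v$alt)) {
      # length-preserving: same genomic span on the alt haplotype
      slabs <- build_slabs(genome, site$chrom, site$strand, v, k)
      alt_seq <- slab_subseq_genomic(slabs, "alt", site$span0, delta = 0L)
      if (is.null(alt_seq) || has_ambiguous(alt_seq)) {
        alt_score <- NA_real_
        flags <- c(flags, "assessment_unavailable")
      } else {
        alt_score <- score_motif(model, alt_seq)
      }
    } else {
      anchored <- substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
      del_iv <- c(v$pos, v$pos - 1L + nchar(v$ref))  # 0-based deleted/edited span excl anchor
      boundary_removed <- v$variant_class == "deletion" && anchored &&
        site$boundary0 > del_iv[1L] && site$boundary0 < del_iv[2L]
      if (boundary_removed || !anchored) {
        swa <- run_swa(v, tx, genome, models, site$site_type)
        alt_score <- swa$alt_best$score
        flags <- c(flags, "native_alt_from_swa")
      } else {
        alt_seq <- native_alt_motif(genome, site, v, k)
        if (is.null(alt_seq) || has_ambiguous(alt_seq)) {
          alt_score <- NA_real_
          flags <- c(flags, "assessment_unavailable")
        } else {
          alt_score <- score_motif(model, alt_seq)
        }
      }
    }
    out[[length(out) + 1L]] <- list(site = site, ref_score = ref_score,
                                    alt_score = alt_score,
                                    diff = ref_score - alt_score, flags = flags)
  }
  out
}

# Extract a genomic interval from a slab haplotype, sense strand. `delta`
# shifts the interval through the edit (positions 3' of an insertion shift by
# +len, of a deletion by -len, in genomic coordinates).
slab_subseq_genomic <- function(slabs, haplotype, span0, delta = 0L) {
  h <- slabs[[haplotype]]
  if (slabs$strand == "+") {
    ps <- span0[1L] - slabs$start0 + delta
    pe <- span0[2L] - slabs$start0 + delta
    sense_start <- ps; sense_end <- pe
  } else {
    n <- nchar(h$seq)
    # plus-coordinate interval within the slab, then flip to sense
    ps <- span0[1L] - slabs$start0 + delta
    pe <- span0[2L] - slabs$start0 + delta
    sense_start <- n - pe; sense_end <- n - ps
  }
  if (sense_start < 0L || sense_end > nchar(h$seq)) return(NULL)
  substr(h$seq, sense_start + 1L, sense_end)
}

# Alternate-haplotype native motif re-anchored at the exon/intron boundary.
native_alt_motif <- function(genome, site, v, k) {
  slabs <- build_slabs(genome, site$chrom, site$strand, v, k)
  len_delta <- nchar(v$alt) - nchar(v$ref)
  b0 <- site$boundary0
  # project the boundary through the edit (plus-strand genomic coordinates;
  # edited bases start after the anchor at pos0)
  edit0 <- v$pos  # first base after the anchor, 0-based
  b0_alt_delta <- if (b0 > edit0) len_delta else 0L
  # motif span around the projected boundary, sense-strand geometry
  if (site$site_type == "donor") {
    span_alt <- if (site$strand == "+") c(b0 - 3L, b0 + 6L) else c(b0 - 6L, b0 + 3L)
  } else {
    span_alt <- if (site$strand == "+") c(b0 - 20L, b0 + 3L) else c(b0 - 3L, b0 + 20L)
  }
  slab_subseq_genomic(slabs, "alt", span_alt, delta = b0_alt_delta)
}

#' Run the sliding-window assessment (MES-SWA)
#'
#' Scores every k-mer window containing the allele on both haplotypes and
#' reports the best alternate window, the best reference window, and the
#' frame-matched reference comparison. For SNVs the comparison score is the
#' reference window at the best alternate window's frame and
#' `diff = ref_comp - alt_best`. For all other variants the frame of the best
#' reference window is projected through the edit onto the alternate
#' haplotype and `diff = ref_best - alt_comp`. Either way diff < 0 predicts
#' gain. Ties among equal-scoring windows resolve to the 5'-most frame.
#'
#' @inheritParams score_native_sites
#' @param site_type "donor" (9-mer windows) or "acceptor" (23-mer).
#' @return object of class `swa_result`: `site_type`, `alt_best`, `ref_best`
#'   (each list(frame, seq, score)), `ref_comp`, `alt_comp`, `diff`, `flags`.
#' @export
run_swa <- function(v, tx, genome, models, site_type = c("donor", "acceptor")) {
  site_type <- match.arg(site_type)
  k <- site_k(site_type)
  model <- models[[site_type]]
  flags <- character(0)

  slabs <- build_slabs(genome, tx$chrom, tx$strand, v, k)
  ena <- enumerate_windows(slabs$alt, k)
  enr <- enumerate_windows(slabs$ref, k)
  if (length(ena$missing_frames) > 0L || length(enr$missing_frames) > 0L) {
    flags <- c(flags, "truncated")
  }
  if (ena$skipped_n > 0L || enr$skipped_n > 0L) {
    flags <- c(flags, "windows_skipped_N")
  }
  wa <- ena$windows; wr <- enr$windows
  unavailable <- list(site_type = site_type,
                      alt_best = list(frame = NA_integer_, seq = NA_character_,
                                      score = NA_real_),
                      ref_best = list(frame = NA_integer_, seq = NA_character_,
                                      score = NA_real_),
                      ref_comp = NA_real_, alt_comp = NA_real_, diff = NA_real_,
                      flags = unique(c(flags, "assessment_unavailable")))
  if (nrow(wa) == 0L || nrow(wr) == 0L) {
    return(structure(unavailable, class = "swa_result"))
  }
  wa$score <- score_motif(model, wa$seq)
  wr$score <- score_motif(model, wr$seq)
  ia <- which.max(wa$score)   # first maximum = 5'-most frame
  ir <- which.max(wr$score)
  alt_best <- list(frame = wa$frame[ia], seq = wa$seq[ia], score = wa$score[ia])
  ref_best <- list(frame = wr$frame[ir], seq = wr$seq[ir], score = wr$score[ir])

  if (v$variant_class == "SNV") {
    match_row <- which(wr$frame == alt_best$frame)
    if (length(match_row) == 0L) {
      ref_comp <- NA_real_
      flags <- c(flags, "ref_comp_unavailable")
    } else {
      ref_comp <- wr$score[match_row[1L]]
    }
    alt_comp <- alt_best$score
    diff <- ref_comp - alt_best$score
  } else {
    # project the 5' end of the best reference window through the edit
    rs <- wr$wstart[ir]
    as_ <- project_sense_coord(rs, slabs)
    alt_seq <- if (as_ >= 0L && as_ + k <= nchar(slabs$alt$seq)) {
      substr(slabs$alt$seq, as_ + 1L, as_ + k)
    } else NA_character_
    if (is.na(alt_seq) || has_ambiguous(alt_seq)) {
      alt_comp <- NA_real_
      flags <- c(flags, "alt_comp_unavailable")
    } else {
      alt_comp <- score_motif(model, alt_seq)
    }
    ref_comp <- ref_best$score
    diff <- ref_comp - alt_comp
  }
  structure(list(site_type = site_type, alt_best = alt_best, ref_best = ref_best,
                 ref_comp = ref_comp, alt_comp = alt_comp, diff = diff,
                 flags = flags),
            class = "swa_result")
}

# Project a reference-slab sense coordinate onto the alt slab: coordinates 5'
# of the edit are unchanged, those 3' shift by the length difference, and
# coordinates inside the edited span collapse to its 5' edge.
project_sense_coord <- function(c0, slabs) {
  if (c0 < slabs$edit_start) return(c0)
  if (c0 >= slabs$edit_ref_end) {
    return(c0 + (slabs$edit_alt_end - slabs$edit_ref_end))
  }
  slabs$edit_start
}

#' @method print swa_result
#' @export
print.swa_result <- function(x, ...) {
  cat(sprintf("<swa_result %s: alt_best %.2f @f%s, ref_best %.2f @f%s, ref_comp %.2f, diff %.2f%s>\n",
              x$site_type, x$alt_best$score, x$alt_best$frame, x$ref_best$score,
              x$ref_best$frame, x$ref_comp, x$diff,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Score the nearest canonical splice sites (MES-NCSS)
#'
#' For each of the four (direction, type) slots, finds the native site whose
#' motif span lies entirely upstream or downstream of the variant in
#' transcript orientation, nearest by genomic distance, scored on the
#' reference haplotype. Absent slots are NULL (absence is a value, not an
#' error).
#'
#' @inheritParams score_native_sites
#' @return object of class `ncss_result` with elements `upstream_donor`,
#'   `upstream_acceptor`, `downstream_donor`, `downstream_acceptor`; each is
#'   NULL or list(site, score, distance).
#' @export
run_ncss <- function(v, tx, genome, models) {
  sites <- native_sites(tx)
  sp <- variant_span0(v)
  slots <- list(upstream_donor = NULL, upstream_acceptor = NULL,
                downstream_donor = NULL, downstream_acceptor = NULL)
  for (site in sites) {
    if (sp[1L] < site$span0[2L] && sp[2L] > site$span0[1L]) next  # overlaps
    genomically_left <- site$span0[2L] <= sp[1L]
    upstream <- if (tx$strand == "+") genomically_left else !genomically_left
    dist <- if (genomically_left) sp[1L] - site$span0[2L] else site$span0[1L] - sp[2L]
    key <- paste0(if (upstream) "upstream_" else "downstream_", site$site_type)
    cur <- slots[[key]]
    if (is.null(cur) || dist < cur$distance) {
      slots[[key]] <- list(site = site,
                           score = score_motif(models[[site$site_type]],
                                               site_sequence(genome, site)),
                           distance = dist)
    }
  }
  structure(slots, class = "ncss_result")
}
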