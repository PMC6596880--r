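# Haplotype slab construction and scoring-window enumeration.
#
# All window work happens on the transcript sense strand: a genomic slab
# around the variant is cut out (reference, or reference with the alt allele
# applied), reverse-complemented once for minus-strand transcripts, and
# windows are enumerated so that the allele's first base slides from window
# position k down to position 1, i.e. from the 5'-most window to the 3'-most.

# Build ref and alt slabs around a variant, plus coordinate bookkeeping.
# Sense coordinates are 0-based within the slab.
build_slabs <- function(genome, chrom, strand, v, k) {
  pos0 <- v$pos - 1L
  lr <- nchar(v$ref); la <- nchar(v$alt)
  chrom_len <- nchar(genome[[chrom]])
  want_start0 <- pos0 - (k + 2L)
  want_end0 <- pos0 + lr + k + 2L
  start0 <- max(0L, want_start0)
  end0 <- min(chrom_len, want_end0)
  truncated <- (start0 > want_start0) || (end0 < want_end0)
  ref_slab <- extract_plus(genome, chrom, start0, end0)
  alt_slab <- paste0(substr(genome[[chrom]], start0 + 1L, pos0),
                     v$alt,
                     substr(genome[[chrom]], pos0 + lr + 1L, end0))

  # Allele intervals in plus-strand slab coordinates.
  a0 <- pos0 - start0
  ref_iv <- c(a0, a0 + lr)
  anchored <- substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
  alt_iv <- if (v$variant_class == "insertion" && anchored) {
    c(a0 + 1L, a0 + la)          # the inserted bases
  } else if (v$variant_class == "deletion" && anchored) {
    if (strand == "+") c(a0 + 1L, a0 + 2L) else c(a0, a0 + 1L)  # junction base, 3' in sense
  } else {
    c(a0, a0 + la)
  }

  flip <- function(slab, iv) {
    n <- nchar(slab)
    list(seq = revcomp(slab), iv = c(n - iv[2L], n - iv[1L]))
  }
  if (strand == "-") {
    r <- flip(ref_slab, ref_iv); a <- flip(alt_slab, alt_iv)
    ref_slab <- r$seq; ref_iv <- r$iv
    alt_slab <- a$seq; alt_iv <- a$iv
  }
  # Edit region in sense coordinates (for projecting frames across indels):
  # slabs are identical outside [edit_start, edit_*_end).
  if (strand == "+") {
    edit_start <- a0
    edit_ref_end <- a0 + lr
    edit_alt_end <- a0 + la
  } else {
    nref <- nchar(ref_slab); nalt <- nchar(alt_slab)
    edit_start <- nref - (a0 + lr)   # == nalt - (a0 + la)
    edit_ref_end <- nref - a0
    edit_alt_end <- nalt - a0
  }
  list(ref = list(seq = ref_slab, iv = ref_iv),
       alt = list(seq = alt_slab, iv = alt_iv),
       start0 = start0, end0 = end0, chrom_len = chrom_len, strand = strand,
       truncated = truncated,
       edit_start = edit_start, edit_ref_end = edit_ref_end,
       edit_alt_end = edit_alt_end)
}

# Enumerate k-windows of one slab overlapping the allele interval.
# Returns a data.frame(frame, wstart (sense slab coord), seq, n_skipped, ...).
enumerate_windows <- function(slab, k) {
  s0 <- slab$iv[1L]; s1 <- slab$iv[2L]
  m <- max(1L, s1 - s0)
  n <- nchar(slab$seq)
  frames <- integer(0); starts <- integer(0); seqs <- character(0)
  missing_frames <- integer(0); skipped_n <- 0L
  for (i in 0:(k + m - 2L)) {
    wstart <- s0 - (k - 1L) + i
    frame <- k - i     # window position (1..k) of the allele's first base
    if (wstart < 0L || wstart + k > n) {
      missing_frames <- c(missing_frames, frame)
      next
    }
    wseq <- substr(slab$seq, wstart + 1L, wstart + k)
    if (has_ambiguous(wseq)) {
      skipped_n <- skipped_n + 1L
      next
    }
    frames <- c(frames, frame); starts <- c(starts, wstart); seqs <- c(seqs, wseq)
  }
  list(windows = data.frame(frame = frames, wstart = starts, seq = seqs,
                            stringsAsFactors = FALSE),
       missing_frames = missing_frames, skipped_n = skipped_n)
}

#' Enumerate scoring windows around a variant
#'
#' Builds the local reference or alternate haplotype on the transcript sense
#' strand and returns every k-mer window in which at least one base of the
#' allele (for a pure deletion, the junction base immediately 3' of the
#' deleted span) occupies a window position. Frames are ordered so the
#' allele's first base moves from window position k down to 1; an SNV yields
#' exactly k windows. Windows containing ambiguous bases are omitted (counted
#' in `skipped_n`); windows falling off the chromosome end raise a
#' `truncated_windows` error listing the missing frames.
#'
#' @param genome named character vector from [load_genome].
#' @param tx a [transcript_model].
#' @param v a [normalize_variant] result overlapping the transcript.
#' @param k window size: 9 (donor) or 23 (acceptor).
#' @param haplotype "ref" or "alt".
#' @return data.frame with columns `frame`, `start0` (genomic 0-based window
#'   start), and `seq` (sense-strand k-mer); attributes `skipped_n` and
#'   `missing_frames`.
#' @export
window_sequences <- function(genome, tx, v, k, haplotype = c("ref", "alt")) {
  haplotype <- match.arg(haplotype)
  stopifnot(k %in% c(9L, 23L))
  slabs <- build_slabs(genome, tx$chrom, tx$strand, v, k)
  en <- enumerate_windows(slabs[[haplotype]], k)
  if (length(en$missing_frames) > 0L) {
    stop(structure(class = c("truncated_windows", "error", "condition"),
                   list(message = sprintf(
                     "windows truncated at chromosome edge for %s:%d (missing frames: %s)",
                     v$chrom, v$pos, paste(en$missing_frames, collapse = ",")),
                     call = NULL)))
  }
  w <- en$windows
  # sense slab coordinate -> genomic 0-based window start
  slab_len <- nchar(slabs[[haplotype]]$seq)
  w$start0 <- if (tx$strand == "+") slabs$start0 + w$wstart
              else slabs$start0 + (slab_len - (w$wstart + k))
  attr(w, "skipped_n") <- en$skipped_n
  attr(w, "missing_frames") <- en$missing_frames
  w[, c("frame", "start0", "seq")]
}
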