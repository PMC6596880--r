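# Transcript models and native splice-site geometry.
#
# Internal coordinates are 0-based half-open throughout; file interfaces
# (GTF/GFF3, VCF) keep their native 1-based inclusive conventions. Exons are
# stored genomically ascending; transcript (5'->3') orientation is derived
# from the strand where needed, so minus-strand handling is a single reverse
# complement at sequence extraction and nowhere else.

#' Construct a transcript model
#'
#' @param transcript_id identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix of 0-based half-open genomic exon intervals
#'   (any row order; stored sorted ascending). Exons must not overlap.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand, exons) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start0", "end0")))
  if (nrow(exons) < 1L) stop("transcript needs at least one exon", call. = FALSE)
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("exon with non-positive width (coordinate inversion?) in ", transcript_id,
         call. = FALSE)
  }
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("overlapping exons in transcript ", transcript_id, call. = FALSE)
  }
  structure(list(transcript_id = transcript_id, chrom = chrom, strand = strand,
                 exons = exons),
            class = "transcript_model")
}

#' @method print transcript_model
#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s %s:%d-%d (%s), %d exon(s)>\n",
              x$transcript_id, x$chrom, x$exons[1L, 1L] + 1L,
              x$exons[nrow(x$exons), 2L], x$strand, nrow(x$exons)))
  invisible(x)
}

tx_span0 <- function(tx) c(tx$exons[1L, 1L], tx$exons[nrow(tx$exons), 2L])

# Exon rows in transcript (5'->3') orientation.
tx_exon_order <- function(tx) {
  if (tx$strand == "+") seq_len(nrow(tx$exons)) else rev(seq_len(nrow(tx$exons)))
}

# Genomic intron intervals (0-based half-open), ascending.
tx_introns <- function(tx) {
  E <- nrow(tx$exons)
  if (E < 2L) return(matrix(integer(0), ncol = 2L))
  cbind(tx$exons[-E, 2L], tx$exons[-1L, 1L])
}

#' Parse transcripts from a GTF or GFF3 file
#'
#' Exon features are grouped by `transcript_id` (GTF) or `Parent` (GFF3).
#' Exonless transcripts (declared but without exon features) are skipped with
#' a warning; coordinate inversions are a parse error.
#'
#' @param path GTF or GFF3 file.
#' @return named list of [transcript_model]s, ordered by transcript id.
#' @export
parse_transcripts <- function(path) {
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  is_exon <- types == "exon"
  ids <- if ("transcript_id" %in% colnames(md)) {
    as.character(md$transcript_id)
  } else if ("Parent" %in% colnames(md)) {
    vapply(md$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else sub("^transcript:", "", p[[1L]])
    }, character(1))
  } else {
    stop(path, ": no transcript_id or Parent attribute on features", call. = FALSE)
  }
  declared <- unique(ids[types %in% c("transcript", "mRNA") & !is.na(ids)])
  exon_ids <- ids[is_exon]
  if (any(is.na(exon_ids))) {
    stop(path, ": exon feature without a transcript identifier", call. = FALSE)
  }
  orphans <- setdiff(declared, unique(exon_ids))
  if (length(orphans) > 0L) {
    warning("skipping exonless transcript(s): ", paste(orphans, collapse = ", "))
  }
  exons <- gr[is_exon]
  out <- list()
  for (id in sort(unique(exon_ids))) {
    sel <- exons[exon_ids == id]
    strands <- unique(as.character(BiocGenerics::strand(sel)))
    chroms <- unique(as.character(GenomicRanges::seqnames(sel)))
    if (length(strands) != 1L || length(chroms) != 1L) {
      stop(path, ": transcript ", id, " spans multiple chromosomes or strands",
           call. = FALSE)
    }
    out[[id]] <- transcript_model(
      id, chroms, strands,
      cbind(BiocGenerics::start(sel) - 1L, BiocGenerics::end(sel)))
  }
  out
}

#' Native splice sites of a transcript
#'
#' A transcript with E exons has E-1 donors and E-1 acceptors. On the
#' transcript sense strand the donor motif covers the last 3 exonic plus the
#' first 6 intronic nucleotides (9-mer) and the acceptor motif the last 20
#' intronic plus the first 3 exonic nucleotides (23-mer). Sites whose
#' intronic context does not fit in the intron (introns shorter than 6 nt for
#' donors, 20 nt for acceptors) are omitted; the number omitted is recorded in
#' the `omitted` attribute.
#'
#' @param tx a [transcript_model].
#' @return list of native-site records (`transcript_id`, `site_type`,
#'   `span0` = genomic 0-based half-open motif interval, `exon_index` in
#'   transcript orientation, `chrom`, `strand`, `boundary0` = the genomic
#'   coordinate of the exon/intron junction point).
#' @export
native_sites <- function(tx) {
  stopifnot(inherits(tx, "transcript_model"))
  ord <- tx_exon_order(tx)
  E <- length(ord)
  sites <- list()
  omitted <- 0L
  if (E < 2L) return(structure(list(), omitted = 0L))
  for (i in seq_len(E - 1L)) {
    ue <- tx$exons[ord[i], ]        # transcript-upstream exon
    de <- tx$exons[ord[i + 1L], ]   # transcript-downstream exon
    intron_len <- if (tx$strand == "+") de[1L] - ue[2L] else ue[1L] - de[2L]
    if (tx$strand == "+") {
      donor_span <- c(ue[2L] - 3L, ue[2L] + 6L)
      donor_bnd <- ue[2L]
      acc_span <- c(de[1L] - 20L, de[1L] + 3L)
      acc_bnd <- de[1L]
    } else {
      donor_span <- c(ue[1L] - 6L, ue[1L] + 3L)
      donor_bnd <- ue[1L]
      acc_span <- c(de[2L] - 3L, de[2L] + 20L)
      acc_bnd <- de[2L]
    }
    if (intron_len >= 6L) {
      sites[[length(sites) + 1L]] <- list(
        transcript_id = tx$transcript_id, site_type = "donor",
        span0 = as.integer(donor_span), exon_index = i, chrom = tx$chrom,
        strand = tx$strand, boundary0 = as.integer(donor_bnd))
    } else omitted <- omitted + 1L
    if (intron_len >= 20L) {
      sites[[length(sites) + 1L]] <- list(
        transcript_id = tx$transcript_id, site_type = "acceptor",
        span0 = as.integer(acc_span), exon_index = i + 1L, chrom = tx$chrom,
        strand = tx$strand, boundary0 = as.integer(acc_bnd))
    } else omitted <- omitted + 1L
  }
  structure(sites, omitted = omitted)
}

# Genomic 0-based position of a 0-based motif offset (transcript sense).
site_offset_pos0 <- function(site, offset) {
  if (site$strand == "+") site$span0[1L] + offset else site$span0[2L] - 1L - offset
}

# Extract the sense-strand motif sequence of a native site.
site_sequence <- function(genome, site) {
  extract_sense(genome, site$chrom, site$span0[1L], site$span0[2L], site$strand)
}

# ---- genome access ----------------------------------------------------------

#' Load a FASTA genome as named character strings
#' @param path FASTA file.
#' @return named character vector, one element per sequence.
#' @export
load_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- as.character(ss)
  names(g) <- sub("\\s.*$", "", names(ss))
  toupper(g)
}

# Plus-strand substring, 0-based half-open; errors outside the chromosome.
extract_plus <- function(genome, chrom, start0, end0) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom, call. = FALSE)
  if (start0 < 0L || end0 > nchar(seq)) {
    stop(sprintf("interval [%d,%d) outside chromosome %s (length %d)",
                 start0, end0, chrom, nchar(seq)), call. = FALSE)
  }
  substr(seq, start0 + 1L, end0)
}

extract_sense <- function(genome, chrom, start0, end0, strand) {
  s <- extract_plus(genome, chrom, start0, end0)
  if (strand == "-") revcomp(s) else s
}
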