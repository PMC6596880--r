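# End-to-end annotation: VCF + GTF/GFF3 + FASTA in, annotated VCF + TSV out.

MES_INFO_KEYS <- c(
  "MES_TX", "MES_REF", "MES_ALT", "MES_DIFF",
  "MES_SWA_DONOR_ALT", "MES_SWA_DONOR_REF", "MES_SWA_DONOR_REF_COMP",
  "MES_SWA_DONOR_DIFF",
  "MES_SWA_ACCEPTOR_ALT", "MES_SWA_ACCEPTOR_REF", "MES_SWA_ACCEPTOR_REF_COMP",
  "MES_SWA_ACCEPTOR_DIFF",
  "MES_NCSS_UP_DONOR", "MES_NCSS_UP_ACCEPTOR",
  "MES_NCSS_DOWN_DONOR", "MES_NCSS_DOWN_ACCEPTOR",
  "MES_CALL", "MES_PRIORITY"
)

fmt2 <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.2f", x))
}

# One flat annotation record per (variant, transcript).
annotation_record <- function(v, tx, call, record = NA_integer_) {
  ev <- call$evidence
  native <- ev$native
  # report the native scores of the winning channel (or the first overlapped
  # site) for the MES_REF/ALT/DIFF columns
  ns <- NULL
  if (length(native) > 0L) {
    pick <- which(vapply(native, function(n) n$site$site_type, character(1)) ==
                  call$site_type)
    ns <- native[[if (length(pick) > 0L) pick[1L] else 1L]]
  }
  swa_cols <- function(st) {
    s <- ev$swa[[st]]
    stats::setNames(
      c(s$alt_best$score, s$ref_best$score, s$ref_comp, s$diff),
      paste0("swa_", st, c("_alt", "_ref", "_ref_comp", "_diff")))
  }
  ncss_cols <- local({
    vals <- vapply(c("upstream_donor", "upstream_acceptor",
                     "downstream_donor", "downstream_acceptor"),
                   function(k) {
                     x <- ev$ncss[[k]]
                     if (is.null(x)) NA_real_ else x$score
                   }, numeric(1))
    stats::setNames(vals, c("ncss_up_donor", "ncss_up_acceptor",
                            "ncss_down_donor", "ncss_down_acceptor"))
  })
  all_flags <- unique(c(call$flags,
                        unlist(lapply(native, `[[`, "flags")),
                        ev$swa$donor$flags, ev$swa$acceptor$flags))
  data.frame(
    record = record,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    variant_class = v$variant_class, transcript_id = tx$transcript_id,
    region = call$region_label, mechanism = call$mechanism,
    priority = call$priority, downgraded = isTRUE(call$downgraded),
    native_ref = if (is.null(ns)) NA_real_ else ns$ref_score,
    native_alt = if (is.null(ns)) NA_real_ else ns$alt_score,
    native_diff = if (is.null(ns)) NA_real_ else ns$diff,
    t(swa_cols("donor")), t(swa_cols("acceptor")), t(ncss_cols),
    flags = paste(all_flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Annotate a VCF with splice predictions
#'
#' Reads variants, transcript annotation and genome, assesses every
#' (variant, transcript) pair where the variant overlaps the transcript, and
#' optionally writes an annotated VCF (original records preserved, MES_*
#' INFO keys appended, per-transcript values pipe-delimited parallel to
#' MES_TX) and a TSV report with one row per (variant, transcript). Records
#' not overlapping any transcript pass through unannotated. A contig-name
#' consistency check across VCF, annotation and FASTA runs first.
#'
#' @param vcf_in input VCF path.
#' @param gtf transcript annotation (GTF or GFF3).
#' @param fasta reference genome FASTA.
#' @param models list with `donor` and `acceptor` [splice_model]s; defaults
#'   to [default_models()].
#' @param thresholds a [splice_thresholds].
#' @param out_vcf,out_tsv optional output paths.
#' @return invisibly, a list with `records` (the TSV data.frame) and
#'   `counts` (variants seen / annotated / skipped).
#' @export
annotate_variants <- function(vcf_in, gtf, fasta, models = default_models(),
                              thresholds = splice_thresholds(),
                              out_vcf = NULL, out_tsv = NULL) {
  genome <- load_genome(fasta)
  txs <- parse_transcripts(gtf)

  tx_chroms <- unique(vapply(txs, `[[`, character(1), "chrom"))
  bad_tx <- setdiff(tx_chroms, names(genome))
  if (length(bad_tx) > 0L) {
    stop("annotation contigs absent from FASTA: ", paste(bad_tx, collapse = ", "),
         call. = FALSE)
  }
  parsed <- read_vcf_variants(vcf_in, genome)

  rows <- list()
  for (vi in seq_along(parsed$variants)) {
    v <- parsed$variants[[vi]]
    rec <- parsed$record_index[vi]
    overlapping <- Filter(function(tx) {
      tx$chrom == v$chrom && variant_overlaps0(v, tx_span0(tx)[1L], tx_span0(tx)[2L])
    }, txs)
    if (length(overlapping) == 0L) next
    for (tx in overlapping[order(names(overlapping))]) {
      call <- assess_variant(v, tx, genome, models, thresholds)
      rows[[length(rows) + 1L]] <- annotation_record(v, tx, call, record = rec)
    }
  }
  records <- if (length(rows) > 0L) do.call(rbind, rows) else empty_records()
  counts <- list(seen = parsed$n_records,
                 annotated = length(unique(records$record)),
                 pairs = nrow(records),
                 skipped = parsed$n_skipped)

  if (!is.null(out_tsv)) write_report_tsv(records, out_tsv, thresholds)
  if (!is.null(out_vcf)) write_annotated_vcf(parsed, records, out_vcf)
  invisible(list(records = records, counts = counts))
}

empty_records <- function() {
  data.frame(record = integer(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), variant_class = character(0),
             transcript_id = character(0), region = character(0),
             mechanism = character(0), priority = character(0),
             downgraded = logical(0),
             native_ref = numeric(0), native_alt = numeric(0),
             native_diff = numeric(0),
             swa_donor_alt = numeric(0), swa_donor_ref = numeric(0),
             swa_donor_ref_comp = numeric(0), swa_donor_diff = numeric(0),
             swa_acceptor_alt = numeric(0), swa_acceptor_ref = numeric(0),
             swa_acceptor_ref_comp = numeric(0), swa_acceptor_diff = numeric(0),
             ncss_up_donor = numeric(0), ncss_up_acceptor = numeric(0),
             ncss_down_donor = numeric(0), ncss_down_acceptor = numeric(0),
             flags = character(0), stringsAsFactors = FALSE)
}

write_report_tsv <- function(records, path, thresholds) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# mesplice %s report; thresholds: high_alt_cut=%g low_alt_cut=%g downgrade_diff_cut=%g",
    as.character(utils::packageVersion("mesplice")),
    thresholds$high_alt_cut, thresholds$low_alt_cut,
    thresholds$downgrade_diff_cut), con)
  out <- records
  numcols <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("record", "pos"))
  for (j in which(numcols)) out[[j]] <- fmt2(out[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

write_annotated_vcf <- function(parsed, records, path) {
  vcf <- parsed$vcf
  meta <- vcf@meta
  # drop any MES_* INFO declarations from a previous run, then re-declare
  meta <- meta[!grepl("^##INFO=<ID=MES_", meta)]
  info_decl <- vapply(MES_INFO_KEYS, function(k) {
    type <- if (k %in% c("MES_TX", "MES_CALL", "MES_PRIORITY")) "String" else "String"
    desc <- switch(k,
      MES_TX = "Alt allele and transcript per annotation, as alt:transcript_id",
      MES_CALL = "Spliceogenicity mechanism per MES_TX entry",
      MES_PRIORITY = "Spliceogenicity priority per MES_TX entry",
      paste0(sub("MES_", "", k), " splice score per MES_TX entry"))
    sprintf('##INFO=<ID=%s,Number=.,Type=%s,Description="%s">', k, type, desc)
  }, character(1))
  # vcfR keeps only the ## lines in @meta; rebuild the #CHROM header line
  gt <- vcf@gt
  chrom_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO",
                        if (!is.null(gt) && ncol(gt) > 0L) colnames(gt)),
                      collapse = "\t")
  out_meta <- c(meta, unname(info_decl), chrom_line)

  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  lines <- character(nrow(fix))
  for (i in seq_len(max(nrow(fix), 0L))) {
    info <- fix[i, "INFO"]
    if (is.na(info) || info == "") info <- "."
    # strip MES_* keys from a previous run
    parts <- strsplit(info, ";", fixed = TRUE)[[1L]]
    parts <- parts[!grepl("^MES_", parts) & parts != "."]
    sel <- records[!is.na(records$record) & records$record == i, , drop = FALSE]
    if (nrow(sel) > 0L) {
      add <- c(
        sprintf("MES_TX=%s", paste0(sel$alt, ":", sel$transcript_id, collapse = "|")),
        sprintf("MES_REF=%s", paste(fmt2(sel$native_ref), collapse = "|")),
        sprintf("MES_ALT=%s", paste(fmt2(sel$native_alt), collapse = "|")),
        sprintf("MES_DIFF=%s", paste(fmt2(sel$native_diff), collapse = "|")),
        sprintf("MES_SWA_DONOR_ALT=%s", paste(fmt2(sel$swa_donor_alt), collapse = "|")),
        sprintf("MES_SWA_DONOR_REF=%s", paste(fmt2(sel$swa_donor_ref), collapse = "|")),
        sprintf("MES_SWA_DONOR_REF_COMP=%s",
                paste(fmt2(sel$swa_donor_ref_comp), collapse = "|")),
        sprintf("MES_SWA_DONOR_DIFF=%s", paste(fmt2(sel$swa_donor_diff), collapse = "|")),
        sprintf("MES_SWA_ACCEPTOR_ALT=%s", paste(fmt2(sel$swa_acceptor_alt), collapse = "|")),
        sprintf("MES_SWA_ACCEPTOR_REF=%s", paste(fmt2(sel$swa_acceptor_ref), collapse = "|")),
        sprintf("MES_SWA_ACCEPTOR_REF_COMP=%s",
                paste(fmt2(sel$swa_acceptor_ref_comp), collapse = "|")),
        sprintf("MES_SWA_ACCEPTOR_DIFF=%s",
                paste(fmt2(sel$swa_acceptor_diff), collapse = "|")),
        sprintf("MES_NCSS_UP_DONOR=%s", paste(fmt2(sel$ncss_up_donor), collapse = "|")),
        sprintf("MES_NCSS_UP_ACCEPTOR=%s", paste(fmt2(sel$ncss_up_acceptor), collapse = "|")),
        sprintf("MES_NCSS_DOWN_DONOR=%s", paste(fmt2(sel$ncss_down_donor), collapse = "|")),
        sprintf("MES_NCSS_DOWN_ACCEPTOR=%s",
                paste(fmt2(sel$ncss_down_acceptor), collapse = "|")),
        sprintf("MES_CALL=%s", paste(sel$mechanism, collapse = "|")),
        sprintf("MES_PRIORITY=%s", paste(sel$priority, collapse = "|"))
      )
      parts <- c(parts, add)
    }
    info_out <- if (length(parts) == 0L) "." else paste(parts, collapse = ";")
    fields <- c(fix[i, c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER")],
                info_out)
    fields[is.na(fields)] <- "."
    if (!is.null(gt) && ncol(gt) > 0L) {
      gtf_ <- gt[i, ]
      gtf_[is.na(gtf_)] <- "."
      fields <- c(fields, gtf_)
    }
    lines[i] <- paste(fields, collapse = "\t")
  }
  writeLines(c(out_meta, lines), path)
  invisible(path)
}

#' Batch-score k-mers
#'
#' Scores a stream of equal-length k-mers with the matching model. Mixed
#' lengths are an error naming the first offending entry.
#'
#' @param seqs character vector of k-mers (or a file path via `file`).
#' @param model a [splice_model].
#' @param file optional path to a file of one k-mer per line.
#' @return data.frame with `seq`, `score` (full precision) and `rendered`
#'   (2-decimal text).
#' @export
score_kmers <- function(seqs = NULL, model, file = NULL) {
  if (!is.null(file)) {
    seqs <- readLines(file)
    seqs <- seqs[nzchar(trimws(seqs))]
  }
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), score = numeric(0),
                      rendered = character(0), stringsAsFactors = FALSE))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    first_bad <- which(lens != lens[1L])[1L]
    stop(sprintf("mixed k-mer lengths: entry %d (%s) has length %d, expected %d",
                 first_bad, seqs[first_bad], lens[first_bad], lens[1L]),
         call. = FALSE)
  }
  sc <- score_motif(model, seqs)
  data.frame(seq = seqs, score = sc, rendered = sprintf("%.2f", sc),
             stringsAsFactors = FALSE)
}
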