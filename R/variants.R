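# Variant normalization: multi-allelic decomposition, parsimony trimming and
# left alignment against the reference genome.

#' Normalize a variant against the reference genome
#'
#' Applies the standard normalization used by variant tooling: verify REF
#' against the genome, trim shared flanking bases (extending left across
#' repeats so indels are left-aligned and parsimonious), and derive the
#' variant class. Symbolic alleles (`<DEL>`, breakends, `*`) are rejected with
#' an `unsupported_variant` condition so callers can skip the record.
#'
#' @param chrom,pos,ref,alt the VCF fields (pos 1-based).
#' @param genome named character vector from [load_genome].
#' @return object of class `normalized_variant`: `chrom`, `pos` (1-based
#'   position of the first ref base), `ref`, `alt`, `variant_class` (one of
#'   "SNV", "insertion", "deletion", "MNV").
#' @export
normalize_variant <- function(chrom, pos, ref, alt, genome) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  if (grepl("[<>\\[\\]]", alt) || alt %in% c("*", ".")) {
    stop(structure(class = c("unsupported_variant", "error", "condition"),
                   list(message = sprintf("symbolic or missing alt allele at %s:%d (%s)",
                                          chrom, pos, alt),
                        call = NULL)))
  }
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt)) {
    stop(structure(class = c("unsupported_variant", "error", "condition"),
                   list(message = sprintf("non-ACGT allele at %s:%d (%s>%s)",
                                          chrom, pos, ref, alt),
                        call = NULL)))
  }
  if (ref == alt) {
    stop(sprintf("ref and alt are identical at %s:%d (%s)", chrom, pos, ref),
         call. = FALSE)
  }
  gref <- extract_plus(genome, chrom, pos - 1L, pos - 1L + nchar(ref))
  if (gref != ref) {
    stop(sprintf("REF mismatch at %s:%d: VCF says %s, genome has %s",
                 chrom, pos, ref, gref), call. = FALSE)
  }
  # Right-trim with left extension (left alignment), then left-trim.
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L && (lr > 1L || la > 1L) &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      ref <- substr(ref, 1L, lr - 1L)
      alt <- substr(alt, 1L, la - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos <= 1L) {
          stop(sprintf("cannot left-align variant at start of chromosome %s", chrom),
               call. = FALSE)
        }
        b <- extract_plus(genome, chrom, pos - 2L, pos - 1L)
        ref <- paste0(b, ref); alt <- paste0(b, alt)
        pos <- pos - 1L
      }
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  lr <- nchar(ref); la <- nchar(alt)
  vclass <- if (lr == 1L && la == 1L) "SNV"
    else if (lr < la) "insertion"
    else if (lr > la) "deletion"
    else "MNV"
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 variant_class = vclass),
            class = "normalized_variant")
}

#' @method print normalized_variant
#' @export
print.normalized_variant <- function(x, ...) {
  cat(sprintf("<variant %s:%d %s>%s (%s)>\n", x$chrom, x$pos, x$ref, x$alt,
              x$variant_class))
  invisible(x)
}

# 0-based half-open genomic interval occupied by the ref allele.
variant_span0 <- function(v) {
  c(v$pos - 1L, v$pos - 1L + nchar(v$ref))
}

# Does the variant's ref span intersect a 0-based half-open interval?
variant_overlaps0 <- function(v, start0, end0) {
  sp <- variant_span0(v)
  sp[1L] < end0 && sp[2L] > start0
}

#' Read and normalize variants from a VCF file
#'
#' Multi-allelic records are decomposed into one normalized variant per alt
#' allele. Unsupported alleles (symbolic, breakend, non-ACGT) are skipped
#' with a warning and counted.
#'
#' @param path VCF file.
#' @param genome named character vector from [load_genome].
#' @return list with `variants` (list of [normalize_variant] results),
#'   `record_index` (input record number per variant), `n_records`,
#'   `n_skipped`, and the `vcfR` object as `vcf`.
#' @export
read_vcf_variants <- function(path, genome) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  bad <- setdiff(unique(fix[, "CHROM"]), names(genome))
  if (length(bad) > 0L) {
    stop("VCF contigs absent from FASTA: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  variants <- list(); record_index <- integer(0); n_skipped <- 0L
  n <- nrow(fix)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (alt in alts) {
      v <- tryCatch(
        normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                          fix[i, "REF"], alt, genome),
        unsupported_variant = function(e) {
          warning("skipping record ", i, ": ", conditionMessage(e), call. = FALSE)
          NULL
        })
      if (!is.null(v)) {
        variants[[length(variants) + 1L]] <- v
        record_index <- c(record_index, i)
      } else {
        n_skipped <- n_skipped + 1L
      }
    }
  }
  list(variants = variants, record_index = record_index, n_records = n,
       n_skipped = n_skipped, vcf = vcf)
}
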