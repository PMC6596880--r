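# Sensitivity/specificity evaluation of spliceogenicity calls against an
# assay truth table. A positive prediction is a high or moderate call (either
# mechanism); truth is the assay outcome (aberrant / normal).

#' Evaluate calls against a truth table
#'
#' Joins calls and truth on (chrom, pos, ref, alt, transcript_id), counts the
#' confusion matrix per region label and overall, and computes sensitivity
#' TP/(TP+FN) and specificity TN/(TN+FP). Cells with an empty denominator
#' are reported as NA (undefined), not zero. Unmatched records on either
#' side are excluded with a warning and listed in the `excluded` attribute.
#' The result is invariant to input row order.
#'
#' @param calls data.frame with columns chrom, pos, ref, alt, transcript_id,
#'   priority (e.g. the `records` element of [annotate_variants]).
#' @param truth data.frame with columns chrom, pos, ref, alt, transcript_id,
#'   region_label, assay_outcome ("aberrant" or "normal"); see
#'   [read_truth_tsv].
#' @return object of class `performance_report`: data.frame with one row per
#'   region label plus "overall" (columns region, tp, fp, tn, fn,
#'   sensitivity, specificity).
#' @export
evaluate_calls <- function(calls, truth) {
  need <- c("chrom", "pos", "ref", "alt", "transcript_id")
  stopifnot(all(need %in% names(calls)), "priority" %in% names(calls),
            all(need %in% names(truth)),
            all(c("region_label", "assay_outcome") %in% names(truth)))
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, d$transcript_id, sep = "\r")
  ck <- key(calls); tk <- key(truth)
  matched <- intersect(ck, tk)
  excl <- c(setdiff(ck, tk), setdiff(tk, ck))
  if (length(excl) > 0L) {
    warning(length(excl), " unmatched record(s) excluded from evaluation: ",
            paste(utils::head(gsub("\r", ":", excl), 5L), collapse = "; "),
            if (length(excl) > 5L) " ..." else "")
  }
  calls <- calls[match(matched, ck), , drop = FALSE]
  truth <- truth[match(matched, tk), , drop = FALSE]
  predicted <- calls$priority %in% c("high", "moderate")
  actual <- truth$assay_outcome == "aberrant"

  tally <- function(sel) {
    tp <- sum(predicted[sel] & actual[sel])
    fp <- sum(predicted[sel] & !actual[sel])
    tn <- sum(!predicted[sel] & !actual[sel])
    fn <- sum(!predicted[sel] & actual[sel])
    data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_)
  }
  regions <- sort(unique(truth$region_label))
  rows <- lapply(regions, function(r) {
    cbind(region = r, tally(truth$region_label == r))
  })
  rows[[length(rows) + 1L]] <- cbind(region = "overall",
                                     tally(rep(TRUE, length(predicted))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- gsub("\r", ":", excl)
  class(out) <- c("performance_report", class(out))
  out
}

#' @method print performance_report
#' @export
print.performance_report <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$sensitivity <- ifelse(is.na(y$sensitivity), "undefined",
                          sprintf("%.1f%%", 100 * y$sensitivity))
  y$specificity <- ifelse(is.na(y$specificity), "undefined",
                          sprintf("%.1f%%", 100 * y$specificity))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Read a truth table TSV
#'
#' Expected columns: chrom, pos, ref, alt, transcript_id, region_label,
#' assay_outcome. A header line is required.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_truth_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "pos", "ref", "alt", "transcript_id", "region_label",
            "assay_outcome")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0L) {
    stop(path, ": truth table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d
}
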