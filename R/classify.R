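# Spliceogenicity decision tree.
#
# Routing: variants overlapping a native splice-site motif are assessed for
# loss of that site (SNVs via the native ref/alt scores, indels via the
# sliding-window result); variants outside all native motifs are assessed for
# gain of a de novo or cryptic site. Loss tiers by the alternate score with a
# small-diff downgrade; gain tiers by the best alternate window score, with
# moderate gains additionally required to outcompete the nearest native site
# of the same type.

PRIORITY_LEVELS <- c(none = 0L, low = 1L, moderate = 2L, high = 3L)

#' Classification thresholds
#'
#' Log2-score cut-offs for the decision tree. Defaults are the ENIGMA
#' consortium values: `high_alt_cut` 6.2, `low_alt_cut` 8.5,
#' `downgrade_diff_cut` 1.15. For loss, alt below `high_alt_cut` is high
#' priority, alt in [high_alt_cut, low_alt_cut] moderate, above low; for
#' gain the direction reverses. Any other user-defined thresholds may be
#' supplied.
#'
#' @param high_alt_cut,low_alt_cut,downgrade_diff_cut numeric cut-offs;
#'   `high_alt_cut < low_alt_cut` and `downgrade_diff_cut > 0`.
#' @return object of class `splice_thresholds`.
#' @export
splice_thresholds <- function(high_alt_cut = 6.2, low_alt_cut = 8.5,
                              downgrade_diff_cut = 1.15) {
  if (!(high_alt_cut < low_alt_cut)) {
    stop("high_alt_cut must be below low_alt_cut", call. = FALSE)
  }
  if (!(downgrade_diff_cut > 0)) {
    stop("downgrade_diff_cut must be positive", call. = FALSE)
  }
  structure(list(high_alt_cut = high_alt_cut, low_alt_cut = low_alt_cut,
                 downgrade_diff_cut = downgrade_diff_cut),
            class = "splice_thresholds")
}

new_call <- function(mechanism, priority, downgraded = FALSE, site_type = NA_character_,
                     region_label = NA_character_, evidence = NULL, flags = character(0)) {
  if (priority == "none") mechanism <- "none"
  if (mechanism == "none") priority <- "none"
  structure(list(mechanism = mechanism, priority = priority,
                 downgraded = downgraded, site_type = site_type,
                 region_label = region_label, evidence = evidence, flags = flags),
            class = "spliceogenicity_call")
}

#' @method print spliceogenicity_call
#' @export
print.spliceogenicity_call <- function(x, ...) {
  cat(sprintf("<call %s/%s%s region=%s%s>\n", x$mechanism, x$priority,
              if (isTRUE(x$downgraded)) " (downgraded)" else "",
              x$region_label,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Classify native splice-site loss
#'
#' Loss requires diff > 0 (reference scores higher than alternate). The base
#' tier comes from the alternate score: below `high_alt_cut` high, between
#' the cuts (inclusive) moderate, above `low_alt_cut` low. When
#' diff < `downgrade_diff_cut`, high is downgraded to moderate and moderate
#' to low.
#'
#' @param scores either a record from [score_native_sites] (SNVs) or a
#'   [run_swa] result (indels overlapping a native site); alternatively pass
#'   `diff` and `alt` directly.
#' @param t a [splice_thresholds].
#' @param diff,alt optional explicit values overriding `scores`.
#' @return a `spliceogenicity_call`.
#' @export
classify_loss <- function(scores = NULL, t = splice_thresholds(),
                          diff = NULL, alt = NULL) {
  if (is.null(diff) || is.null(alt)) {
    if (inherits(scores, "swa_result")) {
      diff <- scores$diff
      # the alternate side of the stored diff: alt_comp (equals alt_best for SNVs)
      alt <- if (!is.null(scores$alt_comp) && !is.na(scores$alt_comp)) {
        scores$alt_comp
      } else {
        scores$alt_best$score
      }
    } else {
      diff <- scores$diff
      alt <- scores$alt_score
    }
  }
  if (is.na(diff) || is.na(alt)) {
    return(new_call("none", "none", flags = "assessment_unavailable",
                    evidence = scores))
  }
  if (diff <= 0) return(new_call("none", "none", evidence = scores))
  base <- if (alt < t$high_alt_cut) "high"
    else if (alt <= t$low_alt_cut) "moderate"
    else "low"
  downgraded <- FALSE
  if (diff < t$downgrade_diff_cut && base %in% c("high", "moderate")) {
    base <- if (base == "high") "moderate" else "low"
    downgraded <- TRUE
  }
  new_call("native_loss", base, downgraded = downgraded, evidence = scores)
}

#' Classify de novo / cryptic splice-site gain
#'
#' Gain requires diff < 0 (the alternate haplotype scores higher). The tier
#' comes from the best alternate window score: above `low_alt_cut` high,
#' between the cuts (inclusive) moderate, below `high_alt_cut` low. A
#' moderate candidate is kept at moderate only if it strictly outcompetes the
#' nearest native site of the same type (nearest by genomic distance over
#' both directions, from the MES-NCSS scores); otherwise it is demoted to
#' low. High candidates are not subjected to the competition test. When no
#' same-type native site exists the competition passes vacuously and the
#' call is flagged.
#'
#' @param swa a [run_swa] result.
#' @param ncss a [run_ncss] result.
#' @param t a [splice_thresholds].
#' @return a `spliceogenicity_call`.
#' @export
classify_gain <- function(swa, ncss, t = splice_thresholds()) {
  diff <- swa$diff
  alt <- swa$alt_best$score
  flags <- character(0)
  ev <- list(swa = swa, ncss = ncss)
  if (is.na(diff) || is.na(alt)) {
    return(new_call("none", "none", site_type = swa$site_type,
                    flags = "assessment_unavailable", evidence = ev))
  }
  if (diff >= 0) return(new_call("none", "none", site_type = swa$site_type,
                                 evidence = ev))
  if (alt > t$low_alt_cut) {
    priority <- "high"
  } else if (alt >= t$high_alt_cut) {
    competitor <- nearest_same_type(ncss, swa$site_type)
    if (is.null(competitor)) {
      priority <- "moderate"
      flags <- c(flags, "no_native_competitor")
    } else {
      priority <- if (alt > competitor$score) "moderate" else "low"
    }
  } else {
    priority <- "low"
  }
  new_call("de_novo_gain", priority, site_type = swa$site_type,
           evidence = ev, flags = flags)
}

nearest_same_type <- function(ncss, site_type) {
  up <- ncss[[paste0("upstream_", site_type)]]
  down <- ncss[[paste0("downstream_", site_type)]]
  if (is.null(up)) return(down)
  if (is.null(down)) return(up)
  if (up$distance <= down$distance) up else down
}

# Region label for evaluation stratification. Precedence: consensus
# dinucleotides, then the remainder of native motifs, then exonic, then
# other intronic.
region_label_for <- function(v, tx) {
  sites <- native_sites(tx)
  sp <- variant_span0(v)
  lab <- NULL
  for (site in sites) {
    if (!(sp[1L] < site$span0[2L] && sp[2L] > site$span0[1L])) next
    dinuc <- if (site$site_type == "donor") c(3L, 4L) else c(18L, 19L)
    dpos <- sort(vapply(dinuc, function(o) site_offset_pos0(site, o), integer(1)))
    hits_dinuc <- sp[1L] <= dpos[2L] && sp[2L] > dpos[1L]
    cand <- paste0(site$site_type, if (hits_dinuc) "_dinucleotide" else "_other")
    rank <- c(donor_dinucleotide = 4L, acceptor_dinucleotide = 3L,
              donor_other = 2L, acceptor_other = 1L)
    if (is.null(lab) || rank[[cand]] > rank[[lab]]) lab <- cand
  }
  if (!is.null(lab)) return(lab)
  in_exon <- any(apply(tx$exons, 1L, function(e) sp[1L] < e[2L] && sp[2L] > e[1L]))
  if (in_exon) "exonic" else "intronic_other"
}

#' Assess one variant against one transcript
#'
#' Computes all three score sets, routes the variant per its position
#' (overlapping a native splice-site motif: loss assessment; outside:
#' gain assessment), evaluates donor and acceptor channels and reports the
#' higher-priority call (ties go to the donor). All raw scores are retained
#' in the call's evidence.
#'
#' @inheritParams score_native_sites
#' @param t a [splice_thresholds].
#' @return a `spliceogenicity_call` with evidence containing `native`
#'   ([score_native_sites]), `swa` (donor and acceptor [run_swa]) and `ncss`
#'   ([run_ncss]).
#' @export
assess_variant <- function(v, tx, genome, models, t = splice_thresholds()) {
  sp <- tx_span0(tx)
  if (!variant_overlaps0(v, sp[1L], sp[2L])) {
    stop(sprintf("variant %s:%d does not overlap transcript %s", v$chrom, v$pos,
                 tx$transcript_id), call. = FALSE)
  }
  native <- score_native_sites(v, tx, genome, models)
  swa <- list(donor = run_swa(v, tx, genome, models, "donor"),
              acceptor = run_swa(v, tx, genome, models, "acceptor"))
  ncss <- run_ncss(v, tx, genome, models)
  evidence <- list(native = native, swa = swa, ncss = ncss)
  region <- region_label_for(v, tx)

  pick_best <- function(calls) {
    # higher priority wins; ties go to the donor channel
    ord <- order(-PRIORITY_LEVELS[vapply(calls, `[[`, character(1), "priority")],
                 vapply(calls, function(cl) {
                   st <- cl$site_type
                   if (identical(st, "donor")) 0L else 1L
                 }, integer(1)))
    calls[[ord[1L]]]
  }

  if (length(native) > 0L) {
    is_indel <- nchar(v$ref) != nchar(v$alt)
    calls <- lapply(native, function(ns) {
      cl <- if (is_indel) {
        classify_loss(swa[[ns$site$site_type]], t)
      } else {
        classify_loss(ns, t)
      }
      cl$site_type <- ns$site$site_type
      cl
    })
    best <- pick_best(calls)
  } else {
    calls <- lapply(c("donor", "acceptor"), function(st) {
      classify_gain(swa[[st]], ncss, t)
    })
    best <- pick_best(calls)
  }
  best$region_label <- region
  best$evidence <- evidence
  best
}
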