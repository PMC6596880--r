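#' Construct a splice-site maximum-entropy model
#'
#' A splice model scores fixed-length motifs as log2 likelihood ratios of a
#' signal distribution over a background distribution. Donor models cover a
#' 9-mer with the near-invariant GT dinucleotide at motif offsets 3-4
#' (0-based); acceptor models cover a 23-mer with AG at offsets 18-19.
#'
#' The distributions are carried in one of two internal representations:
#' \describe{
#'   \item{joint}{an explicit probability vector over all 4^L motifs
#'     (donor only; 4^9 = 262144 cells).}
#'   \item{chain}{a first-order Markov chain: start distribution plus one
#'     4x4 transition matrix per adjacent position pair. This is the exact
#'     maximum-entropy model for first-order plus adjacent-pair constraints
#'     and the only tractable form at acceptor length (4^23 cells).}
#' }
#' Models loaded from score-table files carry only ratio factors (no
#' normalized components) and cannot be sampled from.
#'
#' @param site_type "donor" or "acceptor".
#' @param signal,background component descriptors (lists with a `kind` of
#'   "joint", "chain" or "indep"), or NULL for table-backed models.
#' @param factors list of scoring factors; each factor is a list with
#'   `positions` (1-based offsets into the motif), `log2ratio` (numeric of
#'   length 4^m, lexicographic A<C<G<T) and `sign` (+1 or -1).
#' @param fit optional fitting diagnostics (convergence flag, iterations,
#'   achieved max marginal deviation).
#' @param source free-text provenance tag.
#' @return an object of class `splice_model`.
#' @export
splice_model <- function(site_type, signal = NULL, background = NULL,
                         factors = NULL, fit = NULL, source = "constructed") {
  site_type <- match.arg(site_type, c("donor", "acceptor"))
  motif_length <- if (site_type == "donor") 9L else 23L
  consensus_offsets <- if (site_type == "donor") c(3L, 4L) else c(18L, 19L)
  if (is.null(factors)) {
    if (is.null(signal) || is.null(background)) {
      stop("need either factors or signal+background components", call. = FALSE)
    }
    factors <- build_ratio_factors(signal, background, motif_length)
  }
  for (f in factors) {
    if (any(f$positions < 1L | f$positions > motif_length)) {
      stop("factor positions outside the motif", call. = FALSE)
    }
    if (length(f$log2ratio) != 4L^length(f$positions)) {
      stop("factor table size inconsistent with its position subset", call. = FALSE)
    }
    if (any(!is.finite(f$log2ratio))) {
      stop("non-finite factor entries; apply a probability floor before ratios",
           call. = FALSE)
    }
  }
  structure(
    list(site_type = site_type, motif_length = motif_length,
         consensus_offsets = consensus_offsets, factors = factors,
         signal = signal, background = background, fit = fit, source = source),
    class = "splice_model"
  )
}

#' @method print splice_model
#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("<splice_model %s, %d-mer, %d factor(s), source=%s>\n",
              x$site_type, x$motif_length, length(x$factors), x$source))
  if (!is.null(x$fit)) {
    cat(sprintf("  fit: converged=%s after %d iteration(s), max marginal dev %.2e\n",
                x$fit$converged, x$fit$iterations, x$fit$max_dev))
  }
  invisible(x)
}

# Turn normalized signal/background components into log2-ratio factors.
build_ratio_factors <- function(signal, background, L) {
  if (signal$kind == "joint") {
    ps <- component_joint(signal, L)
    pb <- component_joint(background, L)
    return(list(list(positions = seq_len(L), log2ratio = log2(ps / pb), sign = 1)))
  }
  if (signal$kind %in% c("chain", "indep")) {
    facs <- vector("list", 0L)
    rat <- function(positions) {
      ps <- pmax(component_marginal(signal, positions, L), PROB_FLOOR)
      pb <- pmax(component_marginal(background, positions, L), PROB_FLOOR)
      log2(ps / pb)
    }
    for (i in seq_len(L - 1L)) {
      facs[[length(facs) + 1L]] <-
        list(positions = c(i, i + 1L), log2ratio = rat(c(i, i + 1L)), sign = 1)
    }
    for (i in seq(2L, L - 1L)) {
      facs[[length(facs) + 1L]] <-
        list(positions = i, log2ratio = rat(i), sign = -1)
    }
    return(facs)
  }
  stop("unknown component kind: ", signal$kind, call. = FALSE)
}

PROB_FLOOR <- 1e-9

# ---- component helpers ------------------------------------------------------

# Components:
#   list(kind = "joint", prob = numeric(4^L))
#   list(kind = "chain", start = numeric(4), trans = list of (L-1) 4x4 matrices)
#   list(kind = "indep", probs = list of L numeric(4))   (product of marginals)

component_joint <- function(comp, L) {
  p <- switch(comp$kind,
    joint = comp$prob,
    indep = {
      codes <- enumerate_codes(L)
      p <- rep(1, nrow(codes))
      for (j in seq_len(L)) p <- p * comp$probs[[j]][codes[, j] + 1L]
      p
    },
    chain = {
      codes <- enumerate_codes(L)
      p <- comp$start[codes[, 1L] + 1L]
      for (j in seq_len(L - 1L)) {
        p <- p * comp$trans[[j]][cbind(codes[, j] + 1L, codes[, j + 1L] + 1L)]
      }
      p
    },
    stop("unknown component kind", call. = FALSE)
  )
  # guard against exact zeros so log-ratios stay finite; model-derived cells
  # below the empirical floor are legitimate and must not be distorted
  p[p < 1e-30] <- 1e-30
  p / sum(p)
}

as_chain <- function(comp, L) {
  if (comp$kind == "chain") return(comp)
  if (comp$kind == "indep") {
    trans <- lapply(seq_len(L - 1L), function(i) {
      matrix(rep(comp$probs[[i + 1L]], each = 4L), nrow = 4L)
    })
    return(list(kind = "chain", start = comp$probs[[1L]], trans = trans))
  }
  stop("cannot view a joint component as a chain", call. = FALSE)
}

# Exact marginal of a component over an ordered position subset (gaps allowed).
# Returns numeric(4^m), lexicographic.
component_marginal <- function(comp, positions, L) {
  positions <- as.integer(positions)
  m <- length(positions)
  if (comp$kind == "indep") {
    codes <- enumerate_codes(m)
    p <- rep(1, nrow(codes))
    for (j in seq_len(m)) p <- p * comp$probs[[positions[j]]][codes[, j] + 1L]
    return(p)
  }
  if (comp$kind == "joint") {
    codes <- enumerate_codes(L)
    idx <- codes_to_index(codes, positions)
    out <- numeric(4L^m)
    agg <- rowsum(comp$prob, idx)
    out[as.integer(rownames(agg))] <- agg[, 1L]
    return(out)
  }
  # chain: effective start at positions[1] and effective transitions between
  # consecutive kept positions (matrix products across marginalized gaps).
  start <- comp$start
  if (positions[1L] > 1L) {
    for (i in seq_len(positions[1L] - 1L)) start <- as.numeric(start %*% comp$trans[[i]])
  }
  effs <- list()
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      M <- diag(4)
      for (i in positions[j]:(positions[j + 1L] - 1L)) M <- M %*% comp$trans[[i]]
      effs[[j]] <- M
    }
  }
  codes <- enumerate_codes(m)
  p <- start[codes[, 1L] + 1L]
  if (m > 1L) {
    for (j in seq_len(m - 1L)) {
      p <- p * effs[[j]][cbind(codes[, j] + 1L, codes[, j + 1L] + 1L)]
    }
  }
  p
}

# ---- scoring ----------------------------------------------------------------

score_codes <- function(model, codes) {
  s <- numeric(nrow(codes))
  for (f in model$factors) {
    s <- s + f$sign * f$log2ratio[codes_to_index(codes, f$positions)]
  }
  unname(s)
}

#' Score motifs as log2 likelihood ratios
#'
#' Computes log2(P_signal / P_background) for each motif. Input is
#' case-insensitive; scoring operates on the literal string given, so
#' reverse-complementing minus-strand sequence is the caller's job.
#'
#' @param model a [splice_model].
#' @param seq character vector of motifs, each exactly `model$motif_length` nt.
#' @return numeric vector of scores (full precision; render to 2 decimals for
#'   reports).
#' @examples
#' m <- default_models()$donor
#' score_motif(m, "CAGGTAAGT")
#' @export
score_motif <- function(model, seq) {
  stopifnot(inherits(model, "splice_model"))
  if (length(seq) == 0L) return(numeric(0))
  lens <- nchar(seq)
  if (any(lens != model$motif_length)) {
    stop(sprintf("expected %d-mer(s) for a %s model, got length(s) %s",
                 model$motif_length, model$site_type,
                 paste(unique(lens[lens != model$motif_length]), collapse = ", ")),
         call. = FALSE)
  }
  score_codes(model, seq_to_codes(seq))
}

#' Sample motifs from a model's signal component
#'
#' Independent draws from the signal distribution; reproducible given `seed`.
#'
#' @param model a [splice_model] with a signal component.
#' @param n number of motifs (>= 1).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return character vector of `n` motifs.
#' @export
sample_motifs <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "splice_model"))
  if (!is.numeric(n) || length(n) != 1L || n < 1L) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  comp <- model$signal
  if (is.null(comp)) {
    stop("model has no normalized signal component (table-backed models cannot be sampled)",
         call. = FALSE)
  }
  L <- model$motif_length
  with_seed(seed, {
    if (comp$kind == "joint") {
      idx <- sample.int(length(comp$prob), n, replace = TRUE, prob = comp$prob) - 1L
      codes <- matrix(0L, nrow = n, ncol = L)
      for (j in seq_len(L)) codes[, j] <- (idx %/% 4L^(L - j)) %% 4L
      codes_to_seq(codes)
    } else {
      ch <- as_chain(comp, L)
      codes <- matrix(0L, nrow = n, ncol = L)
      codes[, 1L] <- sample.int(4L, n, replace = TRUE, prob = ch$start) - 1L
      for (j in seq_len(L - 1L)) {
        Tm <- ch$trans[[j]]
        Tm <- Tm / rowSums(Tm)  # conditional given previous base
        u <- stats::runif(n)
        cm <- t(apply(Tm, 1L, cumsum))
        prev <- codes[, j] + 1L
        codes[, j + 1L] <- as.integer(rowSums(u > cm[prev, , drop = FALSE]))
      }
      codes_to_seq(codes)
    }
  })
}

#' Default synthetic donor and acceptor models
#'
#' Consensus-like position probability profiles for the canonical GT donor and
#' AG acceptor motifs. These are synthetic models defined in code, not the
#' published MaxEntScan tables: they reproduce the qualitative structure of
#' human splice sites (near-invariant GT/AG, A-rich donor intron positions,
#' a pyrimidine tract upstream of the acceptor AG) on a log2 score scale where
#' a consensus donor scores around 12, so the usual 6.2/8.5 thresholds are
#' meaningful. The background is a fixed 54% AT genomic base composition.
#'
#' @return list with elements `donor` and `acceptor`, both [splice_model]s.
#' @export
default_models <- function() {
  bg <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  donor_pwm <- rbind(
    c(0.33, 0.36, 0.18, 0.13),   # -3 exonic
    c(0.60, 0.13, 0.14, 0.13),   # -2
    c(0.10, 0.03, 0.80, 0.07),   # -1
    c(0.0017, 0.0017, 0.9949, 0.0017),  # +1 intronic G
    c(0.0017, 0.0017, 0.0017, 0.9949),  # +2 T
    c(0.50, 0.05, 0.35, 0.10),   # +3
    c(0.70, 0.08, 0.12, 0.10),   # +4
    c(0.06, 0.05, 0.80, 0.09),   # +5
    c(0.15, 0.18, 0.22, 0.45)    # +6
  )
  tract <- c(0.10, 0.32, 0.12, 0.46)   # pyrimidine-rich intron body
  acceptor_pwm <- rbind(
    do.call(rbind, rep(list(tract), 14L)),          # -20 .. -7
    c(0.22, 0.28, 0.18, 0.32),                      # -6
    c(0.10, 0.36, 0.10, 0.44),                      # -5
    c(0.24, 0.30, 0.14, 0.32),                      # -4
    c(0.06, 0.62, 0.04, 0.28),                      # -3
    c(0.9949, 0.0017, 0.0017, 0.0017),              # -2 A
    c(0.0017, 0.0017, 0.9949, 0.0017),              # -1 G
    c(0.26, 0.14, 0.46, 0.14),                      # +1 exonic
    c(0.28, 0.22, 0.24, 0.26),                      # +2
    c(0.26, 0.24, 0.24, 0.26)                       # +3
  )
  pwm_to_model <- function(site_type, pwm) {
    probs <- lapply(seq_len(nrow(pwm)), function(i) {
      p <- pwm[i, ] / sum(pwm[i, ])
      stats::setNames(p, DNA_BASES)
    })
    L <- nrow(pwm)
    signal <- list(kind = "indep", probs = probs)
    background <- list(kind = "indep", probs = rep(list(bg), L))
    if (site_type == "donor") {
      signal <- list(kind = "joint", prob = component_joint(signal, L))
    }
    splice_model(site_type, signal = signal, background = background,
                 source = "synthetic consensus-like profile")
  }
  list(donor = pwm_to_model("donor", donor_pwm),
       acceptor = pwm_to_model("acceptor", acceptor_pwm))
}

# ---- native serialized model format ----------------------------------------

#' Write and read the native model serialization
#'
#' A versioned JSON document carrying site type, motif length, consensus
#' offsets and the scoring factors. Round-trips scores exactly (within
#' double-precision text rendering).
#'
#' @param model a [splice_model].
#' @param path file path.
#' @export
save_splice_model <- function(model, path) {
  stopifnot(inherits(model, "splice_model"))
  doc <- list(
    format = "mesplice-model", version = 1L,
    site_type = model$site_type, motif_length = model$motif_length,
    consensus_offsets = model$consensus_offsets, source = model$source,
    factors = lapply(model$factors, function(f) {
      list(positions = f$positions, sign = f$sign, log2ratio = f$log2ratio)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_splice_model
#' @export
read_splice_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "mesplice-model")) {
    stop("not a mesplice model document: ", path, call. = FALSE)
  }
  factors <- lapply(seq_len(nrow_or_len(doc$factors)), function(i) {
    f <- if (is.data.frame(doc$factors)) doc$factors[i, ] else doc$factors[[i]]
    list(positions = as.integer(unlist(f$positions)),
         log2ratio = as.numeric(unlist(f$log2ratio)),
         sign = as.numeric(f$sign))
  })
  splice_model(doc$site_type, factors = factors, source = doc$source)
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
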