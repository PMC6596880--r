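#' Build a marginal constraint set from training sequences
#'
#' For each position subset, tabulates the empirical joint frequency of the
#' sub-sequences at those positions, floors zero cells at 1e-9 and
#' renormalizes, so fitted ratios stay finite on unseen k-mers.
#'
#' @param seqs character vector of equal-length training sequences.
#' @param subsets list of integer vectors of 1-based motif positions; default
#'   is all single positions plus all adjacent pairs.
#' @param tolerance maximum absolute deviation between fitted and empirical
#'   marginals accepted as converged.
#' @return object of class `marginal_constraints`: list of
#'   `list(positions, table)` plus the tolerance.
#' @export
marginal_constraints <- function(seqs, subsets = NULL, tolerance = 1e-6) {
  codes <- seq_to_codes(seqs)
  L <- ncol(codes)
  if (is.null(subsets)) {
    subsets <- c(as.list(seq_len(L)),
                 lapply(seq_len(L - 1L), function(i) c(i, i + 1L)))
  }
  cons <- lapply(subsets, function(S) {
    S <- as.integer(S)
    if (any(S < 1L | S > L)) stop("constraint subset outside the motif", call. = FALSE)
    idx <- codes_to_index(codes, S)
    tab <- tabulate(idx, nbins = 4L^length(S)) / nrow(codes)
    tab <- pmax(tab, PROB_FLOOR)
    list(positions = S, table = tab / sum(tab))
  })
  structure(list(constraints = cons, tolerance = tolerance),
            class = "marginal_constraints")
}

#' Fit a maximum-entropy splice model by iterative scaling
#'
#' Finds the maximum-entropy distribution whose marginals on each constraint
#' subset match the empirical marginals of the training sequences, by
#' iterative proportional fitting: each sweep multiplies the current model by
#' the ratio of empirical to model marginals for every constraint, until the
#' largest absolute marginal deviation falls below the tolerance or `max_iter`
#' sweeps have run. The background component is fitted the same way from
#' `background_seqs` with first-order (per-position) constraints, or uniform
#' when no background sequences are given.
#'
#' Two fitting regimes, chosen by motif length:
#' \itemize{
#'   \item motifs up to 10 nt (donor): updates run on the explicit joint
#'     distribution, so arbitrary position subsets are allowed.
#'   \item longer motifs (acceptor, 4^23 not enumerable): constraints must be
#'     single positions and adjacent pairs; updates run on chain factor
#'     potentials with exact forward-backward marginals. The fixed point is
#'     the first-order Markov chain, the closed-form maximum-entropy model
#'     for that constraint set.
#' }
#'
#' @param site_type "donor" or "acceptor".
#' @param training_seqs at least 50 motif-length ACGT sequences.
#' @param background_seqs optional motif-length sequences for the background;
#'   NULL or empty gives a uniform background.
#' @param constraints a [marginal_constraints] object, or NULL for the default
#'   (all singles + adjacent pairs).
#' @param max_iter,tolerance iterative scaling controls.
#' @return a [splice_model]; `$fit` records convergence. Non-convergence
#'   raises a warning with the achieved deviation, not an error.
#' @export
fit_model <- function(site_type, training_seqs, background_seqs = NULL,
                      constraints = NULL, max_iter = 1000L, tolerance = 1e-6) {
  site_type <- match.arg(site_type, c("donor", "acceptor"))
  L <- if (site_type == "donor") 9L else 23L
  if (length(training_seqs) == 0L) {
    stop("empty training set", call. = FALSE)
  }
  if (length(training_seqs) < 50L) {
    stop("need at least 50 training sequences, got ", length(training_seqs),
         call. = FALSE)
  }
  if (any(nchar(training_seqs) != L)) {
    stop(sprintf("training sequences must all be %d nt for a %s model", L, site_type),
         call. = FALSE)
  }
  if (is.null(constraints)) {
    constraints <- marginal_constraints(training_seqs, tolerance = tolerance)
  }
  stopifnot(inherits(constraints, "marginal_constraints"))
  tol <- if (!is.null(constraints$tolerance)) constraints$tolerance else tolerance

  signal <- if (L <= 10L) {
    ipf_joint(constraints$constraints, L, max_iter, tol)
  } else {
    ipf_chain(constraints$constraints, L, max_iter, tol)
  }

  background <- if (is.null(background_seqs) || length(background_seqs) == 0L) {
    list(kind = "indep",
         probs = rep(list(stats::setNames(rep(0.25, 4L), DNA_BASES)), L))
  } else {
    if (any(nchar(background_seqs) != L)) {
      stop("background sequences must be motif-length", call. = FALSE)
    }
    bc <- marginal_constraints(background_seqs, subsets = as.list(seq_len(L)))
    list(kind = "indep", probs = lapply(bc$constraints, `[[`, "table"))
  }

  fitinfo <- attr(signal, "fit")
  attr(signal, "fit") <- NULL
  if (!fitinfo$converged) {
    warning(sprintf(
      "iterative scaling did not reach tolerance %.1e within %d sweeps (achieved %.2e)",
      tol, max_iter, fitinfo$max_dev))
  }
  splice_model(site_type, signal = signal, background = background,
               fit = fitinfo, source = "fitted (iterative scaling)")
}

# IPF on the explicit joint distribution (L <= 10).
ipf_joint <- function(cons, L, max_iter, tol) {
  codes <- enumerate_codes(L)
  n <- nrow(codes)
  idxs <- lapply(cons, function(cn) codes_to_index(codes, cn$positions))
  p <- rep(1 / n, n)
  dev <- Inf
  it <- 0L
  while (it < max_iter && dev >= tol) {
    it <- it + 1L
    dev <- 0
    for (k in seq_along(cons)) {
      idx <- idxs[[k]]
      emp <- cons[[k]]$table
      mod <- numeric(length(emp))
      agg <- rowsum(p, idx)
      mod[as.integer(rownames(agg))] <- agg[, 1L]
      dev <- max(dev, max(abs(mod - emp)))
      ratio <- emp / pmax(mod, .Machine$double.xmin)
      p <- p * ratio[idx]
    }
    p <- p / sum(p)
  }
  out <- list(kind = "joint", prob = p)
  attr(out, "fit") <- list(converged = dev < tol, iterations = it, max_dev = dev)
  out
}

# IPF on chain factor potentials (singles + adjacent pairs only).
ipf_chain <- function(cons, L, max_iter, tol) {
  for (cn in cons) {
    m <- length(cn$positions)
    ok <- m == 1L || (m == 2L && diff(cn$positions) == 1L)
    if (!ok) {
      stop("motifs longer than 10 nt support only single-position and adjacent-pair constraints",
           call. = FALSE)
    }
  }
  psi <- rep(list(matrix(1, 4L, 4L)), L - 1L)

  chain_marginals <- function() {
    alpha <- matrix(0, L, 4L); beta <- matrix(0, L, 4L)
    alpha[1L, ] <- 1
    for (i in seq_len(L - 1L)) {
      a <- alpha[i, ] %*% psi[[i]]
      alpha[i + 1L, ] <- a / sum(a)
    }
    beta[L, ] <- 1
    for (i in (L - 1L):1L) {
      b <- psi[[i]] %*% beta[i + 1L, ]
      beta[i, ] <- b / sum(b)
    }
    pairs <- lapply(seq_len(L - 1L), function(i) {
      m <- outer(alpha[i, ], beta[i + 1L, ]) * psi[[i]]
      m / sum(m)
    })
    singles <- vector("list", L)
    for (i in seq_len(L - 1L)) singles[[i]] <- rowSums(pairs[[i]])
    singles[[L]] <- colSums(pairs[[L - 1L]])
    list(pairs = pairs, singles = singles)
  }

  dev <- Inf; it <- 0L
  while (it < max_iter && dev >= tol) {
    it <- it + 1L
    dev <- 0
    for (cn in cons) {
      mg <- chain_marginals()
      if (length(cn$positions) == 2L) {
        i <- cn$positions[1L]
        emp <- matrix(cn$table, 4L, 4L, byrow = TRUE)  # row-major: first pos varies slowest
        mod <- mg$pairs[[i]]
        dev <- max(dev, max(abs(mod - emp)))
        psi[[i]] <- psi[[i]] * emp / pmax(mod, .Machine$double.xmin)
      } else {
        j <- cn$positions
        emp <- cn$table
        mod <- mg$singles[[j]]
        dev <- max(dev, max(abs(mod - emp)))
        r <- emp / pmax(mod, .Machine$double.xmin)
        if (j < L) psi[[j]] <- psi[[j]] * r            # scale rows
        else psi[[L - 1L]] <- t(t(psi[[L - 1L]]) * r)  # scale columns
      }
    }
  }

  mg <- chain_marginals()
  start <- mg$singles[[1L]]
  trans <- lapply(seq_len(L - 1L), function(i) {
    tm <- mg$pairs[[i]] / pmax(mg$singles[[i]], .Machine$double.xmin)
    tm / rowSums(tm)
  })
  out <- list(kind = "chain", start = start,
              trans = lapply(seq_len(L - 1L), function(i) {
                # joint-form transition: P(x_{i+1}|x_i)
                trans[[i]]
              }))
  attr(out, "fit") <- list(converged = dev < tol, iterations = it, max_dev = dev)
  out
}
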