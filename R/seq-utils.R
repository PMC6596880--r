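DNA_BASES <- c("A", "C", "G", "T")

#' Convert sequences to a base-code matrix
#'
#' Each row is one sequence, coded A=0, C=1, G=2, T=3. Case-insensitive.
#' Any character outside ACGT (including N) is an error; ambiguous bases are
#' handled by the callers that can skip windows, never silently here.
#'
#' @param seqs character vector of equal-length nucleotide strings.
#' @return integer matrix, one row per sequence.
#' @keywords internal
seq_to_codes <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = 0L))
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  L <- lens[1L]
  chars <- unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE)
  codes <- match(chars, DNA_BASES) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop(sprintf("ambiguous or non-ACGT base(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  matrix(codes, ncol = L, byrow = TRUE)
}

codes_to_seq <- function(codes) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  apply(codes, 1L, function(r) paste(DNA_BASES[r + 1L], collapse = ""))
}

#' Enumerate all k-mers of a given length as a code matrix
#'
#' Rows are ordered lexicographically (A < C < G < T), so row i corresponds to
#' table index i in the score-table files.
#' @keywords internal
enumerate_codes <- function(k) {
  n <- 4L^k
  idx <- seq_len(n) - 1L
  m <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    m[, j] <- (idx %/% 4L^(k - j)) %% 4L
  }
  m
}

# Index (1-based) of each row's sub-sequence at `positions` into a 4^m table,
# lexicographic order.
codes_to_index <- function(codes, positions) {
  m <- length(positions)
  pow <- 4L^((m - 1L):0L)
  as.integer(codes[, positions, drop = FALSE] %*% pow) + 1L
}

#' Reverse complement of plain character DNA
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Complement without reversal (single bases or strings).
complement_seq <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

has_ambiguous <- function(x) {
  grepl("[^ACGTacgt]", x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
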