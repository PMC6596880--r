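# Score-table layout, mirroring the structure of the classic MaxEntScan
# distribution: the donor score is a consensus-dinucleotide frequency-ratio
# term (positions 4-5, the intronic GT) times one ratio table over the seven
# non-consensus positions; the acceptor score is the consensus AG term
# (positions 19-20) times a product of five "included" sub-model ratio tables
# divided by four "correction" tables over overlapping 7-position windows of
# the 21 non-consensus positions. Every table is 4^7 = 16384 lines,
# lexicographic in A<C<G<T. Block position subsets are written explicitly in
# the headers, so readers never hard-code them.

DONOR_REST_POSITIONS <- c(1:3, 6:9)

ACCEPTOR_BLOCKS <- list(
  list(id = 1L, sign = 1,  positions = 1:7),
  list(id = 2L, sign = 1,  positions = 8:14),
  list(id = 3L, sign = 1,  positions = c(15:18, 21:23)),
  list(id = 4L, sign = 1,  positions = 5:11),
  list(id = 5L, sign = 1,  positions = 12:18),
  list(id = 6L, sign = -1, positions = 5:7),
  list(id = 7L, sign = -1, positions = 8:11),
  list(id = 8L, sign = -1, positions = 12:14),
  list(id = 9L, sign = -1, positions = 15:18)
)

fmt_freqs <- function(p) {
  paste(sprintf("%s=%.10g", DNA_BASES, p), collapse = " ")
}

marginal_ratio <- function(model, positions) {
  ps <- pmax(component_marginal(model$signal, positions, model$motif_length), PROB_FLOOR)
  pb <- pmax(component_marginal(model$background, positions, model$motif_length), PROB_FLOOR)
  ps / pb
}

#' Write donor/acceptor models as MaxEntScan-style score tables
#'
#' Serializes the models' marginal ratio tables in the layout described above.
#' The exact factorized score defined by the files is an approximation of the
#' source model (the consensus dinucleotide is scored independently of the
#' remaining positions); [load_reference_tables] reproduces the file-defined
#' score exactly.
#'
#' @param donor_model,acceptor_model [splice_model]s with normalized
#'   components (fitted or constructed; table-backed models cannot be
#'   re-serialized).
#' @param donor_path,acceptor_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_mes_tables <- function(donor_model, acceptor_model, donor_path, acceptor_path) {
  stopifnot(inherits(donor_model, "splice_model"),
            inherits(acceptor_model, "splice_model"))
  if (is.null(donor_model$signal) || is.null(acceptor_model$signal)) {
    stop("models must carry normalized signal/background components", call. = FALSE)
  }

  dn <- donor_model
  lines <- c(
    sprintf("#%%mes-donor-table v1 source=%s", gsub("\\s+", "_", dn$source)),
    sprintf("#%%cons pos=4 %s", fmt_freqs(component_marginal(dn$signal, 4L, 9L))),
    sprintf("#%%cons pos=5 %s", fmt_freqs(component_marginal(dn$signal, 5L, 9L))),
    sprintf("#%%bgd pos=4 %s", fmt_freqs(component_marginal(dn$background, 4L, 9L))),
    sprintf("#%%bgd pos=5 %s", fmt_freqs(component_marginal(dn$background, 5L, 9L))),
    sprintf("#%%rest positions=%s", paste(DONOR_REST_POSITIONS, collapse = ",")),
    sprintf("%.10g", marginal_ratio(dn, DONOR_REST_POSITIONS))
  )
  writeLines(lines, donor_path)

  ac <- acceptor_model
  lines <- c(
    sprintf("#%%mes-acceptor-table v1 source=%s", gsub("\\s+", "_", ac$source)),
    sprintf("#%%cons pos=19 %s", fmt_freqs(component_marginal(ac$signal, 19L, 23L))),
    sprintf("#%%cons pos=20 %s", fmt_freqs(component_marginal(ac$signal, 20L, 23L))),
    sprintf("#%%bgd pos=19 %s", fmt_freqs(component_marginal(ac$background, 19L, 23L))),
    sprintf("#%%bgd pos=20 %s", fmt_freqs(component_marginal(ac$background, 20L, 23L)))
  )
  for (blk in ACCEPTOR_BLOCKS) {
    lines <- c(lines,
               sprintf("#%%block id=%d sign=%d positions=%s", blk$id, blk$sign,
                       paste(blk$positions, collapse = ",")),
               sprintf("%.10g", marginal_ratio(ac, blk$positions)))
  }
  writeLines(lines, acceptor_path)
  invisible(c(donor = donor_path, acceptor = acceptor_path))
}

parse_freq_header <- function(line, path, lineno) {
  m <- regmatches(line, gregexpr("[ACGT]=[0-9.eE+-]+", line))[[1]]
  if (length(m) != 4L) {
    stop(sprintf("%s:%d: malformed frequency header: %s", path, lineno, line),
         call. = FALSE)
  }
  vals <- as.numeric(sub("^[ACGT]=", "", m))
  names(vals) <- sub("=.*$", "", m)
  vals[DNA_BASES]
}

parse_positions <- function(line, path, lineno) {
  m <- regmatches(line, regexpr("positions=[0-9,]+", line))
  if (length(m) != 1L) {
    stop(sprintf("%s:%d: missing positions= in header: %s", path, lineno, line),
         call. = FALSE)
  }
  as.integer(strsplit(sub("positions=", "", m), ",")[[1]])
}

read_table_file <- function(path, expected_tag) {
  if (!file.exists(path)) stop("no such table file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], paste0("#%", expected_tag))) {
    stop(sprintf("%s:1: expected a '#%%%s' header", path, expected_tag), call. = FALSE)
  }
  cons <- list(); bgd <- list(); blocks <- list()
  is_header <- startsWith(lines, "#%")
  for (i in which(is_header)[-1L]) {
    ln <- lines[i]
    if (startsWith(ln, "#%cons")) {
      pos <- as.integer(sub(".*pos=([0-9]+).*", "\\1", ln))
      cons[[as.character(pos)]] <- parse_freq_header(ln, path, i)
    } else if (startsWith(ln, "#%bgd")) {
      pos <- as.integer(sub(".*pos=([0-9]+).*", "\\1", ln))
      bgd[[as.character(pos)]] <- parse_freq_header(ln, path, i)
    } else if (startsWith(ln, "#%rest") || startsWith(ln, "#%block")) {
      sign <- if (grepl("sign=-1", ln)) -1 else 1
      blocks[[length(blocks) + 1L]] <- list(
        positions = parse_positions(ln, path, i), sign = sign, header_line = i)
    } else {
      stop(sprintf("%s:%d: unrecognized header line: %s", path, i, ln), call. = FALSE)
    }
  }
  value_lines <- which(!is_header & nzchar(trimws(lines)))
  block_starts <- vapply(blocks, `[[`, integer(1), "header_line")
  if (length(value_lines) > 0L && length(blocks) == 0L) {
    stop(sprintf("%s:%d: value line before any block header", path, value_lines[1L]),
         call. = FALSE)
  }
  for (k in seq_along(blocks)) {
    lo <- block_starts[k]
    hi <- if (k < length(blocks)) block_starts[k + 1L] else length(lines) + 1L
    vl <- value_lines[value_lines > lo & value_lines < hi]
    vals <- suppressWarnings(as.numeric(lines[vl]))
    if (anyNA(vals)) {
      bad <- vl[which(is.na(vals))[1L]]
      stop(sprintf("%s:%d: not a number: %s", path, bad, lines[bad]), call. = FALSE)
    }
    blocks[[k]]$values <- vals
  }
  stray <- value_lines[value_lines < min(c(block_starts, Inf))]
  if (length(stray) > 0L) {
    stop(sprintf("%s:%d: value line before any block header", path, stray[1L]),
         call. = FALSE)
  }
  for (blk in blocks) {
    expect <- 4L^length(blk$positions)
    got <- length(blk$values)
    if (got != expect) {
      stop(sprintf(
        "%s:%d: block over positions %s has %d value(s), expected %d (truncated or malformed table)",
        path, blk$header_line, paste(blk$positions, collapse = ","), got, expect),
        call. = FALSE)
    }
  }
  list(cons = cons, bgd = bgd, blocks = blocks)
}

table_to_model <- function(parsed, site_type, path) {
  L <- if (site_type == "donor") 9L else 23L
  cons_pos <- if (site_type == "donor") c(4L, 5L) else c(19L, 20L)
  factors <- list()
  for (p in cons_pos) {
    key <- as.character(p)
    if (is.null(parsed$cons[[key]]) || is.null(parsed$bgd[[key]])) {
      stop(sprintf("%s: missing consensus/background frequencies for position %d",
                   path, p), call. = FALSE)
    }
    factors[[length(factors) + 1L]] <- list(
      positions = p,
      log2ratio = log2(pmax(parsed$cons[[key]], PROB_FLOOR) /
                       pmax(parsed$bgd[[key]], PROB_FLOOR)),
      sign = 1)
  }
  for (blk in parsed$blocks) {
    if (any(blk$positions < 1L | blk$positions > L)) {
      stop(sprintf("%s: block positions %s outside a %d-mer motif", path,
                   paste(blk$positions, collapse = ","), L), call. = FALSE)
    }
    factors[[length(factors) + 1L]] <- list(
      positions = blk$positions,
      log2ratio = log2(pmax(blk$values, PROB_FLOOR)),
      sign = blk$sign)
  }
  splice_model(site_type, factors = factors,
               source = sprintf("score tables (%s)", basename(path)))
}

#' Load donor and acceptor score tables
#'
#' Reads MaxEntScan-style table files (see [write_mes_tables] for the layout)
#' and returns scorable models that reproduce the file-defined factorized
#' score exactly.
#'
#' @param donor_table_path,acceptor_table_path table file paths.
#' @return list with [splice_model] elements `donor` and `acceptor`.
#' @export
load_reference_tables <- function(donor_table_path, acceptor_table_path) {
  dparsed <- read_table_file(donor_table_path, "mes-donor-table")
  if (length(dparsed$blocks) != 1L ||
      !identical(dparsed$blocks[[1L]]$positions, DONOR_REST_POSITIONS)) {
    stop(donor_table_path,
         ": donor table must contain exactly one block over positions 1,2,3,6,7,8,9",
         call. = FALSE)
  }
  aparsed <- read_table_file(acceptor_table_path, "mes-acceptor-table")
  if (length(aparsed$blocks) < 1L) {
    stop(acceptor_table_path, ": acceptor table has no sub-model blocks", call. = FALSE)
  }
  list(donor = table_to_model(dparsed, "donor", donor_table_path),
       acceptor = table_to_model(aparsed, "acceptor", acceptor_table_path))
}
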