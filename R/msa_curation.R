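#' Curation parameters for the iterative alignment loop
#'
#' The canonical thresholds: rows covering less than 30% of the alignment
#' columns are eliminated (strict `<`), columns consisting of at least 90%
#' gaps are removed (inclusive `>=`), and sequences at 95% pairwise identity
#' or more to an already-kept sequence are removed (inclusive `>=`).
#'
#' @param min_seq_coverage minimum non-gap fraction of columns a row must
#'   cover to be retained.
#' @param max_col_gap_frac gap fraction at (or above) which a column is
#'   removed.
#' @param max_pairwise_identity identity at (or above) which the later of a
#'   pair of sequences is removed.
#' @param max_cycles safety bound on curation cycles.
#' @return list of class `curation_params`.
#' @export
curation_params <- function(min_seq_coverage = 0.30,
                            max_col_gap_frac = 0.90,
                            max_pairwise_identity = 0.95,
                            max_cycles = 20L) {
  stopifnot(min_seq_coverage >= 0, min_seq_coverage <= 1,
            max_col_gap_frac >= 0, max_col_gap_frac <= 1,
            max_pairwise_identity >= 0, max_pairwise_identity <= 1,
            max_cycles >= 1)
  structure(list(min_seq_coverage = min_seq_coverage,
                 max_col_gap_frac = max_col_gap_frac,
                 max_pairwise_identity = max_pairwise_identity,
                 max_cycles = as.integer(max_cycles)),
            class = "curation_params")
}

check_alignment <- function(aln) {
  if (!length(aln)) return(aln)
  if (is.null(names(aln))) stop("alignment rows must be named")
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows must all have equal length")
  }
  aln
}

aln_char_matrix <- function(aln) {
  if (!length(aln)) return(matrix(character(), 0, 0))
  do.call(rbind, strsplit(aln, "", fixed = TRUE))
}

#' Remove low-coverage and duplicate rows from an alignment
#'
#' A row is removed when its non-gap residues cover less than
#' `min_seq_coverage` of the alignment columns (strict `<`: a row at exactly
#' the threshold is retained). Exact duplicate rows are also removed, the
#' first occurrence being kept.
#'
#' @param aln named character vector of equal-length aligned strings
#'   (gap `-`).
#' @param min_seq_coverage coverage threshold (default 0.30).
#' @return filtered alignment (same representation).
#' @export
drop_low_coverage <- function(aln, min_seq_coverage = 0.30) {
  aln <- check_alignment(aln)
  if (!length(aln)) return(aln)
  ncol <- nchar(aln[[1L]])
  cov <- if (ncol == 0L) rep(0, length(aln)) else {
    (ncol - vapply(gregexpr("-", aln, fixed = TRUE), function(m) {
      if (m[1L] == -1L) 0L else length(m)
    }, 0L)) / ncol
  }
  keep <- cov >= min_seq_coverage & !duplicated(unname(aln))
  aln[keep]
}

#' Remove gap-dominated columns from an alignment
#'
#' Columns whose gap fraction is at least `max_col_gap_frac` are removed
#' (inclusive: a column at exactly 90% gaps goes).
#'
#' @inheritParams drop_low_coverage
#' @param max_col_gap_frac column gap-fraction threshold (default 0.90).
#' @return alignment with the offending columns excised.
#' @export
drop_gappy_columns <- function(aln, max_col_gap_frac = 0.90) {
  aln <- check_alignment(aln)
  if (!length(aln) || nchar(aln[[1L]]) == 0L) return(aln)
  m <- aln_char_matrix(aln)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac < max_col_gap_frac
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  stats::setNames(as.character(out), names(aln))
}

#' Pairwise identity of two aligned sequences
#'
#' Identity is the number of columns where both sequences carry the same
#' non-gap residue, divided by the aligned length excluding columns where
#' both are gaps.
#'
#' @param a,b aligned strings of equal length.
#' @return identity in `[0, 1]`; `NA` if no comparable columns exist.
#' @export
pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  comparable <- !(ca == "-" & cb == "-")
  if (!any(comparable)) return(NA_real_)
  sum(ca == cb & ca != "-" & comparable) / sum(comparable)
}

#' Remove near-duplicate sequences
#'
#' Greedy scan in input order: a sequence is dropped when its pairwise
#' identity to any already-kept sequence reaches `max_pairwise_identity`
#' (inclusive). The first member of each near-identical set is the one
#' retained; later members are compared against the kept set only, so a
#' chain A~B~C with A and C below threshold keeps both A and C.
#'
#' @inheritParams drop_low_coverage
#' @param max_pairwise_identity identity threshold (default 0.95).
#' @return filtered alignment.
#' @export
drop_near_duplicates <- function(aln, max_pairwise_identity = 0.95) {
  aln <- check_alignment(aln)
  if (length(aln) < 2L) return(aln)
  keep <- logical(length(aln))
  keep[1L] <- TRUE
  for (i in 2L:length(aln)) {
    ident <- vapply(which(keep), function(j) {
      pairwise_identity(aln[[i]], aln[[j]])
    }, 0)
    keep[i] <- !any(!is.na(ident) & ident >= max_pairwise_identity)
  }
  aln[keep]
}

strip_gaps <- function(aln) {
  stats::setNames(gsub("-", "", aln, fixed = TRUE), names(aln))
}

#' Iterative alignment curation to a fixed point
#'
#' Runs the cycle align -> drop low-coverage/duplicate rows -> drop gappy
#' columns -> drop near-duplicate sequences -> realign, until the sequence
#' count and column count are both unchanged between consecutive cycles (or
#' `max_cycles` is hit, with a warning). The filters only remove material,
#' so the (sequences, columns) pair is non-increasing and the loop
#' terminates. The filter order is fixed as stated; reordering the row and
#' column filters can change the result.
#'
#' @param seqs named character vector of *unaligned* sequences.
#' @param aligner function mapping a named character vector of sequences to
#'   an alignment (named character vector of equal-length gapped strings).
#'   Use [mafft_aligner()] for a real aligner, or any deterministic stub.
#' @param params a [curation_params()] object.
#' @return list with `alignment` (final, fixed-point alignment), `log`
#'   (data frame `cycle`, `sequences`, `columns` after each cycle's
#'   filters) and `converged` (logical).
#' @export
curation_cycle <- function(seqs, aligner, params = curation_params()) {
  stopifnot(is.function(aligner), inherits(params, "curation_params"))
  log <- data.frame(cycle = integer(), sequences = integer(),
                    columns = integer())
  prev <- c(NA_integer_, NA_integer_)
  aln <- NULL
  converged <- FALSE
  for (cycle in seq_len(params$max_cycles)) {
    aln <- tryCatch(check_alignment(aligner(seqs)), error = function(e) {
      stop(sprintf("aligner failed in cycle %d: %s", cycle,
                   conditionMessage(e)))
    })
    aln <- drop_low_coverage(aln, params$min_seq_coverage)
    aln <- drop_gappy_columns(aln, params$max_col_gap_frac)
    aln <- drop_near_duplicates(aln, params$max_pairwise_identity)
    counts <- c(length(aln), if (length(aln)) nchar(aln[[1L]]) else 0L)
    log <- rbind(log, data.frame(cycle = cycle, sequences = counts[1L],
                                 columns = counts[2L]))
    if (identical(counts, prev)) {
      converged <- TRUE
      break
    }
    prev <- counts
    seqs <- strip_gaps(aln)
  }
  if (!converged) {
    warning("curation did not stabilise within max_cycles = ",
            params$max_cycles)
  }
  list(alignment = aln, log = log, converged = converged)
}

#' Aligner contract backed by the MAFFT executable
#'
#' Returns a function satisfying the aligner contract of
#' [curation_cycle()], shelling out to `mafft` (which must be on the
#' `PATH`). Intended for production use on real families; tests use
#' deterministic stubs instead.
#'
#' @param args extra command-line arguments (default `--auto`).
#' @return function: named character vector -> named character vector of
#'   aligned strings.
#' @export
mafft_aligner <- function(args = "--auto") {
  function(seqs) {
    if (Sys.which("mafft") == "") stop("mafft executable not found on PATH")
    fin <- tempfile(fileext = ".fa")
    on.exit(unlink(fin))
    write_fasta(seqs, fin, type = "protein")
    out <- system2("mafft", c(args, "--amino", shQuote(fin)),
                   stdout = TRUE, stderr = FALSE)
    tc <- textConnection(out)
    on.exit(close(tc), add = TRUE)
    lines <- readLines(tc)
    hdr <- grepl("^>", lines)
    ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
    grp <- cumsum(hdr)
    body <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
    stats::setNames(toupper(unname(body)), ids)
  }
}

#' Rebuild a curated sequence from its motif table
#'
#' Concatenates the motif residue strings of one sequence in order of start
#' coordinate (ties broken by end coordinate, then motif id). Overlapping
#' motifs are concatenated as-is with no overlap resolution, so the output
#' length is always the sum of motif lengths.
#'
#' @param motifs data frame with columns `start`, `end`, `residues` and
#'   optionally `motif_id`, all for a single sequence.
#' @return curated residue string.
#' @export
build_curated_sequence <- function(motifs) {
  if (nrow(motifs) == 0L) return("")
  stopifnot(all(motifs$start <= motifs$end))
  mid <- motifs$motif_id %||% rep("", nrow(motifs))
  ord <- order(motifs$start, motifs$end, mid)
  paste(motifs$residues[ord], collapse = "")
}

#' Read a motif annotation table
#'
#' Reads the 5/6-column TSV layout `sequence_id, motif_id, start, end,
#' residues[, evalue]` produced by parsing motif-discovery output.
#'
#' @param path file path.
#' @return data frame of motif annotations.
#' @export
read_motifs <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sequence_id", "motif_id", "start", "end", "residues")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("motif TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(d$start > d$end)) stop("motif coordinates must satisfy start <= end")
  d
}
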