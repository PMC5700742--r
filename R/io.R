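#' Read and write FASTA files
#'
#' Thin wrappers around [Biostrings] readers that return plain named
#' character vectors, the sequence container used throughout this package.
#'
#' @param path file path.
#' @param type `"protein"` or `"nucleotide"`.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  x <- if (type == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @param x named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  set <- if (type == "protein") Biostrings::AAStringSet(x) else Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read domain hits
#'
#' Reads a domain-hit table either from the HMMER3 per-domain tabular output
#' (`--domtblout` of `hmmscan`/`hmmsearch`) or from a generic 7-column TSV
#' with columns `sequence_id, frame, domain, evalue, bitscore, start, end`.
#' For `domtblout`, the per-domain (independent) E-value, the domain bit
#' score and the envelope coordinates are used, matching how domain evidence
#' enters rule-based family classification.
#'
#' @param path file path.
#' @param format `"tsv"` or `"domtblout"`.
#' @return data frame with columns `sequence_id`, `frame`, `domain`,
#'   `evalue`, `bitscore`, `start`, `end`.
#' @export
read_domain_hits <- function(path, format = c("tsv", "domtblout")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sequence_id", "frame", "domain", "evalue", "bitscore", "start", "end")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("hit TSV missing column(s): ", paste(miss, collapse = ", "))
    d$frame <- normalize_frame(d$frame)
    return(domain_hits(d$sequence_id, d$frame, d$domain, d$evalue,
                       d$bitscore, d$start, d$end))
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(domain_hits(character(), character(), character(),
                       numeric(), numeric(), integer(), integer()))
  }
  f <- strsplit(trimws(lines), "\\s+")
  getcol <- function(i) vapply(f, `[[`, "", i)
  domain_hits(
    sequence_id = getcol(4L),
    frame       = NA_character_,
    domain      = getcol(1L),
    evalue      = as.numeric(getcol(13L)),  # independent ("i-Evalue")
    bitscore    = as.numeric(getcol(14L)),
    start       = as.integer(getcol(20L)),  # envelope from
    end         = as.integer(getcol(21L))   # envelope to
  )
}

#' Construct a validated domain-hit table
#'
#' @param sequence_id,frame,domain,evalue,bitscore,start,end vectors of equal
#'   length; `frame` may be `NA` for protein-level hits.
#' @return data frame of class `domain_hits`.
#' @export
domain_hits <- function(sequence_id, frame = NA_character_, domain,
                        evalue, bitscore = NA_real_, start = NA_integer_,
                        end = NA_integer_) {
  d <- data.frame(
    sequence_id = as.character(sequence_id),
    frame = normalize_frame(rep_len(frame, length(sequence_id))),
    domain = as.character(domain),
    evalue = as.numeric(evalue),
    bitscore = as.numeric(rep_len(bitscore, length(sequence_id))),
    start = as.integer(rep_len(start, length(sequence_id))),
    end = as.integer(rep_len(end, length(sequence_id))),
    stringsAsFactors = FALSE
  )
  if (any(!is.na(d$evalue) & d$evalue <= 0)) stop("e-values must be > 0")
  ok <- is.na(d$start) | is.na(d$end) | d$start <= d$end
  if (!all(ok)) stop("hit coordinates must satisfy start <= end")
  class(d) <- c("domain_hits", "data.frame")
  d
}

#' Read 12-column tabular similarity-search output
#'
#' Parses the standard 12-column tabular layout written by BLAST
#' (`-outfmt 6`) and FASTA-family tools. Only the columns the linkage step
#' consumes are typed; the full row is retained.
#'
#' @param path file path (no header line expected).
#' @return data frame with the standard columns `qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore`.
#' @export
read_hits12 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 12L) stop("expected >= 12 tab-separated columns")
  d <- d[, 1:12]
  names(d) <- cols
  for (nm in c("pident", "evalue", "bitscore")) d[[nm]] <- as.numeric(d[[nm]])
  for (nm in c("length", "mismatch", "gapopen", "qstart", "qend", "sstart", "send")) {
    d[[nm]] <- as.integer(d[[nm]])
  }
  d
}

#' Read an FPKM expression matrix
#'
#' Expects a TSV with transcript ids in the first column and one column per
#' tissue/condition.
#'
#' @param path file path.
#' @return numeric matrix, transcripts in rows, tissues in columns.
#' @export
read_fpkm <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d)
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("FPKM values must be non-negative")
  m
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
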