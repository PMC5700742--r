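#' Merge two annotation versions into a non-redundant protein set
#'
#' When a genome has been annotated twice (e.g. two exon-calling routes over
#' the same assembly), the two protein sets largely overlap. This keeps
#' exactly one record per distinct amino-acid string: the first-seen id is
#' retained and input order is otherwise preserved, so the merge is
#' idempotent and commutative up to which id represents a duplicated
#' composition.
#'
#' @param set_a,set_b named character vectors of protein sequences
#'   (id -> residues).
#' @return named character vector containing one record per distinct
#'   residue string.
#' @export
merge_annotation_versions <- function(set_a, set_b) {
  for (s in list(set_a, set_b)) {
    if (length(s) && is.null(names(s))) stop("protein sets must be named")
    if (any(!nzchar(s))) stop("empty residue strings are not allowed")
    # heuristic guard: a long record over the DNA alphabet only is almost
    # certainly an untranslated nucleotide sequence
    dna_like <- grepl("^[ACGTUNacgtun]+$", s) & nchar(s) >= 10L
    if (any(dna_like)) {
      stop("nucleotide record(s) in protein set: ",
           paste(utils::head(names(s)[dna_like], 3L), collapse = ", "))
    }
  }
  all <- c(set_a, set_b)
  all[!duplicated(unname(all))]
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates all three forward frames and the three frames of the reverse
#' complement under the standard genetic code. Stop codons are rendered `*`
#' and retained (downstream domain scanning operates on the full frame
#' peptide, not on called ORFs). Codons containing `N` translate to `X`.
#' Frames shorter than one codon yield empty peptides rather than an error.
#'
#' @param seq a single nucleotide sequence over `A,C,G,T,N` (case
#'   insensitive). Other IUPAC ambiguity codes are rejected unless
#'   `allow_ambiguity = TRUE`, in which case their codons translate to `X`.
#' @param id optional sequence id carried into the output.
#' @param allow_ambiguity accept non-N ambiguity codes.
#' @return data frame with columns `parent_id`, `frame`
#'   (`+1,+2,+3,-1,-2,-3`) and `peptide`.
#' @export
six_frame_translate <- function(seq, id = "seq", allow_ambiguity = FALSE) {
  stopifnot(length(seq) == 1L, is.character(seq))
  s <- toupper(seq)
  legal <- if (allow_ambiguity) "[^ACGTNRYSWKMBDHV]" else "[^ACGTN]"
  bad <- regexpr(legal, s)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d of '%s'",
                 substr(s, bad, bad), bad, id))
  }
  fwd <- Biostrings::DNAString(s)
  rev <- Biostrings::reverseComplement(fwd)
  translate_frame <- function(x, off) {
    n <- length(x) - off
    ncod <- n %/% 3L
    if (ncod < 1L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, start = off + 1L, width = ncod * 3L),
      if.fuzzy.codon = "X"
    ))
  }
  data.frame(
    parent_id = id,
    frame = VALID_FRAMES,
    peptide = c(vapply(0:2, function(o) translate_frame(fwd, o), ""),
                vapply(0:2, function(o) translate_frame(rev, o), "")),
    stringsAsFactors = FALSE
  )
}

#' Derive gene ids from gene-model ids
#'
#' Annotation pipelines emit one record per gene model (isoform); several
#' models may belong to one gene, conventionally marked by a trailing
#' `.<integer>` suffix (Phytozome style, e.g. `Phvul.001G001100.1`). The
#' suffix is stripped when it matches `pattern`; ids without a matching
#' suffix are returned unchanged, so `|genes| <= |gene models|` always.
#'
#' @param model_id character vector of gene-model ids.
#' @param pattern regular expression for the model suffix
#'   (default trailing `.<integer>`).
#' @return character vector of gene ids.
#' @export
gene_id_of <- function(model_id, pattern = "\\.\\d+$") {
  sub(pattern, "", model_id)
}
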