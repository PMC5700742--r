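#' Best reference hit per query
#'
#' Filters a similarity-search hit table at an E-value cutoff and keeps, for
#' every query, the single subject with the lowest E-value (tie-breaks:
#' higher bit score, then lexicographically smallest subject id; tie events
#' are recorded in the `ties` attribute). The result is invariant under row
#' order of the input table, and lowering the threshold can only remove
#' links, never add them.
#'
#' @param hits data frame with at least `qseqid`, `sseqid`, `evalue` and
#'   optionally `bitscore` (see [read_hits12()]).
#' @param e_threshold E-value cutoff; rows with `evalue > e_threshold` are
#'   discarded (default `1e-5`, the conventional nucleotide-search linkage
#'   cutoff).
#' @return data frame `qseqid`, `sseqid`, `evalue`, `bitscore`, one row per
#'   linked query, with attribute `ties`.
#' @export
best_hit <- function(hits, e_threshold = 1e-5) {
  stopifnot(e_threshold > 0)
  empty <- data.frame(qseqid = character(), sseqid = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) {
    attr(empty, "ties") <- character()
    return(empty)
  }
  if (is.null(hits$bitscore)) hits$bitscore <- NA_real_
  h <- hits[hits$evalue <= e_threshold,
            c("qseqid", "sseqid", "evalue", "bitscore"), drop = FALSE]
  if (nrow(h) == 0L) {
    attr(empty, "ties") <- character()
    return(empty)
  }
  h <- h[order(h$qseqid, h$evalue,
               -ifelse(is.na(h$bitscore), -Inf, h$bitscore), h$sseqid), ,
         drop = FALSE]
  out <- h[!duplicated(h$qseqid), , drop = FALSE]
  # a query is tie-flagged when several subjects share its minimal e-value
  min_ev <- stats::ave(h$evalue, h$qseqid, FUN = min)
  at_min <- h[h$evalue == min_ev, , drop = FALSE]
  n_sub <- tapply(at_min$sseqid, at_min$qseqid,
                  function(s) length(unique(s)))
  rownames(out) <- NULL
  attr(out, "ties") <- sort(names(n_sub)[n_sub > 1L])
  out
}

#' Join expression values onto best-hit links
#'
#' Attaches to every linked query the FPKM row of its best-matching
#' reference transcript. Queries whose subject is absent from the matrix
#' keep their link but receive an all-`NA` expression vector and are
#' flagged; queries with no link at all may be injected via `all_queries`
#' so downstream tables stay aligned with the repertoire.
#'
#' @param links output of [best_hit()].
#' @param fpkm numeric matrix, reference transcripts in rows, tissues in
#'   columns (see [read_fpkm()]).
#' @param families optional named character vector query -> family label.
#' @param all_queries optional character vector of query ids that must each
#'   appear exactly once in the output (unlinked ones get `NA` rows).
#' @return data frame of class `link_table`: `qseqid`, `sseqid`, `evalue`,
#'   `family`, `flag` (`ok`, `no-link` or `subject-missing`), then one
#'   column per tissue.
#' @export
join_expression <- function(links, fpkm, families = NULL,
                            all_queries = NULL) {
  stopifnot(is.matrix(fpkm))
  q <- unique(c(links$qseqid, all_queries))
  i <- match(q, links$qseqid)
  sub <- links$sseqid[i]
  ev <- links$evalue[i]
  flag <- ifelse(is.na(sub), "no-link",
                 ifelse(sub %in% rownames(fpkm), "ok", "subject-missing"))
  if (any(flag == "subject-missing")) {
    warning("linked subject(s) absent from FPKM matrix: ",
            paste(utils::head(sub[flag == "subject-missing"], 3L),
                  collapse = ", "))
  }
  expr <- matrix(NA_real_, length(q), ncol(fpkm),
                 dimnames = list(q, colnames(fpkm)))
  ok <- flag == "ok"
  expr[ok, ] <- fpkm[sub[ok], , drop = FALSE]
  out <- data.frame(qseqid = q, sseqid = sub, evalue = ev,
                    family = if (is.null(families)) NA_character_
                             else unname(families[q]),
                    flag = flag, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(expr))
  rownames(out) <- NULL
  class(out) <- c("link_table", "data.frame")
  out
}

#' Rescue homologs for a family absent from the repertoire
#'
#' When no pipeline finds members of a family in the focal species, members
#' of the family from a related species are used as queries in a
#' translated/nucleotide similarity search against the raw assembly; the
#' distinct subjects hit below the cutoff are the candidate homologs.
#'
#' @param family family label (carried into the output).
#' @param queries named character vector of query sequences from the
#'   related species.
#' @param db named character vector of target sequences (e.g. raw assembly
#'   scaffolds).
#' @param search function `(queries, db) -> hit data frame` with columns
#'   `qseqid`, `sseqid`, `evalue` (a real search tool in production; a stub
#'   in tests).
#' @param e_threshold rescue cutoff; hits must satisfy
#'   `evalue < e_threshold` (strict, default `1e-3`).
#' @return list with `family`, `n_rescued` (distinct subjects) and `hits`
#'   (the passing hit rows).
#' @export
homolog_rescue <- function(family, queries, db, search, e_threshold = 1e-3) {
  stopifnot(is.function(search), e_threshold > 0)
  hits <- search(queries, db)
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(family = family, n_rescued = 0L,
                hits = data.frame(qseqid = character(), sseqid = character(),
                                  evalue = numeric())))
  }
  pass <- hits[hits$evalue < e_threshold, , drop = FALSE]
  list(family = family,
       n_rescued = length(unique(pass$sseqid)),
       hits = pass)
}

#' Expression matrix ordered for display beside a tree
#'
#' Reorders the expression columns of a link table into a numeric matrix
#' whose rows follow a supplied ordering (typically the tip order of a
#' plotted tree, so heatmap rows align with tree leaves). Queries without a
#' link keep a row of `NA`s rather than being dropped, preserving the
#' row-to-leaf correspondence.
#'
#' @param link_table output of [join_expression()].
#' @param ordering character vector of query ids giving the row order;
#'   defaults to the table's own order.
#' @param log10_transform apply `log10(x + 1)` to the values.
#' @return numeric matrix, queries in rows (in `ordering`), tissues in
#'   columns.
#' @export
heatmap_table <- function(link_table, ordering = NULL,
                          log10_transform = FALSE) {
  stopifnot(inherits(link_table, "link_table"))
  meta <- c("qseqid", "sseqid", "evalue", "family", "flag")
  tissues <- setdiff(names(link_table), meta)
  m <- as.matrix(link_table[, tissues, drop = FALSE])
  rownames(m) <- link_table$qseqid
  if (!is.null(ordering)) {
    missing <- setdiff(ordering, rownames(m))
    if (length(missing)) {
      stop("ordering contains unknown query id(s): ",
           paste(utils::head(missing, 3L), collapse = ", "))
    }
    m <- m[ordering, , drop = FALSE]
  }
  if (log10_transform) m <- log10(m + 1)
  m
}
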