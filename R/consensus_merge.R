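#' Build a table of pipeline classification records
#'
#' One record is one claim, by one source pipeline, that a sequence (protein
#' or translated transcript on a given reading frame) belongs to a family.
#'
#' @param source source label; must appear in the merge priority order.
#' @param kind `"protein"` or `"transcript"`.
#' @param sequence_id sequence / gene-model id.
#' @param frame reading frame for transcript records; `NA` for proteins.
#' @param family canonical family label.
#' @return data frame of class `pipeline_records`.
#' @export
pipeline_records <- function(source, kind, sequence_id, frame, family) {
  n <- length(sequence_id)
  d <- data.frame(source = rep_len(as.character(source), n),
                  kind = rep_len(as.character(kind), n),
                  sequence_id = as.character(sequence_id),
                  frame = normalize_frame(rep_len(frame, n)),
                  family = as.character(family),
                  stringsAsFactors = FALSE)
  bad_kind <- !(d$kind %in% c("protein", "transcript"))
  if (any(bad_kind)) stop("record kind must be 'protein' or 'transcript'")
  if (any(d$kind == "transcript" & is.na(d$frame))) {
    stop("transcript records must carry a frame")
  }
  if (any(d$kind == "protein" & !is.na(d$frame))) {
    stop("protein records must not carry a frame")
  }
  class(d) <- c("pipeline_records", "data.frame")
  d
}

DEFAULT_PRIORITY <- c("protein", "tfcat", "itak", "rule")

#' Merge multi-pipeline classifications into one non-redundant repertoire
#'
#' Applies a stepwise priority rule over record sources: a protein-level
#' record is always accepted; a transcript record is accepted only if no
#' higher-priority source already claimed the same (sequence, frame, family)
#' key, and only if no accepted protein record covers the same
#' (sequence, family) pair. Records on distinct reading frames are distinct
#' keys. Every eliminated record is logged together with the source of the
#' record that displaced it, so the merge conserves its input:
#' accepted + eliminated = supplied.
#'
#' @param protein,tfcat,itak,rule `pipeline_records` tables (or data frames
#'   with the same columns), one per source; any may be empty or `NULL`.
#' @param priority character vector ordering the sources from most to least
#'   trusted; defaults to `protein > tfcat > itak > rule`.
#' @return object of class `merged_repertoire`: list with `accepted`
#'   (records plus `source`) and `eliminated` (records plus `displaced_by`).
#' @export
merge_repertoires <- function(protein = NULL, tfcat = NULL, itak = NULL,
                              rule = NULL, priority = DEFAULT_PRIORITY) {
  inputs <- list(protein = protein, tfcat = tfcat, itak = itak, rule = rule)
  inputs <- inputs[!vapply(inputs, is.null, TRUE)]
  cols <- c("source", "kind", "sequence_id", "frame", "family")
  all <- if (length(inputs)) {
    do.call(rbind, c(lapply(unname(inputs), function(d) {
      as.data.frame(d)[, cols, drop = FALSE]
    }), list(make.row.names = FALSE)))
  } else NULL
  if (is.null(all) || nrow(all) == 0L) {
    empty <- data.frame(source = character(), kind = character(),
                        sequence_id = character(), frame = character(),
                        family = character(), stringsAsFactors = FALSE)
    out <- list(accepted = empty,
                eliminated = cbind(empty, displaced_by = character()),
                priority = priority)
    class(out) <- "merged_repertoire"
    return(out)
  }
  unknown <- setdiff(unique(all$source), priority)
  if (length(unknown)) {
    stop("record source(s) not in priority order: ",
         paste(unknown, collapse = ", "))
  }
  all$frame <- normalize_frame(all$frame)
  all <- all[order(match(all$source, priority)), , drop = FALSE]

  key <- paste(all$sequence_id, ifelse(is.na(all$frame), ".", all$frame),
               all$family, sep = "\r")
  dup <- duplicated(key)
  survivor_src <- stats::setNames(all$source[!dup], key[!dup])
  eliminated <- all[dup, , drop = FALSE]
  eliminated$displaced_by <- unname(survivor_src[key[dup]])
  accepted <- all[!dup, , drop = FALSE]

  # protein presence suppresses transcript claims for the same
  # (sequence, family), whatever their frame
  prot_key <- with(accepted[accepted$kind == "protein", , drop = FALSE],
                   paste(sequence_id, family, sep = "\r"))
  sup <- accepted$kind == "transcript" &
    paste(accepted$sequence_id, accepted$family, sep = "\r") %in% prot_key
  if (any(sup)) {
    e2 <- accepted[sup, , drop = FALSE]
    e2$displaced_by <- "protein"
    eliminated <- rbind(eliminated, e2)
    accepted <- accepted[!sup, , drop = FALSE]
  }
  rownames(accepted) <- rownames(eliminated) <- NULL
  out <- list(accepted = accepted, eliminated = eliminated,
              priority = priority)
  class(out) <- "merged_repertoire"
  out
}

#' @export
print.merged_repertoire <- function(x, ...) {
  cat(sprintf("merged_repertoire: %d accepted, %d eliminated (priority: %s)\n",
              nrow(x$accepted), nrow(x$eliminated),
              paste(x$priority, collapse = " > ")))
  invisible(x)
}

#' Count domains, sequences and genes in a merged repertoire
#'
#' Three granularities of the same repertoire: the *domain* count is the
#' number of accepted (sequence, frame, family) records (a sequence with two
#' family claims contributes two domains), the *sequence* count is the
#' number of distinct (sequence, frame) pairs (gene models, including
#' per-frame translations), and the *gene* count collapses gene models onto
#' genes via [gene_id_of()]. By construction
#' `domains >= sequences >= genes`.
#'
#' @param merged a `merged_repertoire`.
#' @param gene_pattern suffix pattern passed to [gene_id_of()], or a named
#'   character vector mapping sequence id -> gene id.
#' @return list with `totals` (named vector `domains`, `sequences`,
#'   `genes`) and `per_family` (data frame `family`, `domains`, `sequences`,
#'   `genes`).
#' @export
domains_sequences_genes <- function(merged, gene_pattern = "\\.\\d+$") {
  stopifnot(inherits(merged, "merged_repertoire"))
  a <- merged$accepted
  gid <- if (is.character(gene_pattern) && !is.null(names(gene_pattern))) {
    unname(gene_pattern[a$sequence_id])
  } else {
    gene_id_of(a$sequence_id, gene_pattern)
  }
  sfk <- seq_frame_key(a$sequence_id, a$frame)
  totals <- c(domains = nrow(a),
              sequences = length(unique(sfk)),
              genes = length(unique(gid)))
  per_family <- if (nrow(a)) {
    fams <- sort(unique(a$family))
    do.call(rbind, lapply(fams, function(f) {
      i <- a$family == f
      data.frame(family = f, domains = sum(i),
                 sequences = length(unique(sfk[i])),
                 genes = length(unique(gid[i])),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(family = character(), domains = integer(),
               sequences = integer(), genes = integer())
  }
  list(totals = totals, per_family = per_family)
}
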