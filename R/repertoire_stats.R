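#' Per-species repertoire tables
#'
#' A repertoire table holds, for one species, the per-family counts of the
#' TF/TAP repertoire at three granularities: domains (family records,
#' counting multi-family sequences once per family), sequences (gene
#' models / per-frame translations) and genes. The species' total number of
#' protein-coding genes can be attached as the denominator for the
#' genome-wide share basis.
#'
#' @param counts data frame with columns `family`, `domains`, `sequences`,
#'   `genes` (counts may also be supplied for a subset of granularities;
#'   missing columns are filled with `NA`).
#' @param species species label.
#' @param protein_coding_total total number of protein-coding
#'   genes/transcripts in the species (optional).
#' @param totals optional named vector (`domains`, `sequences`, `genes`)
#'   giving the full repertoire totals when `counts` lists only a subset of
#'   families (e.g. a published table of the largest families). Must be at
#'   least the column sums; defaults to the column sums themselves.
#' @return data frame of class `repertoire_table`.
#' @export
repertoire_table <- function(counts, species = "query",
                             protein_coding_total = NA_real_,
                             totals = NULL) {
  stopifnot(is.data.frame(counts), "family" %in% names(counts))
  for (col in c("domains", "sequences", "genes")) {
    if (is.null(counts[[col]])) counts[[col]] <- NA_integer_
    if (any(!is.na(counts[[col]]) & counts[[col]] < 0)) {
      stop("counts must be non-negative")
    }
  }
  if (anyDuplicated(counts$family)) stop("duplicated family rows")
  counts <- counts[, c("family", "domains", "sequences", "genes")]
  if (!is.null(totals)) {
    for (col in c("domains", "sequences", "genes")) {
      if (!is.na(totals[col]) &&
          totals[col] < sum(counts[[col]], na.rm = TRUE)) {
        stop("explicit totals must be at least the per-family column sums")
      }
    }
  }
  structure(counts, species = species,
            protein_coding_total = protein_coding_total,
            totals = totals,
            class = c("repertoire_table", "data.frame"))
}

#' @rdname repertoire_table
#' @param x a `repertoire_table`.
#' @return `repertoire_totals()`: named numeric vector of repertoire totals
#'   (the explicit `totals` when supplied, otherwise column sums).
#' @export
repertoire_totals <- function(x) {
  stopifnot(inherits(x, "repertoire_table"))
  sums <- c(domains = sum(x$domains), sequences = sum(x$sequences),
            genes = sum(x$genes))
  tot <- attr(x, "totals")
  if (is.null(tot)) return(sums)
  for (nm in names(sums)) if (!is.na(tot[nm])) sums[nm] <- tot[nm]
  sums
}

granularity_column <- function(granularity = c("gene_models", "genes")) {
  switch(match.arg(granularity), gene_models = "sequences", genes = "genes")
}

#' Share of a repertoire held by one family
#'
#' Three bases are supported. `repertoire_share`: the family's count as a
#' percentage of the species' whole TF/TAP repertoire at the stated
#' granularity (e.g. a family with 511 of 4416 sequences holds 11.57%).
#' `protein_gene_share`: the family's gene count as a percentage of all
#' protein-coding genes of the species. `raw_count`: the count itself.
#' Shares are returned at full precision; round to 2 decimal places for
#' display.
#'
#' @param table a `repertoire_table`.
#' @param family family name.
#' @param basis `"repertoire_share"`, `"raw_count"` or
#'   `"protein_gene_share"`.
#' @param granularity `"gene_models"` (sequence-level counts) or
#'   `"genes"`.
#' @return numeric scalar (percentage for share bases); `NA` with a warning
#'   when the denominator is zero or unknown.
#' @export
family_share <- function(table, family,
                         basis = c("repertoire_share", "raw_count",
                                   "protein_gene_share"),
                         granularity = c("gene_models", "genes")) {
  basis <- match.arg(basis)
  col <- granularity_column(granularity)
  i <- match(family, table$family)
  n <- if (is.na(i)) 0 else table[[col]][i]
  if (basis == "raw_count") return(n)
  tot <- repertoire_totals(table)
  denom <- if (basis == "repertoire_share") {
    tot[[switch(col, sequences = "sequences", genes = "genes")]]
  } else {
    attr(table, "protein_coding_total")
  }
  if (is.na(denom) || denom == 0) {
    warning("undefined share: zero or unknown denominator")
    return(NA_real_)
  }
  100 * n / denom
}

#' Percentage difference between two repertoire totals
#'
#' `mode = "fewer"` expresses how much smaller the query total is than the
#' comparator (`(1 - q/c) * 100`); `mode = "of"` expresses the query as a
#' percentage of the comparator (`q/c * 100`). Full precision is returned;
#' the conventional display rounding is one decimal place.
#'
#' @param query_total,comparator_total totals being compared.
#' @param mode `"fewer"` or `"of"`.
#' @return numeric percentage at full precision.
#' @export
percent_difference <- function(query_total, comparator_total,
                               mode = c("fewer", "of")) {
  mode <- match.arg(mode)
  if (comparator_total == 0) stop("comparator total must be > 0")
  r <- query_total / comparator_total
  if (mode == "fewer") (1 - r) * 100 else r * 100
}

#' Divide repertoire counts by a ploidy factor
#'
#' For a comparison between species of unequal ploidy (e.g. a diploid
#' against a paleotetraploid whose families are systematically doubled),
#' the comparator's counts can be divided by a ploidy factor before ratio
#' formation. Rounding is half-away-from-zero, so a total of 13419 halves
#' to 6710.
#'
#' @param x a `repertoire_table` or a numeric vector of counts.
#' @param divisor ploidy divisor (default 2).
#' @return object of the same shape with every count divided and rounded.
#' @export
halve_counts <- function(x, divisor = 2) {
  stopifnot(divisor > 0)
  if (is.numeric(x)) return(round_half_away(x / divisor))
  stopifnot(inherits(x, "repertoire_table"))
  for (col in c("domains", "sequences", "genes")) {
    x[[col]] <- round_half_away(x[[col]] / divisor)
  }
  tot <- attr(x, "totals")
  if (!is.null(tot)) attr(x, "totals") <- round_half_away(tot / divisor)
  x
}

#' Compare family representation between two species
#'
#' For every family in the union of the two tables, forms the ratio
#' query measure / comparator measure on the chosen basis and granularity
#' and calls the family `under`-represented when the ratio falls below
#' `lower`, `over`-represented when it exceeds `upper`, and `similar` when
#' it lies inside the closed band `[lower, upper]`. Families present in
#' exactly one species are flagged (`absent-query` / `absent-comparator`)
#' rather than given an infinite ratio, and are excluded from the summary
#' triple. The query is always the numerator; because the band is not
#' reciprocal-symmetric, swapping the roles of the species can change calls
#' near the bounds.
#'
#' @param query,comparator `repertoire_table`s.
#' @inheritParams family_share
#' @param lower,upper band bounds for `similar` (defaults 0.9 and 1.1,
#'   closed interval).
#' @param ploidy_divisor divisor applied to the comparator's counts before
#'   ratio formation (`raw_count` basis only; shares are scale-invariant).
#' @return object of class `representation_report`: list with `table`
#'   (per-family measures, ratio, call), `summary` (named vector `n_under`,
#'   `n_similar`, `n_over`) and the comparison parameters.
#' @export
compare_repertoires <- function(query, comparator,
                                basis = c("repertoire_share", "raw_count",
                                          "protein_gene_share"),
                                granularity = c("gene_models", "genes"),
                                lower = 0.9, upper = 1.1,
                                ploidy_divisor = 1) {
  basis <- match.arg(basis)
  granularity <- match.arg(granularity)
  stopifnot(0 < lower, lower < 1, 1 < upper)
  if (ploidy_divisor != 1 && basis == "raw_count") {
    comparator <- halve_counts(comparator, ploidy_divisor)
  }
  fams <- sort(union(query$family, comparator$family))
  col <- granularity_column(granularity)
  cnt <- function(tab, f) {
    i <- match(f, tab$family)
    ifelse(is.na(i), 0, tab[[col]][i])
  }
  qn <- vapply(fams, cnt, 0, tab = query)
  cn <- vapply(fams, cnt, 0, tab = comparator)
  qm <- vapply(fams, function(f) {
    suppressWarnings(family_share(query, f, basis, granularity))
  }, 0)
  cm <- vapply(fams, function(f) {
    suppressWarnings(family_share(comparator, f, basis, granularity))
  }, 0)
  ratio <- qm / cm
  call <- rep(NA_character_, length(fams))
  defined <- qn > 0 & cn > 0 & is.finite(ratio)
  call[defined & ratio < lower] <- "under"
  call[defined & ratio >= lower & ratio <= upper] <- "similar"
  call[defined & ratio > upper] <- "over"
  call[qn == 0 & cn > 0] <- "absent-query"
  call[qn > 0 & cn == 0] <- "absent-comparator"
  tab <- data.frame(family = fams, query = qm, comparator = cm,
                    ratio = ifelse(defined, ratio, NA_real_),
                    call = call, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  out <- list(table = tab,
              summary = c(n_under = sum(tab$call == "under", na.rm = TRUE),
                          n_similar = sum(tab$call == "similar", na.rm = TRUE),
                          n_over = sum(tab$call == "over", na.rm = TRUE)),
              basis = basis, granularity = granularity,
              lower = lower, upper = upper, ploidy_divisor = ploidy_divisor,
              query_species = attr(query, "species"),
              comparator_species = attr(comparator, "species"))
  class(out) <- "representation_report"
  out
}

#' @export
print.representation_report <- function(x, ...) {
  cat(sprintf("representation_report: %s vs %s (%s, %s; band [%g, %g])\n",
              x$query_species, x$comparator_species, x$basis, x$granularity,
              x$lower, x$upper))
  cat(sprintf("  under: %d  similar: %d  over: %d  (flagged absences: %d)\n",
              x$summary[["n_under"]], x$summary[["n_similar"]],
              x$summary[["n_over"]],
              sum(grepl("^absent", x$table$call), na.rm = TRUE)))
  invisible(x)
}
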