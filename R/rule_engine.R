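#' Family rule sets: mandatory/forbidden domain rules with synonyms
#'
#' A family rule set defines membership of TF/TAP families purely by the
#' presence and absence of protein domains: a family is *satisfied* by a set
#' of domain hits when all of its mandatory domains are present and none of
#' its forbidden domains is. A synonym map reconciles the different names
#' that databases use for the same family (e.g. `NF-YC` for `CCAAT-HAP5`,
#' `ABI3/VP1` for `B3`); aliases resolve to their canonical name in one step.
#'
#' @param families named list; each element is a list with character vectors
#'   `mandatory` (non-empty) and `forbidden` (possibly empty, disjoint from
#'   `mandatory`).
#' @param synonyms named character vector mapping alias -> canonical family
#'   name. Targets must not themselves be aliases.
#' @param provenance free-text label recording where the rules came from.
#' @return object of class `family_rules`.
#' @export
family_rules <- function(families = list(), synonyms = character(),
                         provenance = "user") {
  if (length(families)) {
    if (is.null(names(families)) || anyDuplicated(names(families))) {
      stop("families must be uniquely named")
    }
    for (nm in names(families)) {
      f <- families[[nm]]
      if (is.null(f$mandatory) || !length(f$mandatory)) {
        stop(sprintf("family '%s': mandatory domain set must be non-empty", nm))
      }
      f$forbidden <- as.character(f$forbidden %||% character())
      both <- intersect(f$mandatory, f$forbidden)
      if (length(both)) {
        stop(sprintf("family '%s': domain(s) %s are both mandatory and forbidden",
                     nm, paste(both, collapse = ", ")))
      }
      families[[nm]] <- list(mandatory = as.character(f$mandatory),
                             forbidden = f$forbidden)
    }
  }
  if (length(synonyms)) {
    if (is.null(names(synonyms))) stop("synonyms must be a named vector (alias -> canonical)")
    unresolved <- synonyms %in% names(synonyms)
    if (any(unresolved)) {
      stop("synonym target(s) are themselves aliases (must resolve in one step): ",
           paste(synonyms[unresolved], collapse = ", "))
    }
  }
  structure(list(families = families,
                 synonyms = synonyms,
                 provenance = provenance),
            class = "family_rules")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.family_rules <- function(x, ...) {
  n_mand <- sum(vapply(x$families, function(f) length(f$mandatory), 0L))
  n_forb <- sum(vapply(x$families, function(f) length(f$forbidden), 0L))
  cat(sprintf("family_rules: %d families, %d mandatory + %d forbidden rules (%d total), %d synonyms [%s]\n",
              length(x$families), n_mand, n_forb, n_mand + n_forb,
              length(x$synonyms), x$provenance))
  invisible(x)
}

#' Count rules in a rule set
#'
#' @param rules a `family_rules` object.
#' @return named integer vector with `families`, `mandatory`, `forbidden`,
#'   `total` (mandatory + forbidden) and `synonyms`.
#' @export
rule_counts <- function(rules) {
  stopifnot(inherits(rules, "family_rules"))
  n_mand <- sum(vapply(rules$families, function(f) length(f$mandatory), 0L))
  n_forb <- sum(vapply(rules$families, function(f) length(f$forbidden), 0L))
  c(families = length(rules$families), mandatory = n_mand,
    forbidden = n_forb, total = n_mand + n_forb,
    synonyms = length(rules$synonyms))
}

#' Load / save a family rule set
#'
#' Rules live in a YAML file with two top-level keys: `families` (each entry
#' carrying `mandatory` and optional `forbidden` domain lists) and
#' `synonyms` (alias -> canonical). Invariants are validated on load and a
#' summary of the counts is reported.
#'
#' @param path YAML file path.
#' @return `load_rules()`: a `family_rules` object.
#' @export
load_rules <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y) || (is.null(y$families) && is.null(y$synonyms))) {
    warning("empty rule file: ", path)
    return(family_rules(provenance = path))
  }
  fams <- lapply(y$families %||% list(), function(f) {
    list(mandatory = as.character(unlist(f$mandatory)),
         forbidden = as.character(unlist(f$forbidden)))
  })
  syn <- unlist(y$synonyms %||% list())
  syn <- if (length(syn)) stats::setNames(as.character(syn), names(syn)) else character()
  rules <- family_rules(fams, syn, provenance = y$provenance %||% path)
  rc <- rule_counts(rules)
  message(sprintf("loaded %d families, %d mandatory + %d forbidden rules, %d synonyms",
                  rc[["families"]], rc[["mandatory"]], rc[["forbidden"]],
                  rc[["synonyms"]]))
  rules
}

#' @param rules a `family_rules` object.
#' @rdname load_rules
#' @export
save_rules <- function(rules, path) {
  stopifnot(inherits(rules, "family_rules"))
  y <- list(provenance = rules$provenance,
            families = lapply(rules$families, function(f) {
              list(mandatory = as.list(f$mandatory),
                   forbidden = as.list(f$forbidden))
            }),
            synonyms = as.list(rules$synonyms))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Resolve family-name synonyms to canonical names
#'
#' Aliases map to their canonical family name; canonical names map to
#' themselves. An unknown label is returned unchanged with a warning, so a
#' misspelt family in an input table surfaces without aborting a run.
#'
#' @param label character vector of family names or aliases.
#' @param rules a `family_rules` object.
#' @return character vector of canonical family names.
#' @export
resolve_synonym <- function(label, rules) {
  stopifnot(inherits(rules, "family_rules"))
  out <- label
  is_alias <- label %in% names(rules$synonyms)
  out[is_alias] <- unname(rules$synonyms[label[is_alias]])
  unknown <- !is.na(out) & !is_alias & !(label %in% names(rules$families)) &
    !(label %in% rules$synonyms)
  if (any(unknown)) {
    warning("unknown family label(s) passed through unchanged: ",
            paste(unique(label[unknown]), collapse = ", "))
  }
  out
}

# canonical families satisfied by a set of present domains, plus whether any
# family failed only because a forbidden domain was present
satisfied_families <- function(present, rules) {
  sat <- character()
  forb_blocked <- FALSE
  for (nm in names(rules$families)) {
    f <- rules$families[[nm]]
    mand_ok <- all(f$mandatory %in% present)
    forb_hit <- length(f$forbidden) && any(f$forbidden %in% present)
    if (mand_ok && !forb_hit) sat <- c(sat, nm)
    if (mand_ok && forb_hit) forb_blocked <- TRUE
  }
  # families that are synonyms of one canonical name count once
  sat_canon <- unique(resolve_synonym(sat, rules))
  list(satisfied = sat_canon, raw = sat, forbidden_blocked = forb_blocked)
}

#' Classify one (sequence, frame) from its domain hits
#'
#' Hits with E-value above `e_threshold` are ignored. A family is satisfied
#' iff all of its mandatory domains are present and none of its forbidden
#' domains is. In `strict` mode a sequence is assigned only when exactly one
#' canonical family is satisfied; two or more satisfied families leave it
#' unassigned with reason `multi-family-conflict` (the behaviour of
#' presence/absence pipelines on, e.g., sequences carrying both NF-YB-like
#' and NF-YC-like domains). In `best-domain` mode such conflicts are broken
#' in favour of the satisfied family whose mandatory-domain hit has the
#' lowest E-value (tie-breaks: higher bit score, then lexicographically
#' smallest family name, recorded in the `note` field).
#'
#' @param hits `domain_hits` rows for a single (sequence, frame).
#' @param rules a `family_rules` object.
#' @param e_threshold domain-hit acceptance E-value cutoff (default `1e-3`).
#' @param mode `"strict"` or `"best-domain"`.
#' @return one-row data frame with `sequence_id`, `frame`, `family`
#'   (`NA` when unassigned), `reason` (one of `assigned`,
#'   `no-rule-satisfied`, `forbidden-domain-present`,
#'   `multi-family-conflict`), `n_hits_used` and `note`.
#' @export
classify_sequence <- function(hits, rules, e_threshold = 1e-3,
                              mode = c("strict", "best-domain")) {
  mode <- match.arg(mode)
  stopifnot(inherits(rules, "family_rules"), e_threshold > 0)
  if (nrow(hits) == 0L) stop("no hits supplied")
  if (length(unique(hits$sequence_id)) != 1L ||
      length(unique(seq_frame_key(hits$sequence_id, hits$frame))) != 1L) {
    stop("classify_sequence() expects hits for exactly one (sequence, frame)")
  }
  sid <- hits$sequence_id[[1L]]
  frm <- hits$frame[[1L]]
  pass <- hits[hits$evalue <= e_threshold, , drop = FALSE]
  present <- unique(pass$domain)
  sf <- satisfied_families(present, rules)
  res <- function(family, reason, note = NA_character_) {
    data.frame(sequence_id = sid, frame = frm, family = family,
               reason = reason, n_hits_used = nrow(pass), note = note,
               stringsAsFactors = FALSE)
  }
  n_sat <- length(sf$satisfied)
  if (n_sat == 0L) {
    reason <- if (sf$forbidden_blocked) "forbidden-domain-present" else "no-rule-satisfied"
    return(res(NA_character_, reason))
  }
  if (n_sat == 1L) return(res(sf$satisfied, "assigned"))
  if (mode == "strict") {
    return(res(NA_character_, "multi-family-conflict",
               note = paste(sort(sf$satisfied), collapse = ";")))
  }
  # best-domain: strongest mandatory-domain similarity wins
  best <- data.frame(family = sf$satisfied,
                     evalue = NA_real_, bitscore = NA_real_)
  for (i in seq_len(nrow(best))) {
    canon <- best$family[i]
    mand <- unique(unlist(lapply(
      sf$raw[resolve_synonym(sf$raw, rules) == canon],
      function(nm) rules$families[[nm]]$mandatory
    )))
    mh <- pass[pass$domain %in% mand, , drop = FALSE]
    best$evalue[i] <- min(mh$evalue)
    best$bitscore[i] <- suppressWarnings(max(mh$bitscore, na.rm = TRUE))
  }
  ord <- order(best$evalue, -ifelse(is.finite(best$bitscore), best$bitscore, -Inf),
               best$family)
  best <- best[ord, , drop = FALSE]
  tie <- nrow(best) > 1L && best$evalue[1L] == best$evalue[2L]
  res(best$family[1L], "assigned",
      note = if (tie) "tie-broken" else paste("conflict-resolved:",
                                              paste(sort(sf$satisfied), collapse = ";")))
}

#' Classify a whole domain-hit table
#'
#' Groups hits by (sequence, frame), classifies each group with
#' [classify_sequence()], and tabulates per-family counts over assigned
#' records. Frames are classified independently: one nucleotide sequence may
#' legitimately yield assignments on several reading frames.
#'
#' @param hits a `domain_hits` data frame (any number of sequences/frames).
#' @inheritParams classify_sequence
#' @return list with `assignments` (one row per (sequence, frame) with at
#'   least one hit passing `e_threshold`) and `counts` (data frame
#'   `family`, `n` over assigned records).
#' @export
classify_set <- function(hits, rules, e_threshold = 1e-3,
                         mode = c("strict", "best-domain")) {
  mode <- match.arg(mode)
  empty <- data.frame(sequence_id = character(), frame = character(),
                      family = character(), reason = character(),
                      n_hits_used = integer(), note = character(),
                      stringsAsFactors = FALSE)
  pass <- hits[hits$evalue <= e_threshold, , drop = FALSE]
  if (nrow(pass) == 0L) {
    return(list(assignments = empty,
                counts = data.frame(family = character(), n = integer())))
  }
  key <- seq_frame_key(pass$sequence_id, pass$frame)
  groups <- split(seq_len(nrow(pass)), key)
  rows <- lapply(groups, function(ix) {
    classify_sequence(pass[ix, , drop = FALSE], rules,
                      e_threshold = e_threshold, mode = mode)
  })
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  assigned <- assignments$family[assignments$reason == "assigned"]
  counts <- if (length(assigned)) {
    tab <- as.data.frame(table(family = assigned), stringsAsFactors = FALSE)
    data.frame(family = as.character(tab$family), n = as.integer(tab$Freq),
               stringsAsFactors = FALSE)
  } else {
    data.frame(family = character(), n = integer())
  }
  list(assignments = assignments, counts = counts[order(counts$family), ,
                                                  drop = FALSE])
}
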