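# Independent oracles and generators shared across test files.

# Brute-force family classifier: re-derives the assignment for an explicit
# set of present domains by direct looping, independently of the package's
# grouping/tie-break code paths. dom_evalue: named vector domain -> e-value.
oracle_classify <- function(domains_present, dom_evalue, rules, mode) {
  canon <- function(x) {
    s <- rules$synonyms
    ifelse(x %in% names(s), unname(s[match(x, names(s))]), x)
  }
  sat <- character()
  blocked <- FALSE
  for (nm in names(rules$families)) {
    f <- rules$families[[nm]]
    m_ok <- all(f$mandatory %in% domains_present)
    f_hit <- length(f$forbidden) > 0 && any(f$forbidden %in% domains_present)
    if (m_ok && !f_hit) sat <- c(sat, nm)
    if (m_ok && f_hit) blocked <- TRUE
  }
  satc <- sort(unique(canon(sat)))
  if (length(satc) == 0L) {
    return(list(family = NA_character_,
                reason = if (blocked) "forbidden-domain-present"
                         else "no-rule-satisfied"))
  }
  if (length(satc) == 1L) return(list(family = satc, reason = "assigned"))
  if (mode == "strict") {
    return(list(family = NA_character_, reason = "multi-family-conflict"))
  }
  best_ev <- vapply(satc, function(cf) {
    members <- sat[canon(sat) == cf]
    mand <- unique(unlist(lapply(members,
                                 function(nm) rules$families[[nm]]$mandatory)))
    min(dom_evalue[intersect(mand, domains_present)])
  }, 0)
  ord <- order(best_ev, satc)
  list(family = satc[ord[1L]], reason = "assigned")
}

# random small rule set over <= 6 domains (caller controls RNG state)
random_small_rules <- function() {
  n_domains <- sample(2:6, 1L)
  doms <- paste0("d", seq_len(n_domains))
  n_fam <- sample(1:4, 1L)
  fams <- list()
  for (i in seq_len(n_fam)) {
    mand <- sample(doms, sample(seq_len(min(3L, n_domains)), 1L))
    rest <- setdiff(doms, mand)
    forb <- if (length(rest) && stats::runif(1) < 0.6) {
      sample(rest, sample(seq_len(min(2L, length(rest))), 1L))
    } else character()
    fams[[paste0("FAM", LETTERS[i])]] <- list(mandatory = mand,
                                              forbidden = forb)
  }
  syn <- if (stats::runif(1) < 0.5) {
    stats::setNames(names(fams)[1L], paste0(names(fams)[1L], "-alias"))
  } else character()
  family_rules(fams, syn, provenance = "test")
}

# exhaustively compare classify_sequence() with the oracle over every hit
# subset of the rule set's domain universe, both modes
check_rules_against_oracle <- function(rules) {
  doms <- sort(unique(unlist(lapply(rules$families,
                                    function(f) c(f$mandatory, f$forbidden)))))
  ev <- stats::setNames(10^-(seq_along(doms) + 3), doms)
  bs <- stats::setNames(-2 * log10(ev), doms)
  for (k in seq_len(2^length(doms)) - 1L) {
    subset <- doms[bitwAnd(k, 2^(seq_along(doms) - 1L)) > 0L]
    if (!length(subset)) next
    hits <- domain_hits("s1", NA_character_, subset, ev[subset],
                        bs[subset], 1L, 15L)
    for (mode in c("strict", "best-domain")) {
      got <- classify_sequence(hits, rules, e_threshold = 1e-3, mode = mode)
      want <- oracle_classify(subset, ev, rules, mode)
      if (!identical(got$family, want$family) ||
          !identical(got$reason, want$reason)) {
        return(sprintf("disagreement (mode %s) on {%s}: got %s/%s want %s/%s",
                       mode, paste(subset, collapse = ","),
                       got$family, got$reason, want$family, want$reason))
      }
    }
  }
  TRUE
}

# deterministic stub aligner: left-justify, pad with gaps to equal length
pad_aligner <- function(seqs) {
  if (!length(seqs)) return(seqs)
  w <- max(nchar(seqs))
  out <- vapply(seqs, function(s) {
    paste0(s, strrep("-", w - nchar(s)))
  }, "")
  stats::setNames(out, names(seqs))
}

# random aligned block: n sequences x m columns over a tiny alphabet with
# gap proportion p
random_alignment <- function(n, m, p_gap = 0.3) {
  stats::setNames(vapply(seq_len(n), function(i) {
    paste(sample(c("A", "R", "N", "D", "-"), m, replace = TRUE,
                 prob = c(rep((1 - p_gap) / 4, 4), p_gap)), collapse = "")
  }, ""), paste0("s", seq_len(n)))
}

# random pipeline-record table over small id/family universes
random_records <- function(source, kind, n) {
  ids <- sprintf("T%02d", sample(1:12, n, replace = TRUE))
  frame <- if (kind == "transcript") {
    sample(c("+1", "+2", "-1"), n, replace = TRUE)
  } else NA_character_
  pipeline_records(source, kind, ids, frame,
                   sample(c("A", "B", "C"), n, replace = TRUE))
}

expect_oracle_ok <- function(res) {
  testthat::expect_true(isTRUE(res), info = if (!isTRUE(res)) res else NULL)
}
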