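# a small hand-written rule system in the field's family vocabulary
nf_rules <- family_rules(
  list(
    "CCAAT-HAP3" = list(mandatory = "D_NFYB", forbidden = character()),
    "CCAAT-HAP5" = list(mandatory = "D_NFYC", forbidden = character()),
    "B3"         = list(mandatory = "D_B3", forbidden = "D_AP2"),
    "AP2-EREBP"  = list(mandatory = "D_AP2", forbidden = character())
  ),
  synonyms = c("NF-YB" = "CCAAT-HAP3", "NF-YC" = "CCAAT-HAP5",
               "ABI3/VP1" = "B3")
)

hit1 <- function(domains, evalues, bits = -2 * log10(evalues)) {
  domain_hits("s1", NA_character_, domains, evalues, bits, 1L, 15L)
}

test_that("rule set invariants are enforced", {
  expect_error(family_rules(list(A = list(mandatory = character()))),
               "non-empty")
  expect_error(family_rules(list(A = list(mandatory = "D1",
                                          forbidden = "D1"))),
               "both mandatory and forbidden")
  expect_error(family_rules(list(A = list(mandatory = "D1")),
                            synonyms = c(x = "y", y = "A")),
               "one step")
  rc <- rule_counts(nf_rules)
  expect_equal(rc[["families"]], 4L)
  expect_equal(rc[["total"]], rc[["mandatory"]] + rc[["forbidden"]])
})

test_that("rule files round-trip through YAML with reported counts", {
  path <- withr::local_tempfile(fileext = ".yaml")
  save_rules(nf_rules, path)
  expect_message(reloaded <- load_rules(path), "4 families")
  expect_equal(reloaded$families, nf_rules$families)
  expect_equal(reloaded$synonyms, nf_rules$synonyms)

  empty <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_warning(r0 <- load_rules(empty), "empty")
  expect_length(r0$families, 0L)
})

test_that("synonyms resolve to canonical names in one step", {
  expect_equal(resolve_synonym("NF-YC", nf_rules), "CCAAT-HAP5")
  expect_equal(resolve_synonym("ABI3/VP1", nf_rules), "B3")
  expect_equal(resolve_synonym("CCAAT-HAP5", nf_rules), "CCAAT-HAP5")
  expect_warning(out <- resolve_synonym("NoSuchFamily", nf_rules), "unknown")
  expect_equal(out, "NoSuchFamily")
  # idempotence
  once <- resolve_synonym(c("NF-YB", "B3"), nf_rules)
  expect_equal(resolve_synonym(once, nf_rules), once)
})

test_that("single satisfied family is assigned", {
  a <- classify_sequence(hit1("D_NFYB", 1e-20), nf_rules)
  expect_equal(a$family, "CCAAT-HAP3")
  expect_equal(a$reason, "assigned")
})

test_that("multi-family evidence conflicts in strict mode, resolves in best-domain mode", {
  hits <- hit1(c("D_NFYB", "D_NFYC"), c(1e-40, 1e-10))
  strict <- classify_sequence(hits, nf_rules, mode = "strict")
  expect_true(is.na(strict$family))
  expect_equal(strict$reason, "multi-family-conflict")

  best <- classify_sequence(hits, nf_rules, mode = "best-domain")
  expect_equal(best$family, "CCAAT-HAP3")  # 1e-40 beats 1e-10
  expect_equal(best$reason, "assigned")
})

test_that("forbidden domains block assignment", {
  a <- classify_sequence(hit1(c("D_B3", "D_AP2"), c(1e-30, 1e-25)),
                         nf_rules, mode = "strict")
  # B3 blocked by forbidden AP2 domain, but AP2-EREBP itself is satisfied
  expect_equal(a$family, "AP2-EREBP")
  only_b3 <- family_rules(list(B3 = list(mandatory = "D_B3",
                                         forbidden = "D_AP2")))
  b <- classify_sequence(hit1(c("D_B3", "D_AP2"), c(1e-30, 1e-25)), only_b3)
  expect_true(is.na(b$family))
  expect_equal(b$reason, "forbidden-domain-present")
})

test_that("hits above the acceptance threshold are ignored", {
  a <- classify_sequence(hit1("D_NFYB", 1e-2), nf_rules, e_threshold = 1e-3)
  expect_equal(a$reason, "no-rule-satisfied")
})

test_that("mixed sequence ids are rejected", {
  h <- domain_hits(c("s1", "s2"), NA_character_, c("D_NFYB", "D_NFYB"),
                   c(1e-9, 1e-9))
  expect_error(classify_sequence(h, nf_rules), "exactly one")
})

test_that("satisfied synonym families collapse onto one canonical family", {
  r <- family_rules(
    list(X = list(mandatory = "D1"), Xsyn = list(mandatory = "D1")),
    synonyms = c(Xsyn = "X"))
  a <- classify_sequence(hit1("D1", 1e-9), r, mode = "strict")
  expect_equal(a$family, "X")
  expect_equal(a$reason, "assigned")
})

test_that("classification agrees with brute-force enumeration", {
  set.seed(101)
  for (i in 1:30) {
    expect_oracle_ok(check_rules_against_oracle(random_small_rules()))
  }
})

test_that("a forbidden-domain hit never rescues an assignment for its family", {
  set.seed(202)
  for (i in 1:25) {
    rules <- random_small_rules()
    fam <- sample(names(rules$families), 1L)
    forb <- rules$families[[fam]]$forbidden
    if (!length(forb)) next
    doms <- setdiff(unique(unlist(rules$families)), forb)
    if (!length(doms)) next
    subset <- sample(doms, sample(seq_along(doms), 1L))
    ev <- stats::setNames(10^-(seq_along(subset) + 4), subset)
    base <- classify_sequence(hit1(subset, ev), rules, mode = "strict")
    with_forb <- classify_sequence(
      hit1(c(subset, forb[1L]), c(ev, 1e-12)), rules, mode = "strict")
    if (is.na(base$family) || base$family != fam) {
      expect_false(identical(with_forb$family, fam))
    }
  }
})

test_that("best-domain assignments are a superset of strict assignments", {
  set.seed(303)
  for (i in 1:20) {
    rules <- random_small_rules()
    doms <- unique(unlist(rules$families))
    subset <- sample(doms, sample(seq_along(doms), 1L))
    ev <- stats::setNames(10^-(seq_along(subset) + 4), subset)
    strict <- classify_sequence(hit1(subset, ev), rules, mode = "strict")
    best <- classify_sequence(hit1(subset, ev), rules, mode = "best-domain")
    if (strict$reason == "assigned") {
      expect_equal(best$family, strict$family)
    }
    if (strict$reason == "multi-family-conflict") {
      expect_equal(best$reason, "assigned")
    }
  }
})

test_that("classify_set tabulates per-family counts and honors mode", {
  empty <- classify_set(domain_hits(character(), character(), character(),
                                    numeric()), nf_rules)
  expect_equal(nrow(empty$assignments), 0L)

  h <- domain_hits(c("s1", "s2", "s2"), NA_character_,
                   c("D_NFYB", "D_NFYB", "D_NFYC"),
                   c(1e-9, 1e-40, 1e-10))
  strict <- classify_set(h, nf_rules, mode = "strict")
  expect_equal(strict$counts$n[strict$counts$family == "CCAAT-HAP3"], 1L)
  expect_equal(sum(strict$counts$n), 1L)  # s2 conflicted out
  best <- classify_set(h, nf_rules, mode = "best-domain")
  expect_equal(sum(best$counts$n), 2L)    # s2 resolved to CCAAT-HAP3
  expect_equal(best$counts$n[best$counts$family == "CCAAT-HAP3"], 2L)
})

test_that("frames are classified independently", {
  h <- domain_hits(c("t1", "t1"), c("+1", "-2"), c("D_NFYB", "D_NFYC"),
                   c(1e-9, 1e-9))
  out <- classify_set(h, nf_rules)
  expect_equal(nrow(out$assignments), 2L)
  expect_setequal(out$assignments$family, c("CCAAT-HAP3", "CCAAT-HAP5"))
})
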