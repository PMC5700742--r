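test_that("spec validation rejects out-of-range parameters", {
  expect_error(synthetic_spec(decoy_rate = 1.5), "proportion")
  expect_error(synthetic_spec(hit_noise = -0.1), "proportion")
  expect_error(synthetic_spec(models_per_gene = c(0, 1)))
  expect_error(synthetic_spec(mandatory_fraction = 0.8,
                              forbidden_fraction = 0.8), "<= 1")
})

test_that("rule-set generation covers the requested family count", {
  spec <- synthetic_spec(n_families = 111, seed = 9)
  rules <- generate_rule_set(spec)
  expect_length(rules$families, 111L)
  expect_true(all(vapply(rules$families,
                         function(f) length(f$mandatory) >= 1L, TRUE)))
  expect_true(all(vapply(rules$families, function(f) {
    length(intersect(f$mandatory, f$forbidden)) == 0L
  }, TRUE)))
  expect_gte(length(rules$synonyms), 1L)

  empty <- generate_rule_set(synthetic_spec(n_families = 0))
  expect_length(empty$families, 0L)
})

test_that("identical seeds give byte-identical serialized outputs", {
  spec <- synthetic_spec(n_families = 5, seed = 1)
  r1 <- generate_rule_set(spec)
  r2 <- generate_rule_set(spec)
  p1 <- withr::local_tempfile(fileext = ".yaml")
  p2 <- withr::local_tempfile(fileext = ".yaml")
  save_rules(r1, p1); save_rules(r2, p2)
  expect_identical(readLines(p1), readLines(p2))

  g1 <- generate_proteome(r1, spec)
  g2 <- generate_proteome(r2, spec)
  expect_identical(g1$proteins, g2$proteins)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g1$transcripts, f1, "nucleotide")
  write_fasta(g2$transcripts, f2, "nucleotide")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted members classify to their family; decoys never do", {
  spec <- synthetic_spec(n_families = 1, family_size = c(3, 3),
                         models_per_gene = c(1, 1), decoy_rate = 0,
                         n_background = 0, seed = 3)
  rules <- generate_rule_set(spec)
  prot <- generate_proteome(rules, spec)
  expect_equal(nrow(prot$truth$models), 3L)
  cls <- classify_set(scan_domains(prot$proteins,
                                   attr(rules, "domain_motifs")), rules)
  expect_equal(cls$counts$n, 3L)
  expect_equal(cls$counts$family, names(rules$families)[1L])

  dspec <- synthetic_spec(n_families = 1, family_size = c(3, 3),
                          models_per_gene = c(1, 1), decoy_rate = 1,
                          n_background = 0, seed = 3)
  dprot <- generate_proteome(rules, dspec)
  expect_true(all(dprot$truth$models$decoy))
  dcls <- classify_set(scan_domains(dprot$proteins,
                                    attr(rules, "domain_motifs")), rules)
  expect_equal(sum(dcls$counts$n), 0L)
  expect_true(all(dcls$assignments$reason == "forbidden-domain-present"))
})

test_that("gene models nest inside genes in the ground truth", {
  spec <- synthetic_spec(n_families = 2, family_size = c(5, 5),
                         models_per_gene = c(2, 2), n_background = 0,
                         seed = 4)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  m <- prot$truth$models
  expect_equal(nrow(m), 20L)                          # 10 genes x 2 models
  expect_equal(length(unique(m$gene_id)), 10L)
  expect_equal(m$gene_id, gene_id_of(m$sequence_id))  # model -> gene map
  expect_lte(length(unique(m$gene_id)), nrow(m))
})

test_that("transcripts encode their protein in the recorded frame", {
  spec <- synthetic_spec(n_families = 2, family_size = c(2, 2), seed = 6)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  for (i in sample(nrow(prot$truth$models), 5)) {
    m <- prot$truth$models[i, ]
    tr <- six_frame_translate(prot$transcripts[[m$sequence_id]],
                              m$sequence_id)
    pep <- tr$peptide[tr$frame == m$frame]
    expect_true(grepl(prot$proteins[[m$sequence_id]], pep, fixed = TRUE))
  }
})

test_that("noise-free hit tables equal the planted architecture", {
  spec <- synthetic_spec(n_families = 3, hit_noise = 0, seed = 8)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  hits <- generate_domain_hits(prot)
  a <- prot$truth$architecture
  expect_equal(hits[, c("sequence_id", "domain", "start", "end")],
               a[, c("sequence_id", "domain", "start", "end")],
               ignore_attr = TRUE)
  # e-values monotone in match length by construction
  expect_true(all(hits$evalue == 10^-((hits$end - hits$start + 1) / 2)))
})

test_that("hit corruption is reproducible at a fixed seed", {
  spec <- synthetic_spec(n_families = 3, hit_noise = 0.5, seed = 8)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  h1 <- generate_domain_hits(prot)
  h2 <- generate_domain_hits(prot)
  expect_identical(h1, h2)
  expect_false(nrow(h1) == nrow(prot$truth$architecture))
})

test_that("drop-only noise retains hits at the binomial expectation", {
  base <- synthetic_spec(n_families = 5, family_size = c(4, 4),
                         models_per_gene = c(1, 1),
                         domains_per_family = c(1, 1), n_background = 0,
                         hit_noise = 0.1, seed = 1)
  rules <- generate_rule_set(base)
  prot <- generate_proteome(rules, base)
  n_planted <- nrow(prot$truth$architecture)
  expect_equal(n_planted, 20L)
  reps <- 400L
  kept <- vapply(seq_len(reps), function(i) {
    sp <- base; sp$seed <- 1000L + i
    nrow(generate_domain_hits(prot, sp, noise = "drop"))
  }, 0L)
  expected <- n_planted * 0.9
  se <- sqrt(n_planted * 0.9 * 0.1 / reps)
  expect_lt(abs(mean(kept) - expected), 3 * se)
})

test_that("zero-disagreement pipeline outputs mirror the truth", {
  spec <- synthetic_spec(n_families = 3, seed = 10)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  po <- generate_pipeline_outputs(prot, c(0, 0, 0))
  truth <- prot$truth$models
  truth <- truth[!is.na(truth$family) & !truth$decoy, ]
  for (src in c("tfcat", "itak", "rule")) {
    expect_equal(po[[src]]$sequence_id, truth$sequence_id)
    expect_equal(po[[src]]$family, truth$family)
    expect_equal(po[[src]]$frame, truth$frame)
  }
  expect_true(all(is.na(po$protein$frame)))
})

test_that("a family dropped by one source is recovered from the others", {
  spec <- synthetic_spec(n_families = 3, seed = 11)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  po <- generate_pipeline_outputs(prot, c(0, 0, 0))
  fam_a <- po$protein$family[1L]
  # protein source loses family A entirely; transcripts still carry it
  po$protein <- po$protein[po$protein$family != fam_a, ]
  m <- merge_repertoires(po$protein, po$tfcat, po$itak, po$rule)
  expect_true(fam_a %in% m$accepted$family)
})

test_that("duplicate (transcript, frame) claims collapse to one record", {
  spec <- synthetic_spec(n_families = 2, seed = 12)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  po <- generate_pipeline_outputs(prot, c(0, 0, 0))
  m <- merge_repertoires(tfcat = po$tfcat, itak = po$itak)
  key <- paste(m$accepted$sequence_id, m$accepted$frame, m$accepted$family)
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(nrow(m$accepted), nrow(po$tfcat))
  expect_true(all(m$accepted$source == "tfcat"))
})

test_that("expression matrices carry the requested tissues and zero rows", {
  spec <- synthetic_spec(n_families = 2, seed = 13)
  prot <- generate_proteome(generate_rule_set(spec), spec)
  ex <- generate_expression(prot, tissues = c("root", "pod_16d"), seed = 99)
  expect_equal(colnames(ex$fpkm), c("root", "pod_16d"))
  expect_true(all(ex$fpkm >= 0))
  expect_equal(nrow(ex$links), length(prot$transcripts))
  # all-zero rows are legal and preserved through joins
  zr <- which(rowSums(ex$fpkm) == 0)[1L]
  if (!is.na(zr)) {
    expect_true(all(ex$fpkm[zr, ] == 0))
  }
})

test_that("planted clade labels are recovered from anchored trees", {
  at <- generate_anchored_tree(c(IIa = 4, IIc = 3, III = 5), seed = 14)
  got <- assign_groups(at$tree, at$anchors)
  expect_equal(got[names(at$truth)], at$truth)
})
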