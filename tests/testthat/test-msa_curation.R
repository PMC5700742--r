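test_that("row coverage filter is strict and drops duplicates", {
  aln <- c(full = "ARNDCEQGHI",
           sparse = "AR--------",        # 20% coverage
           boundary = "ARN-------",      # exactly 30%
           full2 = "ARNDCEQGHI")         # duplicate of 'full'
  out <- drop_low_coverage(aln, 0.30)
  expect_named(out, c("full", "boundary"))
})

test_that("gap-column filter removes columns at >= the gap fraction", {
  rows <- c(paste0("A", "R"), rep("-R", 9))           # col1: 9/10 gaps
  aln <- stats::setNames(rows, paste0("s", 1:10))
  out <- drop_gappy_columns(aln, 0.90)
  expect_equal(nchar(out[[1L]]), 1L)                  # 90% column removed

  rows2 <- c(rep("AR", 2), rep("-R", 8))              # col1: 80% gaps
  aln2 <- stats::setNames(rows2, paste0("s", 1:10))
  expect_equal(nchar(drop_gappy_columns(aln2, 0.90)[[1L]]), 2L)

  solid <- c(a = "AR", b = "AR")
  expect_equal(drop_gappy_columns(solid, 0.90), solid)
})

test_that("pairwise identity excludes dual-gap columns", {
  expect_equal(pairwise_identity("AR-ND", "AR-ND"), 1)
  expect_equal(pairwise_identity("ARND", "ARNC"), 0.75)
  expect_equal(pairwise_identity("A---", "A---"), 1)  # one comparable column
  expect_true(is.na(pairwise_identity("--", "--")))
})

test_that("near-duplicate removal is greedy against the kept set", {
  twin <- c(a = "ARNDCEQGHI", b = "ARNDCEQGHI")
  expect_named(drop_near_duplicates(twin, 0.95), "a")

  # identity 0.94 < 0.95: both kept (50 columns, 3 mismatches)
  base <- strrep("AR", 25)
  v <- sub("^ARARAR", "NRNRNR", base)
  expect_length(drop_near_duplicates(c(a = base, b = v), 0.95), 2L)

  # chain: a~b 96%, b~c 96%, a~c 92% -> keep a and c
  a <- strrep("A", 50)
  b <- paste0(strrep("R", 2), strrep("A", 48))       # 96% to a
  cc <- paste0(strrep("R", 2), strrep("N", 2), strrep("A", 46))
  expect_equal(pairwise_identity(a, b), 0.96)
  expect_equal(pairwise_identity(b, cc), 0.96)
  expect_equal(pairwise_identity(a, cc), 0.92)
  expect_named(drop_near_duplicates(c(a = a, b = b, c = cc), 0.95),
               c("a", "c"))
})

test_that("curation terminates at a fixed point on stable input", {
  seqs <- c(s1 = "ARNDCEQGHI", s2 = "MKVWFPSTYA")
  res <- curation_cycle(seqs, pad_aligner)
  expect_true(res$converged)
  expect_equal(sort(names(res$alignment)), c("s1", "s2"))
  expect_equal(strip_gaps <- gsub("-", "", res$alignment), seqs)
})

test_that("a low-coverage sequence is eliminated by the cycle", {
  seqs <- c(long1 = strrep("ARNDCEQGHI", 4),
            long2 = strrep("MKVWFPSTYA", 4),
            stub = "AR")  # 5% of the padded alignment
  res <- curation_cycle(seqs, pad_aligner)
  expect_false("stub" %in% names(res$alignment))
  expect_true(res$converged)
})

test_that("cycle log is monotone non-increasing and bounded", {
  set.seed(31)
  for (i in 1:20) {
    aln <- random_alignment(sample(3:10, 1), sample(10:30, 1))
    seqs <- stats::setNames(gsub("-", "", aln), names(aln))
    seqs <- seqs[nzchar(seqs)]
    if (!length(seqs)) next
    res <- curation_cycle(seqs, pad_aligner,
                          curation_params(max_cycles = 100L))
    expect_true(all(diff(res$log$sequences) <= 0))
    expect_lte(nrow(res$log), sum(nchar(seqs)) + 2L)
    expect_true(res$converged)
  }
})

test_that("the filter order row->column->near-duplicate is pinned", {
  # 10 rows x 6 cols; row 'x' covers 2/6 columns, but its coverage rises to
  # 2/3 once the three 90%-gap columns go: the two filter orders disagree
  # on x's fate, and the pipeline applies the row filter first
  aln <- c(stats::setNames(paste0("---AR", strsplit("ARNDCEQG", "")[[1L]]),
                           paste0("s", 1:8)),
           x = "---AR-",
           y = "RRR-AN")
  rowfirst <- drop_gappy_columns(drop_low_coverage(aln, 0.5), 0.9)
  colfirst <- drop_low_coverage(drop_gappy_columns(aln, 0.9), 0.5)
  expect_false("x" %in% names(rowfirst))
  expect_true("x" %in% names(colfirst))

  keep_rows_aligner <- function(seqs) aln[names(seqs)]
  res <- curation_cycle(stats::setNames(gsub("-", "", aln), names(aln)),
                        keep_rows_aligner,
                        curation_params(min_seq_coverage = 0.5,
                                        max_col_gap_frac = 0.9,
                                        max_pairwise_identity = 0.95))
  expect_false("x" %in% names(res$alignment))
})

test_that("aligner failures propagate with the cycle index", {
  boom <- function(seqs) stop("no alignment today")
  expect_error(curation_cycle(c(a = "AR"), boom), "cycle 1")
})

test_that("curated sequences are motif concatenations in start order", {
  m <- data.frame(sequence_id = "s", motif_id = c("m2", "m1"),
                  start = c(50L, 10L), end = c(52L, 12L),
                  residues = c("DEF", "ABC"))
  expect_equal(build_curated_sequence(m), "ABCDEF")
  expect_equal(build_curated_sequence(m[1L, ]), "DEF")
  ov <- data.frame(start = c(10L, 12L), end = c(13L, 15L),
                   residues = c("ABCD", "CDEF"))
  expect_equal(build_curated_sequence(ov), "ABCDCDEF")
  expect_equal(nchar(build_curated_sequence(ov)), sum(nchar(ov$residues)))
  expect_equal(build_curated_sequence(m[0L, ]), "")
})

test_that("motif tables read from TSV and validate coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tmotif_id\tstart\tend\tresidues",
               "s1\tm1\t10\t12\tABC"), path)
  m <- read_motifs(path)
  expect_equal(m$residues, "ABC")
  writeLines(c("sequence_id\tmotif_id\tstart\tend\tresidues",
               "s1\tm1\t12\t10\tABC"), path)
  expect_error(read_motifs(path), "start")
})
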