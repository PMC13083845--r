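test_that("CIGAR arithmetic produces the expected aligned blocks", {
  sam <- tmp_sam(c(sam_record("r1", 11, "50M100N50M"),
                   sam_record("r2", 11, "5S95M"),
                   sam_record("r3", 101, "20M5D20M"),
                   "u1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"))
  ar <- read_alignments(sam)
  expect_identical(nrow(ar$reads), 3L)  # unmapped excluded
  # 0-based: read at pos 10 with 50M100N50M -> [10,60) and [160,210)
  b1 <- ar$blocks[[which(ar$reads$qname == "r1")]]
  expect_identical(BiocGenerics::start(b1) - 1L, c(10L, 160L))
  expect_identical(BiocGenerics::end(b1), c(60L, 210L))
  # soft clips consume the read only
  b2 <- ar$blocks[[which(ar$reads$qname == "r2")]]
  expect_identical(BiocGenerics::start(b2) - 1L, 10L)
  expect_identical(BiocGenerics::width(b2), 95L)
  # deletions stay inside one block
  b3 <- ar$blocks[[which(ar$reads$qname == "r3")]]
  expect_identical(length(b3), 1L)
  expect_identical(BiocGenerics::width(b3), 45L)
})

test_that("malformed SAM input raises distinct errors", {
  bad_cigar <- tmp_sam(sam_record("r1", 11, "50M100Q"))
  expect_error(read_alignments(bad_cigar), "malformed")
  no_header <- tempfile(fileext = ".sam")
  writeLines(sam_record("r1", 11, "50M"), no_header)
  expect_error(read_alignments(no_header), "@SQ header")
  expect_error(read_alignments(tempfile()), "not found")
})

test_that("junctions are counted under the anchor rule and keyed exactly", {
  recs <- c(
    vapply(1:80, function(i) sam_record(sprintf("j%02d", i), 11,
                                        "50M100N50M"), ""),
    # 3-base left anchor: not counted with the default min_anchor = 6
    sam_record("short", 58, "3M100N50M"),
    # a second, distinct junction
    sam_record("alt1", 11, "50M200N50M"),
    sam_record("alt2", 11, "50M200N50M"))
  ar <- read_alignments(tmp_sam(recs))
  jc <- count_junctions(ar)
  expect_identical(nrow(jc), 2L)
  expect_identical(jc$donor_end, c(60L, 60L))
  expect_identical(jc$acceptor_start, c(160L, 260L))
  expect_identical(jc$read_count, c(80L, 2L))
  expect_identical(attr(jc, "n_unanchored"), 1L)
  # with a permissive anchor the short read is counted too
  jc1 <- count_junctions(ar, min_anchor = 1L)
  expect_identical(jc1$read_count[jc1$acceptor_start == 160L], 81L)
})

test_that("spliced fraction is J/(J+I) with the documented edge cases", {
  recs <- c(
    vapply(1:80, function(i) sam_record(sprintf("j%02d", i), 11,
                                        "50M100N50M"), ""),
    # intron-interior reads: 50 aligned bases inside [60,160)
    vapply(1:20, function(i) sam_record(sprintf("i%02d", i), 81, "50M"), ""))
  ar <- read_alignments(tmp_sam(recs))
  q <- quantify_splicing(ar)
  expect_identical(nrow(q$junctions), 1L)
  expect_identical(q$junctions$read_count, 80L)
  expect_equal(q$junctions$spliced_fraction, 0.80)

  # J = 0 with intron coverage: fraction 0, not missing
  ar0 <- read_alignments(tmp_sam(
    vapply(1:50, function(i) sam_record(sprintf("i%02d", i), 81, "50M"), "")))
  f0 <- spliced_fraction(list(rname = "plas", donor_end = 60,
                              acceptor_start = 160), ar0)
  expect_identical(f0, 0)

  # no informative reads at all: missing value, not a crash
  far <- read_alignments(tmp_sam(sam_record("x", 900, "20M")))
  expect_true(is.na(spliced_fraction(list(rname = "plas", donor_end = 60,
                                          acceptor_start = 160), far)))
})

test_that("reads contribute to at most one of J or I per junction", {
  recs <- c(sam_record("j1", 11, "50M100N50M"),   # J for [60,160)
            sam_record("sub", 11, "60M80N60M"),   # gap [70,150): I (inside)
            sam_record("out", 601, "50M"))        # neither
  ar <- read_alignments(tmp_sam(recs))
  f <- spliced_fraction(list(rname = "plas", donor_end = 60,
                             acceptor_start = 160), ar)
  # J = 1 (j1), I = 1 (sub aligns 10 bases in [60,70) inside the intron)
  expect_equal(f, 0.5)
})

test_that("report values are invariant to read order", {
  recs <- c(vapply(1:30, function(i) sam_record(sprintf("j%02d", i), 11,
                                                "50M100N50M"), ""),
            vapply(1:10, function(i) sam_record(sprintf("i%02d", i), 81,
                                                "50M"), ""))
  set.seed(3)
  q1 <- quantify_splicing(read_alignments(tmp_sam(recs)))
  q2 <- quantify_splicing(read_alignments(tmp_sam(sample(recs))))
  expect_identical(q1$junctions, q2$junctions)
})

test_that("junction quantification recovers simulated spliced fractions", {
  rep <- make_reporter(seed = 19)
  for (psi in c(0, 0.05, 0.2, 0.5, 1)) {
    n <- 5000L
    sim <- simulate_reads(rep$reference, rep$intron, psi = psi, n_reads = n,
                          read_length = 100L, seed = 23 + round(100 * psi),
                          span_junction = TRUE)
    q <- quantify_splicing(read_alignments(sim$sam))
    est <- if (nrow(q$junctions) == 0L) 0 else {
      expect_identical(q$junctions$donor_end, rep$intron[1])
      expect_identical(q$junctions$acceptor_start, rep$intron[2])
      q$junctions$spliced_fraction[1]
    }
    se <- sqrt(max(psi * (1 - psi), 1e-12) / n)
    expect_lt(abs(est - psi), 3 * se + 1e-9)
  }
})

test_that("coverage track reflects aligned blocks only", {
  ar <- read_alignments(tmp_sam(c(sam_record("a", 1, "10M30N10M"),
                                  sam_record("b", 1, "10M"))))
  cov <- junction_coverage(ar)
  expect_identical(cov$depth[1], 2L)    # pos 0
  expect_identical(cov$depth[15], 0L)   # inside the gap
  expect_identical(cov$depth[45], 1L)   # second block of read a
})
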