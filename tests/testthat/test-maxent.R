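test_that("model loading is deterministic and immutable", {
  m1 <- load_splice_model()
  m2 <- load_splice_model()
  expect_identical(m1$checksum, m2$checksum)
  expect_identical(m1$type, "order1")
  probes <- c("CAGGTAAGT", "TTTGTTTTT", "GAGGTAGTA")
  expect_identical(score_donor(probes, m1), score_donor(probes, m2))
})

test_that("corrupt or missing model tables are detected by name", {
  src <- system.file("extdata", "splice_model_synthetic",
                     package = "spliceaudit")
  dir <- tempfile("model"); dir.create(dir)
  file.copy(list.files(src, full.names = TRUE), dir)
  # truncate one table
  tab <- file.path(dir, "donor_frequencies.tsv")
  writeLines(readLines(tab)[1:4], tab)
  expect_error(load_splice_model(dir), "donor_frequencies")
  unlink(tab)
  expect_error(load_splice_model(dir), "missing model table")
  expect_error(load_splice_model(tempfile()), "not found")
})

test_that("scores agree with an independent per-position oracle", {
  for (kind in c("donor", "acceptor")) {
    width <- splice_geometry(kind)$width
    wins <- random_windows(400, width, seed = 7 + width)
    got <- if (kind == "donor") score_donor(wins, test_model) else
      score_acceptor(wins, test_model)
    want <- vapply(wins, oracle_score, numeric(1), kind = kind,
                   USE.NAMES = FALSE)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("scoring is normalization-invariant and deterministic", {
  expect_identical(score_donor("caggtaagt", test_model),
                   score_donor("CAGGTAAGT", test_model))
  expect_identical(score_donor("CAGGUAAGU", test_model),
                   score_donor("CAGGTAAGT", test_model))
  acc <- "CTCTCTCTCTCTCTCTCCAGGCT"
  expect_identical(score_acceptor(chartr("T", "u", acc), test_model),
                   score_acceptor(acc, test_model))
  expect_identical(score_donor("CAGGTAAGT", test_model),
                   score_donor("CAGGTAAGT", test_model))
})

test_that("frozen consensus-window scores guard against fixture drift", {
  expect_equal(score_donor("CAGGTAAGT", test_model), 12.8048258204,
               tolerance = 1e-8)
  expect_equal(score_acceptor("CTCTCTCTCTCTCTCTCCAGGCT", test_model),
               18.3116202114, tolerance = 1e-8)
  expect_equal(score_donor("AAGGTACCT", test_model), 5.4196301268,
               tolerance = 1e-8)
})

test_that("score functions reject malformed windows with distinct errors", {
  expect_error(score_donor("CAGGTAAG", test_model), "length")
  expect_error(score_acceptor("CAGGTAAGT", test_model), "length")
  expect_error(score_donor("CAGGTAAGX", test_model), "outside")
  expect_error(score_donor("CAGGTAAGN", test_model), "summarize_ambiguous")
})

test_that("summarize_ambiguous matches brute-force expansion", {
  s <- summarize_ambiguous("NNGGTACCN", "donor", tau = 0, model = test_model)
  expect_identical(s$n_expansions, 64L)
  # independent brute force: expand.grid over N slots + oracle scorer
  grid <- expand.grid(n1 = c("A", "C", "G", "T"), n2 = c("A", "C", "G", "T"),
                      n9 = c("A", "C", "G", "T"), stringsAsFactors = FALSE)
  brute <- apply(grid, 1, function(r) {
    oracle_score(paste0(r[1], r[2], "GGTACC", r[3]), "donor")
  })
  expect_equal(s$min_score, min(brute), tolerance = 1e-9)
  expect_equal(s$max_score, max(brute), tolerance = 1e-9)
  expect_equal(s$fraction_ge_tau, mean(brute >= 0), tolerance = 1e-12)
})

test_that("summarize_ambiguous handles degenerate and oversized patterns", {
  s <- summarize_ambiguous("CAGGTAAGT", "donor", model = test_model)
  expect_identical(s$n_expansions, 1L)
  expect_equal(s$min_score, s$max_score)
  expect_equal(s$min_score, score_donor("CAGGTAAGT", test_model))

  s4 <- summarize_ambiguous("GAGGTAGTN", "donor", model = test_model)
  expect_identical(s4$n_expansions, 4L)
  expect_equal(s4$min_score,
               min(score_donor(paste0("GAGGTAGT", c("A", "C", "G", "T")),
                               test_model)))
  expect_error(summarize_ambiguous(strrep("N", 23), "acceptor",
                                   model = test_model,
                                   max_expansions = 1000L), "cap")
  expect_error(summarize_ambiguous("NNGGTACC", "donor", model = test_model),
               "length")
  expect_error(summarize_ambiguous("NNGGTAC!N", "donor", model = test_model),
               "IUPAC")
})

test_that("native MaxEntScan-format table directories load and score", {
  # synthetic stand-in tables in the reference file layout, with values
  # chosen deterministically so the expected score can be hand-computed
  dir <- tempfile("mes"); dir.create(dir)
  set.seed(99)
  me2x5 <- exp(stats::rnorm(4^7, sd = 0.3))
  writeLines(format(me2x5, digits = 10), file.path(dir, "me2x5"))
  acc_lens <- c(4^7, 4^7, 4^7, 4^7, 4^7, 4^3, 4^4, 4^3, 4^4)
  acc_tabs <- lapply(seq_len(9), function(k) {
    set.seed(100 + k)
    exp(stats::rnorm(acc_lens[k], sd = 0.3))
  })
  for (k in seq_len(9)) {
    writeLines(format(acc_tabs[[k]], digits = 10),
               file.path(dir, paste0("me2x3acc", k)))
  }
  m <- load_splice_model(dir)
  expect_identical(m$type, "maxentscan")

  idx <- function(bases) {
    d <- match(bases, c("A", "C", "G", "T")) - 1L
    sum(d * 4^(rev(seq_along(d)) - 1L)) + 1L
  }
  # donor: consensus odds at GT x the 7-mer table entry
  win <- "CAGGTAAGT"
  ch <- strsplit(win, "")[[1]]
  bgd <- c(A = 0.27, C = 0.23, G = 0.23, T = 0.27)
  want <- log2(0.9896 / bgd[["G"]]) + log2(0.9885 / bgd[["T"]]) +
    log2(me2x5[idx(ch[c(1:3, 6:9)])])
  expect_equal(score_donor(win, m), want, tolerance = 1e-9)

  # acceptor: product of tables 1-5 over quotient of 6-9
  aw <- "CTCTCTCTCTCTCTCTCCAGGCT"
  ac <- strsplit(aw, "")[[1]][c(1:18, 21:23)]
  segs <- list(1:7, 8:14, 15:21, 5:11, 12:18, 5:7, 8:11, 12:14, 15:18)
  signs <- c(1, 1, 1, 1, 1, -1, -1, -1, -1)
  want3 <- log2(0.9903 / bgd[["A"]]) + log2(0.9906 / bgd[["G"]])
  for (k in seq_len(9)) {
    want3 <- want3 + signs[k] * log2(acc_tabs[[k]][idx(ac[segs[[k]]])])
  }
  expect_equal(score_acceptor(aw, m), want3, tolerance = 1e-9)

  # corruption: wrong table length
  writeLines("1.0", file.path(dir, "me2x3acc9"))
  expect_error(load_splice_model(dir), "me2x3acc9")
})
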