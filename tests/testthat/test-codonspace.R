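test_that("encoding counts are exact degeneracy products", {
  expect_identical(count_encodings("HHHHHH"), 64)
  expect_identical(count_encodings("DYKDDDDK"), 256)
  # verified against full enumeration below
  expect_identical(count_encodings("EQKLISEEDL"), 41472)
  expect_error(count_encodings(peptide("x", "ACD")), NA)
})

test_that("exhaustive enumeration is complete, unique, and lexicographic", {
  hh <- generate_encodings("HH", mode = "exhaustive")
  expect_identical(hh, c("CACCAC", "CACCAT", "CATCAC", "CATCAT"))
  myc <- generate_encodings("EQKLISEEDL", mode = "exhaustive",
                            exhaustive_cap = 1e6)
  expect_identical(length(myc), 41472L)
  expect_identical(anyDuplicated(myc), 0L)
  expect_true(all(vapply(myc[c(1, 41472)], translate_encoding, "") ==
                    "EQKLISEEDL"))
  expect_error(generate_encodings("GKPIPNPLLGLDST", mode = "exhaustive",
                                  exhaustive_cap = 1e4), "cap")
})

test_that("sampled enumeration is seed-deterministic with the stated length", {
  a <- generate_encodings("GKPIPNPLLGLDST", mode = "sampled", n = 10, seed = 1)
  b <- generate_encodings("GKPIPNPLLGLDST", mode = "sampled", n = 10, seed = 1)
  expect_identical(a, b)
  expect_identical(length(a), 10L)
  expect_true(all(vapply(a, translate_encoding, "") == "GKPIPNPLLGLDST"))
  c2 <- generate_encodings("GKPIPNPLLGLDST", mode = "sampled", n = 10,
                           seed = 2)
  expect_false(identical(a, c2))
  expect_error(generate_encodings("GG", mode = "sampled", n = 0, seed = 1),
               "n >= 1")
  expect_error(generate_encodings("GG", mode = "sampled", n = 5), "seed")
})

test_that("GT/AG-free codon spaces are never splicing-prone", {
  his <- risk_profile("HHHHHH", test_model, mode = "exhaustive")
  expect_identical(his$prone5_fraction, 0)
  expect_identical(his$prone3_fraction, 0)
  expect_identical(his$n_evaluated, 64L)
  # 18 nt cannot host a 23-mer acceptor window at all
  expect_identical(his$mode, "exhaustive")

  flag <- risk_profile("DYKDDDDK", test_model, mode = "exhaustive",
                       keep_records = TRUE)
  expect_identical(flag$prone5_fraction, 0)
  expect_true(all(is.na(flag$records$max_donor)))
  expect_false(any(grepl("GT", flag$records$encoding, fixed = TRUE)))
})

test_that("risk profile invariants hold on a sampled tag ensemble", {
  rp <- risk_profile("GKPIPNPLLGLDST", test_model, mode = "sampled",
                     n = 4000, seed = 9)
  expect_true(rp$prone_both_fraction <=
                min(rp$prone5_fraction, rp$prone3_fraction))
  expect_true(all(c(rp$prone5_fraction, rp$prone3_fraction) <= 1))
  rp2 <- risk_profile("GKPIPNPLLGLDST", test_model, mode = "sampled",
                      n = 4000, seed = 9)
  expect_identical(rp[c("prone5_fraction", "prone3_fraction",
                        "prone_both_fraction")],
                   rp2[c("prone5_fraction", "prone3_fraction",
                         "prone_both_fraction")])
})

test_that("sampled fractions converge to the exhaustive truth", {
  # Gln-Val-Ser: the classic codon-optimization donor-site example; its
  # 48-encoding space is exactly enumerable
  ex <- risk_profile("QVS", test_model, mode = "exhaustive")
  expect_true(ex$prone5_fraction > 0)
  n <- 4000
  sa <- risk_profile("QVS", test_model, mode = "sampled", n = n, seed = 13)
  se <- sqrt(ex$prone5_fraction * (1 - ex$prone5_fraction) / n)
  expect_lt(abs(sa$prone5_fraction - ex$prone5_fraction), 3 * se + 1e-12)
})

test_that("per-encoding records match direct window scoring", {
  rp <- risk_profile("QVS", test_model, mode = "exhaustive",
                     keep_records = TRUE)
  expect_identical(nrow(rp$records), 48L)
  for (i in c(1L, 17L, 48L)) {
    enc <- rp$records$encoding[i]
    want <- naive_find_windows(enc, "donor", tau = -Inf)
    if (nrow(want) == 0L) {
      expect_true(is.na(rp$records$max_donor[i]))
    } else {
      expect_equal(rp$records$max_donor[i], max(want$score),
                   tolerance = 1e-9)
    }
  }
})

test_that("expand_N worst-case flanks dominate internal-only scoring", {
  internal <- risk_profile("GGS", test_model, mode = "exhaustive")
  expanded <- risk_profile("GGS", test_model, mode = "exhaustive",
                           flank_policy = "expand_N")
  expect_true(expanded$prone5_fraction >= internal$prone5_fraction)
  # a 9-nt tag has exactly one internal donor frame but many N-extended ones
  expect_true(expanded$prone5_fraction > 0)

  # the worked Gly-Gly-Ser example: GGAGGTAGT plus worst-case trailing base
  codes <- spliceaudit:::.code_matrix("GGAGGTAGT", 9L)
  mx <- spliceaudit:::.max_window_scores(codes, "donor", test_model,
                                         "expand_N")
  # the window GAGGTAGT+N (maximized over N) is one of the N-extended
  # windows, so the expand_N maximum must dominate it
  s2 <- summarize_ambiguous("GAGGTAGTN", "donor", model = test_model)
  expect_true(mx >= s2$max_score - 1e-9)
})

test_that("fixed flanks reproduce scoring in explicit context", {
  left <- "CCCCCCCCCCCCCCCAAACAG"   # >= 18 bases for the acceptor tract
  right <- "AAGTAAAACCCCCCCCCCCCCCCCCC"
  rec <- risk_profile("VS", test_model, mode = "exhaustive",
                      flank_policy = "fixed_flanks",
                      flanks = c(left, right),
                      keep_records = TRUE)
  i <- which(rec$records$encoding == "GTAAGT")
  want <- naive_find_windows(paste0("CAG", "GTAAGT", "AAGT"), "donor",
                             tau = -Inf)
  expect_equal(rec$records$max_donor[i], max(want$score), tolerance = 1e-9)
  expect_error(risk_profile("VS", test_model, mode = "exhaustive",
                            flank_policy = "fixed_flanks",
                            flanks = c("A", "C")), "flanks")
})

test_that("linker prone fraction grows with repeat count", {
  curve <- linker_prone_curve("GGGGS", repeats = c(1, 2, 3), test_model,
                              n = 3000, seed = 41)
  expect_identical(curve$length_nt, c(15L, 30L, 45L))
  expect_true(curve$prone5_fraction[3] > curve$prone5_fraction[1])
  expect_true(all(diff(curve$prone5_fraction) > -0.02),
              info = "non-decreasing within sampling error")
  flat <- linker_prone_curve("HHHHHH", repeats = 1:2, test_model, n = 500,
                             seed = 42)
  expect_identical(flat$prone5_fraction, c(0, 0))
  expect_error(linker_prone_curve("GGGGS", repeats = 1:2, test_model,
                                  n = 0, seed = 1), "n must be")
})
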