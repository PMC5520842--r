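test_that("NG86 site fractions and counts match direct enumeration", {
  # TTT: only the third position has a synonymous mutant (TTC -> Phe)
  self <- ng86_counts("TTT", "TTT")
  expect_equal(self[["S"]], 1 / 3, tolerance = 1e-12)
  expect_equal(self[["N"]], 3 - 1 / 3, tolerance = 1e-12)
  expect_equal(self[["Sd"]], 0)
  expect_equal(self[["Nd"]], 0)

  set.seed(51)
  codons <- sample(sense_codons(), 100, replace = TRUE)
  same <- ng86_counts(codons, codons)
  expect_equal(same[["Sd"]], 0)
  expect_equal(same[["Nd"]], 0)
  expect_equal(same[["S"]] + same[["N"]], 300)

  # random single-codon pairs with <= 2 differences vs the pathway oracle
  for (rep in 1:120) {
    pr <- random_codon_pair(2)
    got <- ng86_counts(pr[1], pr[2])
    want <- oracle_ng86_codon(pr[1], pr[2])
    expect_equal(got, want, tolerance = 1e-12)
  }

  # three-difference codons average over all six stop-free pathways
  for (rep in 1:25) {
    pr <- random_codon_pair(3)
    got <- ng86_counts(pr[1], pr[2])
    want <- oracle_ng86_codon(pr[1], pr[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("NG86 counting is symmetric and order-invariant", {
  set.seed(61)
  a <- sample(sense_codons(), 50, replace = TRUE)
  b <- vapply(a, function(cd) random_mutant(cd, 2), character(1))
  ab <- ng86_counts(a, b)
  ba <- ng86_counts(b, a)
  expect_equal(ab, ba, tolerance = 1e-12)
  perm <- sample(50)
  expect_equal(ng86_counts(a[perm], b[perm]), ab, tolerance = 1e-12)

  expect_error(ng86_counts("TAA", "TAA"), "stop")
  expect_error(ng86_counts(c("ATG", "AAA"), "ATG"), "equal length")
})

test_that("Jukes-Cantor corrected rates and the ratio behave as defined", {
  est <- kaks_estimate(c(S = 10, N = 20, Sd = 1, Nd = 0))
  expect_equal(est$Ks, -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-12)
  expect_equal(est$Ks, 0.10733, tolerance = 1e-4)
  expect_equal(est$Ka, 0)
  expect_equal(est$ratio, 0)        # Ks > 0, Ka = 0: defined, zero
  expect_error(kaks_estimate(c(S = 10, N = 20, Sd = 8, Nd = 0)),
               "saturated")
  expect_error(kaks_estimate(c(S = 0, N = 20, Sd = 0, Nd = 0)), "positive")

  none <- kaks_estimate(c(S = 10, N = 20, Sd = 0, Nd = 0))
  expect_equal(none$Ka, 0)
  expect_equal(none$Ks, 0)
  expect_true(is.na(none$ratio))
})

test_that("selection classification matches the published calls", {
  expect_equal(classify_selection(0.1706), "purifying")
  expect_equal(classify_selection(2.4152), "positive")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(NA_real_), "undetermined")
  expect_equal(classify_selection(0.95, epsilon = 0.1), "neutral")

  # all seven published (Ka, Ks) pairs reclassify to the printed column
  t2 <- opt_table2()
  cls <- vapply(t2$Ka / t2$Ks, classify_selection, character(1))
  expect_equal(sum(cls == "purifying"), 5L)
  expect_equal(sum(cls == "positive"), 2L)
})

test_that("back-translation maps aligned residues to codons and round-trips", {
  cp <- back_translate_align(c(x = "M-K", y = "MAK"),
                             c(x = "ATGAAA", y = "ATGGCTAAA"),
                             pairs = list(c("x", "y")))
  expect_equal(cp[[1]]$codons_a, c("ATG", "AAA"))
  expect_equal(cp[[1]]$codons_b, c("ATG", "AAA"))

  expect_error(back_translate_align(c(x = "MK"), c(x = "ATGAA")),
               "divisible")
  expect_error(back_translate_align(c(x = "MM", y = "MM"),
                                    c(x = "ATGAAA", y = "ATGATG")),
               "x at residue 2")

  set.seed(71)
  code <- standard_genetic_code()
  for (rep in 1:10) {
    codons <- sample(sense_codons(), 30, replace = TRUE)
    cds <- paste(codons, collapse = "")
    prot <- paste(code[codons], collapse = "")
    got <- back_translate_align(c(g1 = prot, g2 = prot),
                                c(g1 = cds, g2 = cds),
                                pairs = list(c("g1", "g2")))
    expect_equal(got[[1]]$codons_a, codons)
  }
})

test_that("kaks_pairs runs end-to-end on simulated diverged sequences", {
  sim <- simulate_codon_pair(300, 0.2, 0.3, seed = 101)
  res <- kaks_pairs(c(a = sim$cds_a, b = sim$cds_b),
                    pairs = data.frame(id_a = "a", id_b = "b"))
  expect_equal(nrow(res), 1L)
  expect_gt(res$Ks, 0.05)
  expect_equal(res$selection, "purifying")
  expect_equal(res$S + res$N, 900)
})
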