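test_that("motif scan finds exact and planted occurrences, agrees with naive scan", {
  hits <- scan_motif("MMSPYAEVRGGVQQQDDPKK", "SPYxEVRxxVxxxDDP")
  expect_equal(hits$start, 3L)
  expect_equal(nchar(hits$matched), 16L)

  expect_equal(nrow(scan_motif("AAAA", "SPYxEVRxxVxxxDDP")), 0L)

  set.seed(11)
  motif <- "SPYxEVRxxVxxxDDP"
  instance <- "SPYAEVRGGVQQQDDP"
  for (rep in 1:30) {
    body <- strsplit(random_protein(500), "")[[1]]
    pos <- sort(sample(seq_len(500 - 16), 2))
    while (diff(pos) < 16) pos <- sort(sample(seq_len(500 - 16), 2))
    for (p in pos) body[p:(p + 15)] <- strsplit(instance, "")[[1]]
    seq <- paste(body, collapse = "")
    got <- scan_motif(seq, motif)$start
    expect_equal(got, naive_motif_scan(seq, motif))
    expect_true(all(pos %in% got))
  }

  # overlapping occurrences are all reported
  ov <- scan_motif("AAAAA", "AAx")
  expect_equal(ov$start, 1:3)

  expect_error(scan_motif("MKV", "SPZ"), "invalid")
  expect_error(scan_motif("MK9V", "SPY"), "invalid")
})

test_that("molecular weight is the residue-mass sum plus one water and is additive", {
  expect_equal(protein_params("GG")$mw, (2 * 57.0519 + 18.0153) / 1000,
               tolerance = 1e-10)
  set.seed(5)
  for (rep in 1:10) {
    s1 <- random_protein(sample(5:40, 1))
    s2 <- random_protein(sample(5:40, 1))
    expect_equal(protein_params(paste0(s1, s2))$mw,
                 protein_params(s1)$mw + protein_params(s2)$mw -
                   18.0153 / 1000,
                 tolerance = 1e-9)
  }
  expect_error(protein_params(""), "non-empty")
})

test_that("isoelectric point is a zero of the net charge and permutation-invariant", {
  set.seed(7)
  for (rep in 1:10) {
    s <- random_protein(60)
    pp <- protein_params(s)
    # independent charge recomputation at the reported pI
    chars <- strsplit(s, "")[[1]]
    pka <- bjellqvist_pka()
    pick <- function(tab, r) if (r %in% names(tab)) tab[[r]] else tab[["default"]]
    pos <- c(pick(pka$nterm, chars[1]),
             rep(pka$sidechain[["K"]], sum(chars == "K")),
             rep(pka$sidechain[["R"]], sum(chars == "R")),
             rep(pka$sidechain[["H"]], sum(chars == "H")))
    neg <- c(pick(pka$cterm, chars[length(chars)]),
             rep(pka$sidechain[["D"]], sum(chars == "D")),
             rep(pka$sidechain[["E"]], sum(chars == "E")),
             rep(pka$sidechain[["C"]], sum(chars == "C")),
             rep(pka$sidechain[["Y"]], sum(chars == "Y")))
    q <- sum(1 / (1 + 10^(pp$pi - pos))) - sum(1 / (1 + 10^(neg - pp$pi)))
    expect_lt(abs(q), 1e-4)
    # permuting interior residues (termini fixed) leaves pI unchanged
    interior <- chars[-c(1, length(chars))]
    perm <- paste(c(chars[1], sample(interior), chars[length(chars)]),
                  collapse = "")
    expect_equal(protein_params(perm)$pi, pp$pi, tolerance = 1e-6)
  }
})

test_that("transmembrane count follows the hydropathy-window rule", {
  # 25 Leu flanked by 20 Asp each side: one strongly hydrophobic stretch
  tm1 <- protein_params(paste0(strrep("D", 20), strrep("L", 25),
                               strrep("D", 20)))$tm_count
  expect_gte(tm1, 1L)
  expect_equal(protein_params(strrep("D", 60))$tm_count, 0L)
  # shorter than the window: always 0
  expect_equal(protein_params(strrep("L", 18))$tm_count, 0L)
  # two well-separated hydrophobic stretches count twice
  two <- paste0(strrep("D", 25), strrep("L", 25), strrep("D", 40),
                strrep("L", 25), strrep("D", 25))
  expect_equal(protein_params(two)$tm_count, 2L)
})

test_that("family filter keeps exactly the motif-bearing candidates inside the window", {
  set.seed(9)
  motif <- "SPYxEVRxxVxxxDDP"
  instance <- "SPYAEVRGGVQQQDDP"
  cands <- character(10)
  planted <- sort(sample(1:10, 4))
  for (i in 1:10) {
    s <- random_protein(300)
    if (i %in% planted)
      s <- paste0(substr(s, 1, 100), instance, substr(s, 117, 300))
    cands[i] <- s
  }
  names(cands) <- sprintf("g%02d", 1:10)
  fam <- filter_family(cands, motif)
  expect_equal(fam$id, names(cands)[planted])
  # subset of input, idempotent on its own output
  expect_true(all(fam$id %in% names(cands)))
  again <- filter_family(stats::setNames(cands[fam$id], fam$id), motif)
  expect_equal(again$id, fam$id)

  # a 12-16 TM window excludes a soluble (low-TM) protein
  soluble <- paste0(substr(random_protein(280), 1, 100), instance)
  names(soluble) <- "sol1"
  expect_equal(nrow(filter_family(soluble, motif,
                                  params_window = list(tm_count = c(12, 16)))),
               0L)
})
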