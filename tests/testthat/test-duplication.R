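toy_map <- function() {
  data.frame(id = sprintf("c1_g%02d", 1:40), chrom = "chr1",
             start = (0:39) * 20000 + 1, end = (0:39) * 20000 + 4000,
             strand = "+", rank = 1:40, stringsAsFactors = FALSE)
}

test_that("tandem rule counts intervening gene models, symmetrically", {
  map <- toy_map()
  # ranks 10 and 24: 13 intervening -> tandem
  expect_true(detect_tandem(map, "c1_g10", "c1_g24")$tandem)
  expect_equal(detect_tandem(map, "c1_g10", "c1_g24")$intervening, 13L)
  # ranks 10 and 32: 21 intervening -> not tandem
  expect_false(detect_tandem(map, "c1_g10", "c1_g32")$tandem)
  # symmetry
  expect_equal(detect_tandem(map, "c1_g24", "c1_g10"),
               detect_tandem(map, "c1_g10", "c1_g24"))
  # monotone in the threshold
  expect_true(detect_tandem(map, "c1_g10", "c1_g32",
                            max_intervening = 21L)$tandem)
  # different chromosomes never tandem
  map2 <- rbind(map, data.frame(id = "c2_g01", chrom = "chr2", start = 1,
                                end = 4000, strand = "+", rank = 1L))
  td <- detect_tandem(map2, "c1_g10", "c2_g01")
  expect_false(td$tandem)
  expect_true(is.na(td$intervening))
  expect_error(detect_tandem(map, "c1_g10", "nope"), "not in the gene map")
})

make_anchors <- function(starts_a, starts_b, len = 4000) {
  data.frame(id_a = sprintf("a%02d", seq_along(starts_a)), chrom_a = "chr1",
             start_a = starts_a, end_a = starts_a + len - 1,
             id_b = sprintf("b%02d", seq_along(starts_b)), chrom_b = "chr2",
             start_b = starts_b, end_b = starts_b + len - 1,
             stringsAsFactors = FALSE)
}

test_that("anchor chaining respects the gap cap and the anchor minimum", {
  # 6 anchors at 50 kb spacing: one block of 6
  pos <- (0:5) * 50000 + 1
  b1 <- find_collinear_blocks(make_anchors(pos, pos))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_anchors, 6L)
  an <- attr(b1, "anchors")
  expect_equal(nrow(an), 6L)
  # spans contain all anchors
  expect_true(all(an$start_a >= b1$start_a & an$end_a <= b1$end_a))

  # a 150 kb gap splits the chain; 3-anchor fragments die at min_anchors 5
  pos2 <- c(0, 50000, 100000, 250000, 300000, 350000) + 1
  b2 <- find_collinear_blocks(make_anchors(pos2, pos2))
  expect_equal(nrow(b2), 0L)
  b3 <- find_collinear_blocks(make_anchors(pos2, pos2), min_anchors = 3L)
  expect_equal(nrow(b3), 2L)

  # order inconsistency on the second chromosome breaks the chain
  scrambled <- make_anchors(pos, pos[c(1, 2, 6, 3, 4, 5)])
  b4 <- find_collinear_blocks(scrambled, min_anchors = 5L)
  expect_equal(nrow(b4), 0L)
  # a fully inverted block is still collinear
  b5 <- find_collinear_blocks(make_anchors(pos, rev(pos)))
  expect_equal(nrow(b5), 1L)

  expect_equal(nrow(find_collinear_blocks(NULL)), 0L)
})

test_that("classification applies tandem precedence and block evidence", {
  sim <- simulate_gene_map(
    c(chrA = 60, chrB = 60),
    tandem = data.frame(chrom = "chrA", rank_a = c(5, 30),
                        intervening = c(5, 20)),
    segments = data.frame(chrom_a = "chrA", chrom_b = "chrB",
                          start_a = 40, start_b = 10, n_anchors = 6))
  blocks <- find_collinear_blocks(sim$anchors)
  pairs <- rbind(sim$truth$tandem_pairs[, c("id_a", "id_b")],
                 sim$truth$segmental_pairs[, c("id_a", "id_b")],
                 data.frame(id_a = "chrA_g001", id_b = "chrB_g060"))
  ev <- classify_duplication(pairs, sim$map, blocks)
  n_t <- nrow(sim$truth$tandem_pairs)
  n_s <- nrow(sim$truth$segmental_pairs)
  expect_equal(ev$mechanism,
               c(rep("tandem", n_t), rep("segmental", n_s), "unclassified"))

  # a pair satisfying both rules is tandem (stated precedence): two anchors
  # of the same block on one chromosome, close together
  close_anchors <- make_anchors((0:5) * 30000 + 1, (0:5) * 30000 + 1)
  bl <- find_collinear_blocks(close_anchors)
  map <- rbind(
    data.frame(id = close_anchors$id_a, chrom = "chr1",
               start = close_anchors$start_a, end = close_anchors$end_a,
               strand = "+", rank = 1:6),
    data.frame(id = close_anchors$id_b, chrom = "chr2",
               start = close_anchors$start_b, end = close_anchors$end_b,
               strand = "+", rank = 1:6))
  both <- classify_duplication(data.frame(id_a = "a01", id_b = "a03"),
                               map, bl)
  expect_equal(both$mechanism, "tandem")
})

test_that("the reconstructed family map reproduces the published mechanisms", {
  t2 <- opt_table2()
  ev <- classify_duplication(t2[, c("id_a", "id_b")], opt_gene_map(),
                             opt_blocks())
  expect_equal(ev$mechanism, t2$type)
  expect_equal(sum(ev$mechanism == "tandem"), 4L)
  expect_equal(sum(ev$mechanism == "segmental"), 3L)
})
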