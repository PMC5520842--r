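test_that("Poisson distance matches its closed form and a column-count oracle", {
  aln <- c(a = "MKVLW", b = "MKVLW")
  expect_equal(poisson_distance(aln)["a", "b"], 0)

  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("R", 10), strrep("A", 90))
  expect_equal(poisson_distance(c(x = s1, y = s2))["x", "y"], -log(0.9),
               tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:20) {
    a <- strsplit(random_protein(80), "")[[1]]
    b <- strsplit(random_protein(80), "")[[1]]
    keep <- sample(80, 60)           # make them partly similar
    b[keep] <- a[keep]
    p <- sum(a != b) / 80
    d <- poisson_distance(c(u = paste(a, collapse = ""),
                            v = paste(b, collapse = "")))["u", "v"]
    expect_equal(d, -log(1 - p), tolerance = 1e-12)
    expect_gte(d, p)                 # correction only stretches distances
  }

  # saturated pair is an error naming the pair
  expect_error(poisson_distance(c(p1 = "AAAA", p2 = "RRRR")), "p1/p2")
})

test_that("gap policies drop the right columns", {
  aln <- c(a = "MK-VW", b = "MKAVW", c = "MKAV-")
  # complete deletion removes columns 3 and 5
  d_complete <- poisson_distance(aln, "complete")
  expect_equal(d_complete["a", "b"], 0)
  # pairwise keeps column 3 for b/c
  d_pair <- poisson_distance(aln, "pairwise")
  expect_equal(d_pair["a", "b"], 0)
  expect_equal(d_pair["b", "c"], 0)
})

test_that("NJ reproduces the three-point closed form and additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  got <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(got[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  set.seed(31)
  for (rep in 1:25) {
    taxa <- paste0("t", 1:5)
    edges <- random_unrooted_tree(taxa)
    dm <- edge_tree_distances(edges, taxa)
    tr <- nj_tree(dm)
    expect_setequal(tree_splits(tr), edge_tree_splits(edges, taxa))
    # path lengths reproduce the input distances
    path <- ape::cophenetic.phylo(tr)[taxa, taxa]
    expect_lt(max(abs(path - dm)), 1e-9)
  }
})

test_that("NJ is invariant under taxon input order and rejects bad input", {
  set.seed(41)
  taxa <- paste0("t", 1:7)
  edges <- random_unrooted_tree(taxa)
  dm <- edge_tree_distances(edges, taxa)
  perm <- sample(taxa)
  t1 <- nj_tree(dm)
  t2 <- nj_tree(dm[perm, perm])
  expect_setequal(tree_splits(t1), tree_splits(t2))
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)

  bad <- dm; bad[1, 2] <- bad[1, 2] + 1
  expect_error(nj_tree(bad), "symmetric")
  neg <- dm; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(nj_tree(neg), "nonnegative")
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("equal pairwise distances collapse all internal branches", {
  n <- 5
  d <- matrix(2, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-9))
})

test_that("bootstrap support is deterministic under seed and bounded", {
  aln <- two_clade_alignment(paste0("a", 1:3), paste0("b", 1:3))
  r1 <- bootstrap_support(aln, replicates = 100, seed = 42)
  r2 <- bootstrap_support(aln, replicates = 100, seed = 42)
  expect_equal(r1$support, r2$support)
  expect_true(all(r1$support$support >= 0 & r1$support$support <= 100))

  # every informative column supports the two-clade split: support 100
  key <- paste(sort(paste0("a", 1:3)), collapse = "|")
  alt <- paste(sort(paste0("b", 1:3)), collapse = "|")
  main <- r1$support$support[r1$support$split %in% c(key, alt)]
  expect_true(length(main) >= 1 && all(main == 100))

  # one replicate forces support into {0, 100}
  r3 <- bootstrap_support(aln, replicates = 1, seed = 7)
  expect_true(all(r3$support$support %in% c(0, 100)))

  expect_warning(bootstrap_support(aln[1:3], replicates = 2, seed = 1),
                 "fewer than 4")
})

test_that("clade labels follow the smallest reference-containing clade", {
  # known topology: ((a1,a2),(b1,b2)) with outgroup og
  nwk <- "((a1:1,a2:1):1,(b1:1,b2:1):1,og:3);"
  tr <- ape::read.tree(text = nwk)
  refs <- c(a1 = "PT", b1 = "YSL")
  lab <- assign_clades(tr, refs, "og")
  expect_equal(lab$group[lab$taxon == "a2"], "PT")
  expect_equal(lab$group[lab$taxon == "b2"], "YSL")
  expect_equal(lab$group[lab$taxon == "a1"], "PT")

  # taxon sister to the outgroup is ambiguous
  nwk2 <- "((a1:1,a2:1):1,(b1:1,x:1):1,og:3);"
  tr2 <- ape::read.tree(text = nwk2)
  lab2 <- assign_clades(tr2, c(a1 = "PT", b1 = "YSL"), "og")
  expect_equal(lab2$group[lab2$taxon == "x"], "YSL")
  nwk3 <- "(((a1:1,a2:1):1,(b1:1,b2:1):1):1,x:1,og:3);"
  lab3 <- assign_clades(ape::read.tree(text = nwk3),
                        c(a1 = "PT", b1 = "YSL"), "og")
  expect_equal(lab3$group[lab3$taxon == "x"], "ambiguous")

  # references all one group: everything gets that group
  lab4 <- assign_clades(tr, c(a1 = "PT"), "og")
  expect_true(all(lab4$group == "PT"))

  expect_error(assign_clades(tr, refs, "nope"), "not in tree")
})
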