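test_that("nei_da closed forms", {
  f1 <- list(c("120" = 1)); f2 <- list(c("120" = 1))
  expect_equal(nei_da(f1, f2), 0)
  expect_equal(nei_da(list(c("120" = 1)), list(c("124" = 1))), 1)
  # two loci: one shared allele, one disjoint -> 1 - (1 + 0)/2 = 0.5
  x <- list(c("120" = 1), c("100" = 1))
  y <- list(c("120" = 1), c("104" = 1))
  expect_equal(nei_da(x, y), 0.5)
  expect_error(nei_da(list(), list()), "shared loci")
  # symmetry + bounded
  set.seed(104)
  for (i in 1:20) {
    L <- sample(1:5, 1)
    mk <- function() lapply(seq_len(L), function(l) {
      k <- sample(2:5, 1)
      p <- stats::rgamma(k, 1); p <- p / sum(p)
      stats::setNames(p, as.character(100 + 2 * seq_len(k)))
    })
    a <- mk(); b <- mk()
    expect_equal(nei_da(a, b), nei_da(b, a))
    expect_gte(nei_da(a, b), 0)
    expect_lte(nei_da(a, b), 1)
    expect_equal(nei_da(a, a), 0, tolerance = 1e-12)
  }
})

test_that("distance_matrix handles duplicates and missing overlap", {
  calls <- rbind(M1 = c("120", "120", "124"),
                 M2 = c("100", "100", "100"))
  gm <- genotype_matrix(calls, accessions = c("a", "b", "c"))
  d <- distance_matrix(gm)
  expect_equal(d["a", "b"], 0)
  # a vs c: locus 1 disjoint (0), locus 2 identical (1) -> 0.5
  expect_equal(d["a", "c"], 0.5)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  calls2 <- rbind(M1 = c("120", NA), M2 = c(NA, "100"))
  gm2 <- genotype_matrix(calls2, accessions = c("a", "b"))
  expect_error(distance_matrix(gm2), "no shared loci")
})

test_that("neighbor_joining closed forms and conventions", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- neighbor_joining(d3)
  expect_equal(write_newick(t3), "(A:1.000000,B:1.000000,C:3.000000);")

  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(write_newick(neighbor_joining(d2)),
               "(A:0.200000,B:0.200000);")

  bad <- d3; bad[1, 2] <- 9
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- d3; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "non-negative")
})

test_that("NJ recovers additive matrices exactly (n = 4..8)", {
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:10) {
      gt <- random_tree(n, seed = 1000 * n + rep)
      dm <- tree_distances(gt)
      dm <- dm[sort(rownames(dm)), sort(rownames(dm))]
      nj <- neighbor_joining(dm)
      expect_equal(sort(tree_leaves(nj)), sort(rownames(dm)))
      got <- tree_distances(nj)
      expect_equal(got[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
    }
  }
})

test_that("NJ topology matches the ape implementation on random matrices", {
  skip_if_not_installed("ape")
  skip_if_not_installed("phangorn")
  set.seed(105)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
    mine <- ape::read.tree(text = write_newick(neighbor_joining(m)))
    theirs <- ape::nj(stats::as.dist(m))
    expect_equal(phangorn::RF.dist(ape::unroot(mine),
                                   ape::unroot(theirs)), 0)
  }
})

test_that("negative branch lengths are clamped to zero", {
  # the classic NJ negative-branch example
  m <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0),
              4, 4, dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(m)
  walk <- function(node) {
    for (ch in node$children) {
      expect_gte(ch$length, 0)
      walk(ch$node)
    }
  }
  walk(tr)
})

test_that("newick writing round-trips through the reader", {
  for (rep in 1:100) {
    n <- 3 + (rep %% 8)
    gt <- random_tree(n, seed = 5000 + rep)
    s <- write_newick(gt)
    expect_true(endsWith(s, ";"))
    back <- read_newick(s)
    expect_equal(sort(tree_leaves(back)), sort(tree_leaves(gt)))
    d1 <- tree_distances(gt); d2 <- tree_distances(back)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-5)
  }
  # labels with specials get quoted and survive
  tr <- list(label = NULL, children = list(
    list(node = list(label = "acc (wild)", children = list()),
         length = 0.1),
    list(node = list(label = "it's", children = list()), length = 0.2)))
  back <- read_newick(write_newick(tr))
  expect_setequal(tree_leaves(back), c("acc (wild)", "it's"))
})

test_that("monophyly detection works on known trees", {
  s <- "((a:1,b:1):1,(c:1,d:1):1,e:1);"
  tr <- read_newick(s)
  expect_true(is_group_monophyletic(tr, c("a", "b")))
  expect_true(is_group_monophyletic(tr, c("c", "d")))
  expect_false(is_group_monophyletic(tr, c("a", "c")))
  # complement of a clade is monophyletic in the unrooted sense
  expect_true(is_group_monophyletic(tr, c("c", "d", "e")))
})

test_that("simulated divergent groups come out monophyletic", {
  # 733 markers: the size of a full developed-marker panel
  sim <- simulate_genotype_matrix(733, divergence = 0.8, seed = 106)
  dm <- distance_matrix(sim$gm)
  tr <- neighbor_joining(dm)
  for (g in unique(sim$gm$groups)) {
    expect_true(is_group_monophyletic(
      tr, sim$gm$accessions[sim$gm$groups == g]))
  }
  # negative control: divergence 0 leaves no reliable group signal
  sim0 <- simulate_genotype_matrix(733, divergence = 0, seed = 107)
  tr0 <- neighbor_joining(distance_matrix(sim0$gm))
  mono0 <- vapply(unique(sim0$gm$groups), function(g) {
    is_group_monophyletic(tr0, sim0$gm$accessions[sim0$gm$groups == g])
  }, logical(1))
  expect_false(all(mono0))
})
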