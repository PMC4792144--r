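test_that("three-taxon star branch lengths follow the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), class = "wrky_format_error")
})

test_that("additive four-taxon matrices recover the unique fitting topology", {
  set.seed(13)
  for (k in 1:10) {
    tr <- ape::rtree(4, br = function(n) runif(n, 0.5, 2))
    d <- ape::cophenetic.phylo(tr)
    nj_tree <- neighbor_joining(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj_tree), 0,
                 ignore_attr = TRUE)
    # exhaustive check: among all 3 unrooted topologies exactly the NJ one
    # fits the matrix additively
    all_topo <- phangorn::allTrees(4, rooted = FALSE,
                                   tip.label = rownames(d))
    rss <- vapply(all_topo, oracle_topology_rss, 0, d = d)
    expect_equal(sum(rss < 1e-10), 1)
    best <- all_topo[[which.min(rss)]]
    expect_equal(ape::dist.topo(best, nj_tree), 0, ignore_attr = TRUE)
  }
})

test_that("taxon order permutation yields an isomorphic tree", {
  set.seed(17)
  tr <- ape::rtree(7, br = function(n) runif(n, 0.5, 2))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(nrow(d))
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
})

test_that("branch lengths are clamped at zero", {
  set.seed(19)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 1)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- neighbor_joining(d)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(23)
  for (k in 1:5) {
    n <- sample(5:9, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.2, 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    expect_equal(ape::dist.topo(neighbor_joining(d), ape::nj(d)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are reproducible and detect real clades", {
  set.seed(3)
  left <- vapply(1:4, function(i) rand_peptide(40, c("A", "K", "R")), "")
  right <- vapply(1:3, function(i) rand_peptide(40, c("D", "E", "F")), "")
  msa <- setNames(c(left, right), c(paste0("L", 1:4), paste0("R", 1:3)))
  bs1 <- bootstrap_support(msa, 200, seed = 4)
  bs2 <- bootstrap_support(msa, 200, seed = 4)
  expect_identical(unclass(bs1)[order(names(bs1))],
                   unclass(bs2)[order(names(bs2))])
  clade <- paste(sort(paste0("R", 1:3)), collapse = "|")
  side <- names(bs1)[vapply(names(bs1), function(s)
    setequal(strsplit(s, "|", fixed = TRUE)[[1]], paste0("R", 1:3)) ||
      setequal(strsplit(s, "|", fixed = TRUE)[[1]], paste0("L", 1:4)), TRUE)]
  expect_true(length(side) >= 1)
  expect_gte(max(bs1[side]), 0.95)
})

test_that("degenerate alignments give zero supports with a warning", {
  msa <- setNames(rep("AAAAAAAA", 4), paste0("t", 1:4))
  expect_warning(bs <- bootstrap_support(msa, 10, seed = 1), "degenerate")
  expect_true(all(bs == 0))
})
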