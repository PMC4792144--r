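test_that("local alignment scores have the expected closed forms", {
  b62 <- oracle_blosum62
  s <- "WRKYGQKMV"
  chars <- strsplit(s, "")[[1]]
  expect_equal(local_align_score(s, s), sum(b62[cbind(chars, chars)]))
  expect_equal(local_align_score("GGGG", "PPPP"), 0)  # nothing aligns
  set.seed(89)
  for (k in 1:30) {
    a <- rand_peptide(sample(3:12, 1)); b <- rand_peptide(sample(3:12, 1))
    expect_equal(local_align_score(a, b), oracle_align_score(a, b, "local"))
    expect_equal(local_align_score(a, b), local_align_score(b, a))
  }
})

test_that("similarity graph weights are self-normalised into (0, 1]", {
  recs <- data.frame(id = c("a", "b"), species = c("A", "B"),
                     sequence = rep("MKVWACDEFGHIK", 2),
                     stringsAsFactors = FALSE)
  g <- build_similarity_graph(recs)
  expect_equal(g$edges$weight, 1.0)    # duplicate sequences
  expect_equal(nrow(build_similarity_graph(recs, cutoff = 1.0)$edges), 1)

  set.seed(97)
  recs2 <- data.frame(id = paste0("p", 1:6),
                      species = rep(c("A", "B"), 3),
                      sequence = vapply(1:6, function(i) rand_peptide(40), ""),
                      stringsAsFactors = FALSE)
  g2 <- build_similarity_graph(recs2, cutoff = 0)
  expect_true(all(g2$edges$weight > 0 & g2$edges$weight <= 1))
  expect_false(any(g2$edges$from == g2$edges$to))   # no self edges
})

test_that("Markov clustering separates components and dense cliques", {
  nodes <- data.frame(id = letters[1:6], species = "X",
                      stringsAsFactors = FALSE)
  tri <- function(ids) data.frame(from = ids[c(1, 1, 2)], to = ids[c(2, 3, 3)],
                                  weight = 1, stringsAsFactors = FALSE)
  # two disjoint triangles
  g <- list(nodes = nodes, edges = rbind(tri(letters[1:3]), tri(letters[4:6])))
  cl <- mcl(g)
  expect_length(cl, 2)
  expect_setequal(unlist(cl), letters[1:6])

  # two dense cliques joined by one weak edge split at inflation 2
  bridge <- data.frame(from = "c", to = "d", weight = 0.1,
                       stringsAsFactors = FALSE)
  g2 <- list(nodes = nodes, edges = rbind(g$edges, bridge))
  cl2 <- mcl(g2, inflation = 2.0)
  expect_length(cl2, 2)
  expect_setequal(cl2[[which(vapply(cl2, function(x) "a" %in% x, TRUE))]],
                  c("a", "b", "c"))

  expect_length(mcl(list(nodes = nodes[0, ], edges = g$edges[0, ])), 0)

  # clusters always partition the node set
  expect_equal(sort(unlist(cl2)), sort(nodes$id))
})

test_that("Markov clustering is invariant to node relabeling", {
  set.seed(101)
  recs <- simulate_family_evolution(n_genes = 4, seed = 7)$records
  g <- build_similarity_graph(recs)
  cl <- mcl(g)
  # relabel by permuting ids
  perm <- sample(nrow(recs))
  map <- setNames(paste0("z", seq_len(nrow(recs))), recs$id)
  g2 <- list(nodes = data.frame(id = unname(map[recs$id[perm]]),
                                species = recs$species[perm],
                                stringsAsFactors = FALSE),
             edges = data.frame(from = unname(map[g$edges$from]),
                                to = unname(map[g$edges$to]),
                                weight = g$edges$weight,
                                stringsAsFactors = FALSE))
  cl2 <- mcl(g2)
  canon <- function(cls) sort(vapply(cls, function(x) paste(sort(x), collapse = ","), ""))
  expect_equal(canon(lapply(cl, function(x) unname(map[x]))), canon(cl2))
})

test_that("reciprocal best hits follow the mutual-argmax definition", {
  sm <- c(a1 = "A", b1 = "B")
  s <- matrix(c(10, 5, 5, 10), 2, 2, dimnames = list(names(sm), names(sm)))
  expect_equal(nrow(reciprocal_best_hits(s, sm, "A", "B")), 1)

  # asymmetry: a1's best is b1, but b1's best is a2
  sm2 <- c(a1 = "A", a2 = "A", b1 = "B")
  s2 <- matrix(0, 3, 3, dimnames = list(names(sm2), names(sm2)))
  s2["a1", "b1"] <- s2["b1", "a1"] <- 5
  s2["a2", "b1"] <- s2["b1", "a2"] <- 9
  r <- reciprocal_best_hits(s2, sm2, "A", "B")
  expect_equal(nrow(r), 1)
  expect_equal(r$a, "a2")

  set.seed(103)
  for (k in 1:20) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    ids <- c(paste0("a", 1:na), paste0("b", 1:nb))
    smk <- setNames(rep(c("A", "B"), c(na, nb)), ids)
    s <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    s[upper.tri(s)] <- sample(0:10, sum(upper.tri(s)), replace = TRUE)
    s <- s + t(s)
    r <- reciprocal_best_hits(s, smk, "A", "B")
    got <- if (nrow(r)) sort(paste(pmin(r$a, r$b), pmax(r$a, r$b), sep = "\r"))
    else character(0)
    expect_equal(got, sort(oracle_rbh(s, smk, "A", "B")))
  }
})

test_that("pair typing is exhaustive, exclusive and correctly tallied", {
  sm <- c(a1 = "A", a2 = "A", b1 = "B")
  rbh <- data.frame(a = "a1", b = "b1", stringsAsFactors = FALSE)
  tp <- call_pair_types(list(c("a1", "a2", "b1")), sm, rbh)
  expect_equal(nrow(tp), 3)
  expect_equal(tp$type[tp$a == "a1" & tp$b == "a2"], "paralog")
  expect_equal(tp$type[tp$a == "a1" & tp$b == "b1"], "ortholog")
  expect_equal(tp$type[tp$a == "a2" & tp$b == "b1"], "coortholog")

  pt <- pair_count_table(tp, sm, c("A", "B"))
  expect_equal(unname(pt$paralog), c(1, 0))
  expect_equal(pt$ortholog["A", "B"], 1)
  expect_equal(pt$coortholog["B", "A"], 1)
  totals <- aggregate_pair_totals(pt)
  expect_equal(sum(totals), nrow(tp))   # conservation

  empty <- pair_count_table(tp[0, ], sm, c("A", "B"))
  expect_equal(sum(aggregate_pair_totals(empty)), 0)
})

test_that("simulated family histories yield the constructed pair types", {
  # zero duplication, full retention on 2 species: n ortholog pairs only
  fe <- simulate_family_evolution("(A:1,B:1);", n_genes = 5, birth_rate = 0,
                                  loss_rate = 0, sub_prob = 0.02, seed = 11)
  expect_equal(nrow(fe$records), 10)
  expect_equal(sort(unique(fe$truth_pairs$type)), "ortholog")
  expect_equal(nrow(fe$truth_pairs), 5)

  # duplications create paralog and coortholog pairs per definition
  fe2 <- simulate_family_evolution("(A:1,B:1);", n_genes = 3, birth_rate = 1.5,
                                   loss_rate = 0, sub_prob = 0.02, seed = 13)
  expect_true(all(c("paralog", "coortholog") %in% fe2$truth_pairs$type))
  # same-species pairs are always paralogs, cross-species never
  sp <- fe2$species_map
  same <- sp[fe2$truth_pairs$a] == sp[fe2$truth_pairs$b]
  expect_true(all(fe2$truth_pairs$type[same] == "paralog"))
  expect_true(all(fe2$truth_pairs$type[!same] != "paralog"))

  expect_identical(simulate_family_evolution(seed = 17),
                   simulate_family_evolution(seed = 17))
})

test_that("gene density per megabase follows the closed form", {
  expect_equal(wrky_density(10, 100), 0.1)
  expect_equal(wrky_density(95, 95 / 0.1979), 0.1979)
  expect_equal(wrky_density(20, 50), 2 * wrky_density(10, 50))
  expect_error(wrky_density(10, 0), class = "wrky_config_error")
})
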