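test_that("RPKM follows its closed form and scale invariances", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(10, 1000, 1e6), rpkm(20, 1000, 2e6))  # joint scaling
  expect_equal(rpkm(10, 2000, 1e6), rpkm(10, 1000, 1e6) / 2)  # length inverse

  set.seed(107)
  counts <- matrix(rpois(40, 50), 8, 5,
                   dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
  lens <- setNames(sample(200:2000, 8), rownames(counts))
  tot <- setNames(runif(5, 1e5, 1e6), colnames(counts))
  em <- expression_matrix(counts, lens, tot)
  rp <- rpkm_matrix(em)
  for (i in 1:8) for (j in 1:5)
    expect_equal(rp$rpkm[i, j],
                 unname(rpkm(counts[i, j], lens[i], tot[j])))
  expect_equal(rp$log2, log2(rp$rpkm + 1))

  f <- withr::local_tempfile(fileext = ".tsv")
  rpkm_matrix(em, heatmap_path = f)
  expect_equal(read_tsv_matrix(f), rp$log2, tolerance = 1e-6)
})

test_that("2^-ddCt fold changes match hand-computed cases", {
  ct <- data.frame(gene = "g1", condition = c("treated", "control"),
                   ct_target = c(20, 24), ct_reference = c(18, 18))
  res <- ddct_fold_change(ct)
  expect_equal(res$fold[res$condition == "treated"], 16)   # ddCt = -4
  expect_equal(res$fold[res$condition == "control"], 1)

  same <- data.frame(gene = "g1", condition = c("x", "control"),
                     ct_target = c(22, 22), ct_reference = c(19, 19))
  expect_equal(ddct_fold_change(same)$fold, c(1, 1))  # ddCt = 0

  bad <- data.frame(gene = "g2", condition = "treated",
                    ct_target = 20, ct_reference = 18)
  expect_error(ddct_fold_change(bad), "g2", class = "wrky_format_error")
})

test_that("planted qPCR folds are recovered exactly at zero noise", {
  folds <- data.frame(gene = rep(paste0("g", 1:4), each = 2),
                      condition = rep(c("cold", "salt"), 4),
                      fold = c(16, 0.5, 1, 80, 2, 0.125, 12, 14))
  g <- gen_ct_table(folds, noise_sd = 0, seed = 109)
  res <- ddct_fold_change(g$ct_table)
  m <- merge(res, g$truth, by = c("gene", "condition"))
  expect_equal(m$fold.x, m$fold.y)
})

test_that("fold-change bias stays below 5% at Ct noise sd 0.1", {
  n <- 1000
  folds <- data.frame(gene = paste0("g", seq_len(n)), condition = "treat",
                      fold = 16)
  g <- gen_ct_table(folds, noise_sd = 0.1, seed = 113)
  res <- ddct_fold_change(g$ct_table)
  rec <- res$fold[res$condition == "treat"]
  expect_lt(abs(mean(rec) / 16 - 1), 0.05)
})

test_that("Pearson correlation handles exact and degenerate cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pcc(x, 2 * x + 1), 1)
  expect_equal(pcc(x, -x), -1)
  expect_true(is.na(pcc(rep(2, 5), x)))
  expect_error(pcc(x, x[1:3]), class = "wrky_config_error")
  expect_error(pcc(1:2, 1:2), class = "wrky_config_error")
})

test_that("co-expression networks annotate candidates and conserve counts", {
  ge <- gen_expression(n_genes = 40, n_samples = 40,
                       modules = list(list(genes = 1:8, loading = 0.9),
                                      list(genes = 9:16, loading = -0.9,
                                           factor = 1)),
                       seed = 127)
  rp <- rpkm_matrix(ge$em)$rpkm
  intra <- data.frame(a = rownames(rp)[1:7], b = rownames(rp)[2:8],
                      stringsAsFactors = FALSE)
  cross <- data.frame(a = rownames(rp)[1:4], b = rownames(rp)[9:12],
                      stringsAsFactors = FALSE)
  missing <- data.frame(a = "nonexistent", b = rownames(rp)[1],
                        stringsAsFactors = FALSE)
  cand <- rbind(intra, cross, missing)
  expect_warning(nw <- coexpression_network(rp, cand), "absent")
  expect_equal(nw$sign[1:7], rep("positive", 7))     # planted module
  expect_equal(nw$sign[8:11], rep("negative", 4))    # opposite loadings
  expect_equal(nw$sign[12], "na")
  expect_equal(nw$na_reason[12], "missing")
  sc <- attr(nw, "sign_counts")
  expect_equal(sum(sc), nrow(cand))                  # conservation
  expect_equal(nrow(coexpression_network(rp, cand[0, ])), 0)
})

test_that("planted module structure is enriched in positive signs", {
  ge <- gen_expression(n_genes = 60, n_samples = 30,
                       modules = list(list(genes = 1:10, loading = 0.9)),
                       seed = 131)
  rp <- rpkm_matrix(ge$em)$rpkm
  mod_ids <- rownames(rp)[1:10]
  bg_ids <- rownames(rp)[31:60]
  intra <- t(combn(mod_ids, 2))
  set.seed(7)
  bg_all <- t(combn(bg_ids, 2))
  bg <- bg_all[sample(nrow(bg_all), 45), ]
  r_intra <- apply(intra, 1, function(p) pcc(rp[p[1], ], rp[p[2], ]))
  r_bg <- apply(bg, 1, function(p) pcc(rp[p[1], ], rp[p[2], ]))
  tab <- matrix(c(sum(r_intra > 0), sum(r_intra <= 0),
                  sum(r_bg > 0), sum(r_bg <= 0)), 2, 2)
  expect_lt(fisher.test(tab)$p.value, 0.01)
})

test_that("expression generator plants correlation where it says it does", {
  ge <- gen_expression(n_genes = 30, n_samples = 50,
                       modules = list(list(genes = 1:10, loading = 0.9)),
                       seed = 137)
  rp <- rpkm_matrix(ge$em)$rpkm
  intra <- combn(1:10, 2)
  inter <- rbind(sample(1:10, 30, TRUE), sample(15:30, 30, TRUE))
  mean_r <- function(prs) mean(apply(prs, 2, function(p)
    pcc(rp[p[1], ], rp[p[2], ])))
  expect_gt(mean_r(intra), mean_r(inter))

  ge0 <- gen_expression(n_genes = 30, n_samples = 50,
                        modules = list(list(genes = 1:10, loading = 0)),
                        seed = 139)
  rp0 <- rpkm_matrix(ge0$em)$rpkm
  r0 <- apply(intra, 2, function(p) pcc(rp0[p[1], ], rp0[p[2], ]))
  expect_lt(mean(abs(r0)), 0.2)

  expect_identical(gen_expression(seed = 141), gen_expression(seed = 141))
})
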