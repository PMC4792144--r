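mk_domain <- function(type) list(finger = list(finger_type = type))

test_that("rule classification follows domain count and finger type", {
  expect_equal(classify_by_rule(list())$group, "unclassified")
  expect_equal(classify_by_rule(list(mk_domain("C2H2")))$group, "II")
  expect_equal(classify_by_rule(list(mk_domain("C2HC")))$group, "III")
  two <- classify_by_rule(list(mk_domain("C2H2"), mk_domain("C2H2")))
  expect_equal(two$group, "I")
  expect_false(two$conflict)
  odd <- classify_by_rule(list(mk_domain("C2H2"), mk_domain("C2HC")))
  expect_equal(odd$group, "I")
  expect_true(odd$conflict)
})

test_that("pairwise identity is exact on closed-form cases and symmetric", {
  expect_equal(pairwise_identity("WRKYGQK", "WRKYGQK"), 1.0)
  expect_equal(pairwise_identity("AAAA", "DDDD"), 0.0)
  set.seed(5)
  for (k in 1:20) {
    a <- rand_peptide(sample(5:15, 1)); b <- rand_peptide(sample(5:15, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
  expect_error(pairwise_identity("", "AAA"), class = "wrky_format_error")
})

test_that("center-star MSA merges on anchor coordinates", {
  seqs <- c(a = "MKVWACD", b = "MKVWACD", c = "MKVWACD")
  msa <- center_star_msa(seqs, "a")
  expect_equal(unname(msa), unname(seqs))   # identical sequences: gapless

  seqs2 <- c(anchor = "MKVWACDEFG", ins = "MKVWAPPPCDEFG")
  msa2 <- center_star_msa(seqs2, "anchor")
  expect_equal(nchar(msa2[["anchor"]]), 13)
  expect_equal(lengths(regmatches(msa2[["anchor"]],
                                  gregexpr("-", msa2[["anchor"]]))), 3)

  set.seed(8)
  for (k in 1:10) {
    n <- sample(3:6, 1)
    seqs <- setNames(vapply(seq_len(n), function(i)
      rand_peptide(sample(10:30, 1)), ""), paste0("s", seq_len(n)))
    msa <- center_star_msa(seqs, "s1")
    expect_length(unique(nchar(msa)), 1)              # equal row lengths
    expect_gte(nchar(msa[["s1"]]), nchar(seqs[["s1"]]))  # >= anchor length
    expect_equal(gsub("-", "", msa), seqs)            # rows preserve sequences
  }
  expect_error(center_star_msa(c(a = "MKV"), "zz"), class = "wrky_config_error")
})

test_that("p-distances match direct counting", {
  msa <- c(r1 = "AAAAAAAAAA", r2 = "AAAAAAAAAA")
  expect_equal(unname(pdistance_matrix(msa)[1, 2]), 0)
  msa2 <- c(r1 = "AAAAAAAAAA", r2 = "DDAAAAAAAA")
  expect_equal(unname(pdistance_matrix(msa2)[1, 2]), 0.2)
  set.seed(9)
  for (k in 1:30) {
    len <- sample(8:20, 1)
    mk_row <- function() paste(sample(c("A", "C", "D", "-"), len, TRUE,
                                      prob = c(.3, .3, .3, .1)), collapse = "")
    msa <- c(x = mk_row(), y = mk_row())
    expected <- oracle_pdistance(msa[["x"]], msa[["y"]])
    if (is.na(expected)) {
      expect_error(pdistance_matrix(msa), "comparable",
                   class = "wrky_format_error")
    } else {
      expect_equal(unname(pdistance_matrix(msa)[1, 2]), expected)
    }
  }
})

test_that("subgroup assignment uses patristic distance with the tie rule", {
  refs <- data.frame(id = c("rA", "rB", "rC"),
                     label = c("IIa", "IIb", "IIa"),
                     stringsAsFactors = FALSE)
  d <- matrix(c(0, 1, 1, 1.2,
                1, 0, 2, 2,
                1, 2, 0, 2,
                1.2, 2, 2, 0), 4, 4,
              dimnames = list(c("q", "rA", "rB", "rC"),
                              c("q", "rA", "rB", "rC")))
  # exact tie rA/rB at 1; third nearest is rC (IIa) -> majority IIa
  expect_equal(assign_subgroup(d, "q", refs), "IIa")

  d2 <- d; d2["q", "rB"] <- d2["rB", "q"] <- 0
  expect_equal(assign_subgroup(d2, "q", refs), "IIb")  # distance 0 wins
  expect_error(assign_subgroup(d, "q", refs[0, ]), class = "wrky_config_error")
})

test_that("classify_family recovers groups and subgroups from generator truth", {
  refs <- gen_reference_set()
  coh <- gen_wrky_cohort(10, c("I", "IIb", "III"), seed = 31,
                         reference_set = refs)
  fam <- classify_family(coh$records, refs)
  expect_equal(fam$group, coh$truth$group)   # 30/30 recovery
  expect_false(any(fam$conflict))
  expect_equal(fam$subgroup[fam$group == "II"], rep("IIb", 10))

  empty <- classify_family(coh$records[0, ], refs)
  expect_equal(nrow(empty), 0)
})

test_that("rule-versus-phylogeny conflicts are flagged, not overridden", {
  # a C2HC protein whose domain is identical to the IIc reference sequence
  refs <- gen_reference_set()
  q <- gen_wrky_protein("III", seed = 77)
  dom <- q$truth$domains[[1]]
  dom_seq <- substr(q$record$sequence, dom$hept_start,
                    dom$finger_positions[4])
  refs$sequence[refs$label == "IIc"] <- dom_seq
  fam <- classify_family(q$record, refs)
  expect_equal(fam$group, "III")        # the rule call stands
  expect_true(fam$conflict)
  expect_equal(fam$subgroup, "IIc")     # the disagreeing placement is recorded
})

test_that("family summaries aggregate the packaged fixture correctly", {
  s <- summarize_family(load_table1())
  expect_equal(s$n, 95)
  expect_equal(unname(s$group_counts["I"]), 17)
  expect_equal(unname(s$group_counts["II"]), 67)
  expect_equal(unname(s$group_counts["III"]), 11)
  expect_equal(unname(s$variant_counts["WRKYGQK"]), 88)
  expect_equal(sum(s$variant_counts) - s$variant_counts[["WRKYGQK"]], 7)
  expect_equal(s$length_min, 101)
  expect_equal(s$length_max, 865)
  expect_equal(s$length_mean, round(s$length_mean_raw, 1))
})
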