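test_that("heptapeptide search finds all variants at exact positions", {
  s <- paste0(strrep("A", 10), "WRKYGQK", strrep("A", 5))
  h <- find_heptapeptides(s)
  expect_equal(h$start, 11)
  expect_equal(h$variant, "WRKYGQK")

  h2 <- find_heptapeptides(paste0("MAA", "WKKYDQK", "GG"))
  expect_equal(h2$variant, "WKKYDQK")

  expect_equal(nrow(find_heptapeptides(strrep("A", 30))), 0)
  # results do not depend on variant set ordering
  s3 <- paste0("WRKYGQK", "AA", "WRKYGKK")
  expect_identical(find_heptapeptides(s3, c("WRKYGKK", "WRKYGQK")),
                   find_heptapeptides(s3, c("WRKYGQK", "WRKYGKK")))
})

test_that("zinc finger search honours spacing ranges and type preference", {
  mk <- function(n1, n2, n3, last)
    paste0("C", strrep("A", n1), "C", strrep("A", n2), "H",
           strrep("A", n3), last)
  f <- find_zinc_finger(mk(7, 23, 1, "C"))
  expect_equal(f$finger_type, "C2HC")
  expect_equal(f$spacings, c(7, 23, 1))

  f2 <- find_zinc_finger(mk(4, 22, 1, "H"))
  expect_equal(f2$finger_type, "C2H2")
  expect_equal(f2$spacings, c(4, 22, 1))

  expect_null(find_zinc_finger(strrep("A", 60)))
  # ambiguous X never fills a coordinating position
  expect_null(find_zinc_finger(gsub("C", "X", mk(4, 22, 1, "H"))))
  # spacing outside the profile is rejected
  expect_null(find_zinc_finger(mk(9, 23, 1, "H")))
  # strict profile rejects X24 that the default accepts
  expect_equal(find_zinc_finger(mk(4, 24, 1, "H"))$spacings[2], 24)
  expect_null(find_zinc_finger(mk(4, 24, 1, "H"),
                               pattern_space = wrky_pattern_space("strict")))
})

test_that("domain assembly pairs anchors with downstream fingers", {
  p1 <- gen_wrky_protein("I", seed = 21)
  d1 <- assemble_domains(p1$record$sequence)
  expect_length(d1, 2)
  expect_equal(vapply(d1, `[[`, "", "terminus"), c("N", "C"))

  p3 <- gen_wrky_protein("III", seed = 22)
  d3 <- assemble_domains(p3$record$sequence)
  expect_length(d3, 1)
  expect_equal(d3[[1]]$terminus, "only")
  expect_equal(d3[[1]]$finger$finger_type, "C2HC")

  # finger beyond the max gap is not assembled
  far <- paste0("WRKYGQK", strrep("A", 70),
                "C", strrep("A", 4), "C", strrep("A", 22), "HAH")
  expect_length(assemble_domains(far), 0)
  expect_length(assemble_domains(far,
    pattern_space = wrky_pattern_space(max_gap = 100)), 1)
})

test_that("implanted domains are recovered exactly across the pattern space", {
  cases <- expand.grid(group = c("II", "III"), n2 = 22:23,
                       stringsAsFactors = FALSE)
  k <- 0
  for (i in seq_len(nrow(cases))) {
    g <- cases$group[i]
    n1s <- if (g == "III") 7 else 4:5
    for (n1 in n1s) {
      k <- k + 1
      sp <- c(n1, cases$n2[i], 1)
      p <- gen_wrky_protein(g, spacing_choice = sp, seed = 300 + k)
      d <- assemble_domains(p$record$sequence)
      expect_length(d, 1)
      expect_equal(d[[1]]$hept_start, p$truth$domains[[1]]$hept_start)
      expect_equal(d[[1]]$finger$spacings, sp)
      expect_equal(d[[1]]$finger$positions,
                   p$truth$domains[[1]]$finger_positions)
    }
  }
  # group I: both implanted domains and their coordinates recovered
  for (s in 1:5) {
    p <- gen_wrky_protein("I", seed = 400 + s)
    d <- assemble_domains(p$record$sequence)
    expect_length(d, 2)
    expect_equal(vapply(d, `[[`, 0, "hept_start"),
                 vapply(p$truth$domains, `[[`, 0, "hept_start"))
  }
})

test_that("spacing signatures render and parse in both dialects", {
  expect_equal(spacing_signature(list(finger = list(spacings = c(7, 23, 1),
                                                    finger_type = "C2HC"))),
               "C-X7-C-X23-H-X1-C")
  expect_equal(spacing_signature(list(finger = list(spacings = c(5, 23, 1),
                                                    finger_type = "C2H2"))),
               "C-X5-C-X23-H-X1-H")

  p <- parse_signature("C-X_7_-C-X_23_-HTC")
  expect_equal(p[[1]]$finger_type, "C2HC")
  expect_equal(p[[1]]$spacings, c(7, 23, 1))

  p2 <- parse_signature("C-X_5_-C-X_23_-HXH")
  expect_equal(p2[[1]]$finger_type, "C2H2")
  expect_equal(p2[[1]]$spacings, c(5, 23, 1))

  dual <- parse_signature("C-X_4_-C-X_22_-HXH (N)/C-X_4_-C-X_23_-HXH (C)")
  expect_length(dual, 2)
  expect_equal(vapply(dual, `[[`, "", "terminus"), c("N", "C"))
  expect_equal(dual[[1]]$spacings, c(4, 22, 1))
  expect_equal(dual[[2]]$spacings, c(4, 23, 1))

  expect_error(parse_signature("W-X_4_-nonsense"), "cannot parse",
               class = "wrky_format_error")

  # canonical render/parse is a round trip over the whole pattern space
  for (type in c("C2H2", "C2HC")) for (n1 in 4:7) for (n2 in 22:24) {
    sig <- spacing_signature(list(finger = list(spacings = c(n1, n2, 1),
                                                finger_type = type)))
    back <- parse_signature(sig)[[1]]
    expect_equal(back$finger_type, type)
    expect_equal(back$spacings, c(n1, n2, 1))
  }
})

test_that("scanning is deterministic and cohort-level scan matches truth", {
  coh <- gen_wrky_cohort(4, c("I", "II", "III"), seed = 9)
  tab1 <- scan_domains(coh$records)
  tab2 <- scan_domains(coh$records)
  expect_identical(tab1, tab2)
  n_expected <- sum(ifelse(coh$truth$group == "I", 2, 1))
  expect_equal(nrow(tab1), n_expected)
})
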