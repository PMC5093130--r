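gb5 <- gb5_sequence

test_that("gB5 has the canonical 8C framework and loop content", {
  fw <- detect_framework(gb5)
  expect_identical(fw$cys_positions, c(4L, 12L, 17L, 18L, 24L, 31L, 36L, 40L))
  expect_identical(fw$pattern, "C-C-CC-C-C-C-C")
  expect_identical(names(fw$cys_labels),
                   c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"))
  ld <- decompose_loops(gb5, fw)
  expect_identical(ld$n_term, "DPT")
  expect_identical(ld$loops[["1"]], "SVLGDFK")
  expect_identical(ld$loops[["3"]], "SKFNY")
  expect_identical(ld$loops[["4"]], "GSTAAY")
  expect_identical(ld$loops[["7"]], "P")
  # the empty CC gap carries no loop number
  expect_length(ld$loops, 7L)
})

test_that("framework detection covers degenerate spacings", {
  expect_identical(detect_framework("CACAC")$cys_positions, c(1L, 3L, 5L))
  expect_identical(detect_framework("CACAC")$pattern, "C-C-C")
  fw0 <- detect_framework("AAAA")
  expect_identical(fw0$cys_positions, integer(0))
  expect_identical(fw0$pattern, "")
  # 8C sequence ending exactly at CysVIII has an empty loop 7
  trimmed <- substr(gb5, 1, 40)
  expect_identical(decompose_loops(trimmed)$loops[["7"]], "")
})

test_that("loop decomposition reconstructs any input sequence", {
  set.seed(21)
  for (rep in 1:50) {
    s <- random_peptide(sample(10:80, 1))
    expect_identical(reconstruct_sequence(decompose_loops(s)), s)
  }
  for (sf in c("pro_rich_8C", "8C", "6C", "10C")) {
    s <- generate_peptide(sf, seed = 100 + nchar(sf))$record$sequence
    expect_identical(reconstruct_sequence(decompose_loops(s)), s)
  }
  expect_error(decompose_loops("AAAA", detect_framework("CAC")),
               "inconsistent")
})

test_that("proline metrics match gB5 and edge cases", {
  pm <- pro_metrics(gb5)
  expect_equal(pm$count, 4L)
  expect_identical(pm$positions, c(2L, 14L, 33L, 41L))
  expect_true(pm$n_flank)
  expect_true(pm$c_flank)
  pm0 <- pro_metrics("AAAA")
  expect_equal(pm0$count, 0L)
  expect_false(pm0$n_flank || pm0$c_flank)
  pm2 <- pro_metrics("PAAAP")
  expect_equal(pm2$count, 2L)
  expect_true(pm2$n_flank && pm2$c_flank)
})

test_that("the chitin-binding motif is found once in gB5, at Ser19", {
  hits <- scan_chitin_motif(gb5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$ser_pos, 19L)
  expect_equal(hits$phi1_pos, 21L)
  expect_equal(hits$phi2_pos, 23L)
  expect_equal(hits$tyr_pos, 30L)
  expect_identical(hits$matched_window, "SKFNYCGSTAAY")
  expect_equal(nrow(scan_chitin_motif(strrep("A", 30))), 0L)
})

test_that("strict-small X mode rejects the non-small X residues of gB5", {
  # gB5 carries K20 at an X position, so the literal small-aa reading
  # of the motif must reject it while the default wildcard accepts it
  strict <- motif_definition(x_mode = "strict_small")
  expect_equal(nrow(scan_chitin_motif(gb5, strict)), 0L)
})

test_that("motif scanner agrees with a regex oracle on random sequences", {
  set.seed(22)
  n_checked <- 0
  for (rep in 1:400) {
    s <- random_peptide(sample(15:60, 1))
    if (rep %% 2 == 0) {
      # plant one motif window at a random admissible offset
      planted <- paste0("S", "A", sample(c("F", "W", "Y"), 1), "A",
                        sample(c("F", "W", "Y"), 1), "CG", "AAAA",
                        sample(c("F", "W", "Y"), 1))
      at <- sample(nchar(s) - 12 + 1, 1)
      substr(s, at, at + 11) <- planted
    }
    got <- scan_chitin_motif(s)$ser_pos
    expect_identical(got, oracle_motif_positions(s))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 400)
})

test_that("subfamily classification applies the Pro-rich 8C criteria", {
  call <- classify_subfamily(gb5)
  expect_identical(call$subfamily, "8C")
  expect_true(call$pro_rich_8C)
  expect_true(all(call$evidence))
  # 6C with motif is 6C but never Pro-rich 8C
  six <- generate_peptide("6C", seed = 31)$record$sequence
  call6 <- classify_subfamily(six)
  expect_identical(call6$subfamily, "6C")
  expect_false(call6$pro_rich_8C)
  # odd cysteine count is unclassified
  expect_identical(classify_subfamily("ACAACAACA")$subfamily,
                   "unclassified")
  # undetermined residues block classification with a reason
  withx <- classify_subfamily(sub("K", "X", gb5))
  expect_identical(withx$subfamily, "unclassified")
  expect_match(withx$reason, "undetermined")
})
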