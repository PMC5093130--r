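test_that("generated peptides satisfy their labelled class definitions", {
  g <- generate_peptide("pro_rich_8C", seed = 71)
  call <- classify_subfamily(g$record$sequence)
  expect_true(call$pro_rich_8C)
  # truth metadata is re-derivable from the emitted sequence
  hits <- scan_chitin_motif(g$record$sequence)
  expect_true(g$truth$motif_ser %in% hits$ser_pos)
  expect_identical(pro_metrics(g$record$sequence)$positions,
                   g$truth$pro_positions)
  expect_identical(classify_subfamily(
    generate_peptide("6C", seed = 72)$record$sequence)$subfamily, "6C")
  expect_identical(classify_subfamily(
    generate_peptide("10C", seed = 73)$record$sequence)$subfamily, "10C")
  eight <- classify_subfamily(
    generate_peptide("8C", seed = 74)$record$sequence)
  expect_identical(eight$subfamily, "8C")
  expect_false(eight$pro_rich_8C)
})

test_that("identical seeds give identical output; the RNG is restored", {
  a <- generate_peptide("pro_rich_8C", seed = 75)
  b <- generate_peptide("pro_rich_8C", seed = 75)
  expect_identical(a, b)
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_precursor("short", seed = 76))
  expect_identical(runif(1), before)
  p1 <- generate_precursor("barwin", seed = 77)
  p2 <- generate_precursor("barwin", seed = 77)
  expect_identical(p1$record$full_sequence, p2$record$full_sequence)
})

test_that("generator and classifier agree on class labels", {
  set.seed(78)
  for (rep in 1:200) {
    sf <- sample(c("pro_rich_8C", "8C", "6C", "10C"), 1)
    s <- generate_peptide(sf)$record$sequence
    call <- classify_subfamily(s)
    if (sf == "pro_rich_8C") {
      expect_true(call$pro_rich_8C)
    } else {
      expect_identical(call$subfamily, sub("pro_rich_", "", sf))
      expect_false(call$pro_rich_8C)
    }
  }
})

test_that("precursor C-tails follow the configured cargo modes", {
  short <- generate_precursor("short", seed = 81)
  expect_equal(nchar(short$record$c_tail), 20L)
  expect_identical(cargo_classification(short$record)$status, "cargo_free")
  barwin <- generate_precursor("barwin", seed = 82)
  expect_equal(nchar(barwin$record$c_tail), 126L)
  expect_identical(cargo_classification(barwin$record)$status, "cargo")
  chit <- generate_precursor("chitinase", seed = 83)
  expect_equal(nchar(chit$record$c_tail), 254L)
})

test_that("rule-based partitioning recovers generator ground truth", {
  recovered <- 0L
  for (i in 1:500) {
    g <- generate_precursor("short", seed = 8000L + i)
    p <- partition_domains(g$record$full_sequence)
    if (identical(p$signal_end, g$truth$signal_end) &&
        identical(p$mature_end, g$truth$mature_end)) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered / 500, 0.99)
})

test_that("the screen fixture has the published composition", {
  fx <- screen_fixture(seed = 1)
  expect_length(fx$records, 85L)
  expect_equal(nrow(fx$truth), 85L)
  expect_equal(sum(fx$truth$category == "none"), 52L)
  expect_equal(table(fx$truth$category)[["odd_cys"]], 1L)
  expect_equal(table(fx$truth$category)[["short_signal"]], 3L)
  expect_equal(table(fx$truth$category)[["undetermined"]], 3L)
  expect_equal(table(fx$truth$category)[["duplicate_same_plant"]], 9L)
  expect_equal(table(fx$truth$category)[["missing_pro_flanks"]], 17L)
  expect_gte(length(unique(fx$truth$organism)), 40L)
})

test_that("each decoy is removed by exactly its assigned criterion", {
  fx <- screen_fixture(seed = 9)
  res <- filter_homologs(fx$records)
  for (criterion in names(res$report$removed)) {
    expect_setequal(res$report$removed[[criterion]]$ids,
                    fx$truth$id[fx$truth$category == criterion])
  }
  expect_setequal(res$report$survivor_ids,
                  fx$truth$id[fx$truth$category == "none"])
})

test_that("fixture survivors reproduce the screen arithmetic per seed", {
  for (seed in c(1, 17, 123)) {
    fx <- screen_fixture(seed = seed)
    res <- filter_homologs(fx$records)
    expect_length(res$survivors, 52L)
    um <- unique_mature_domains(res$survivors)
    expect_equal(um$n_unique, 42L)
    expect_equal(um$n_multi_plant, 6L)
    counts <- sort(unname(vapply(um$groups[um$multi_plant], nrow,
                                 integer(1))), decreasing = TRUE)
    expect_equal(counts, c(6L, 2L, 2L, 2L, 2L, 2L))
  }
  a <- screen_fixture(seed = 42)
  b <- screen_fixture(seed = 42)
  expect_identical(a, b)
})

test_that("infeasible generator configurations are rejected", {
  expect_error(generator_config(mature_len = c(20, 25)), "minimum")
})
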