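make_precursor_seq <- function(signal_len = 20) {
  paste0(strrep("A", signal_len - 1), "G", gb5_sequence, strrep("L", 20))
}

test_that("rule-based partitioning cleaves between Gly and Asp", {
  full <- make_precursor_seq(20)
  rec <- partition_domains(full)
  expect_equal(rec$signal_end, 20L)
  expect_identical(substr(rec$signal, 20, 20), "G")
  expect_identical(substr(rec$mature, 1, 1), "D")
  expect_identical(rec$mature, gb5_sequence)  # CysVIII + 1-residue tail
  expect_identical(rec$c_tail, strrep("L", 20))
  expect_match(rec$cleavage_rule_used, "G|D")
})

test_that("annotation boundaries are used verbatim", {
  full <- make_precursor_seq(20)
  rec <- partition_domains(full, annotation = list(signal_end = 18,
                                                   mature_end = 55))
  expect_equal(rec$signal_end, 18L)
  expect_equal(nchar(rec$mature), 55L - 18L)
  expect_identical(rec$cleavage_rule_used, "annotation")
})

test_that("a missing cleavage site yields a diagnostic, not a partition", {
  full <- paste0(strrep("A", 25), strrep("L", 30))
  rec <- partition_domains(full)
  expect_true(is.na(rec$mature))
  expect_match(attr(rec, "diagnostic"), "no .*cleavage site")
  expect_error(partition_domains("GDAAA"), "30 residues")
})

test_that("cargo classification thresholds the C-tail length", {
  base <- make_precursor_seq(20)
  rec20 <- partition_domains(base)
  expect_identical(cargo_classification(rec20)$status, "cargo_free")
  rec126 <- partition_domains(paste0(strrep("A", 19), "G", gb5_sequence,
                                     strrep("L", 126)))
  expect_identical(cargo_classification(rec126)$status, "cargo")
  expect_equal(cargo_classification(rec126)$c_tail_length, 126L)
  # the boundary is half-open: exactly 50 residues is cargo
  rec50 <- partition_domains(paste0(strrep("A", 19), "G", gb5_sequence,
                                    strrep("L", 50)))
  expect_identical(cargo_classification(rec50)$status, "cargo")
  unset <- partition_domains(paste0(strrep("A", 25), strrep("L", 30)))
  expect_error(cargo_classification(unset), "unset")
})

test_that("the filter conserves records and attributes each once", {
  fx <- screen_fixture(seed = 3)
  res <- filter_homologs(fx$records)
  counts <- vapply(res$report$removed, function(x) x$count, integer(1))
  expect_equal(sum(counts) + length(res$survivors),
               res$report$input_count)
  all_removed <- unlist(lapply(res$report$removed, function(x) x$ids))
  expect_false(anyDuplicated(all_removed) > 0)
  expect_length(intersect(all_removed, res$report$survivor_ids), 0)
})

test_that("re-filtering the survivors changes nothing (idempotence)", {
  fx <- screen_fixture(seed = 4)
  res1 <- filter_homologs(fx$records)
  res2 <- filter_homologs(res1$survivors)
  expect_equal(length(res2$survivors), length(res1$survivors))
  expect_identical(res2$report$survivor_ids, res1$report$survivor_ids)
  expect_true(all(vapply(res2$report$removed, function(x) x$count,
                         integer(1)) == 0L))
})

test_that("empty and all-passing inputs behave as identities", {
  empty <- filter_homologs(list())
  expect_length(empty$survivors, 0)
  expect_equal(empty$report$input_count, 0L)
  fx <- screen_fixture(seed = 5)
  keep <- filter_homologs(fx$records)$survivors
  again <- filter_homologs(keep)
  expect_identical(vapply(again$survivors, function(r) r$id, ""),
                   vapply(keep, function(r) r$id, ""))
})

test_that("criterion order changes attribution but not the survivor set", {
  fx <- screen_fixture(seed = 6)
  default_res <- filter_homologs(fx$records)
  reordered <- filter_criteria(order = c("missing_pro_flanks",
                                         "undetermined", "short_signal",
                                         "odd_cys",
                                         "duplicate_same_plant"))
  res2 <- filter_homologs(fx$records, reordered)
  expect_setequal(res2$report$survivor_ids,
                  default_res$report$survivor_ids)
})

test_that("duplicate removal is input-order dependent, keeping the first", {
  a <- precursor_record("first", make_precursor_seq(20), "Pinus sylvestris",
                        signal_end = 20, mature_end = 61)
  b <- precursor_record("second", make_precursor_seq(20), "Pinus sylvestris",
                        signal_end = 20, mature_end = 61)
  c_ <- precursor_record("other_plant", make_precursor_seq(20),
                         "Picea abies", signal_end = 20, mature_end = 61)
  res <- filter_homologs(list(a, b, c_))
  expect_identical(res$report$survivor_ids, c("first", "other_plant"))
  res_rev <- filter_homologs(list(b, a, c_))
  expect_identical(res_rev$report$survivor_ids, c("second", "other_plant"))
})

test_that("mature-domain grouping counts unique and multi-plant domains", {
  fx <- screen_fixture(seed = 2)
  surv <- filter_homologs(fx$records)$survivors
  um <- unique_mature_domains(surv)
  expect_equal(um$n_unique, 42L)
  expect_equal(um$n_multi_plant, 6L)
  sizes <- sort(unname(vapply(um$groups[um$multi_plant], nrow,
                               integer(1))), decreasing = TRUE)
  expect_equal(sizes, c(6L, 2L, 2L, 2L, 2L, 2L))
  # all-distinct input gives one group per record
  distinct <- surv[1:6]
  expect_equal(unique_mature_domains(distinct)$n_unique,
               length(unique(vapply(distinct, function(r) r$mature, ""))))
  # unset mature domain is an error naming the record
  bad <- precursor_record("nodomain", make_precursor_seq(20))
  expect_error(unique_mature_domains(list(bad)), "nodomain")
})
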