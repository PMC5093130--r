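test_that("p-distance counts mismatches over comparable sites", {
  al <- c(a = "AAAA", b = "AAAA")
  expect_equal(p_distance(al)["a", "b"], 0)
  expect_equal(p_distance(c(a = "AAAA", b = "TTTT"))["a", "b"], 1)
  expect_equal(p_distance(c(a = "AAAA", b = "AATT"))["a", "b"], 0.5)
  # pairwise deletion: gapped sites drop out of the denominator
  expect_equal(p_distance(c(a = "AA-A", b = "AATT"))["a", "b"], 1 / 3)
  expect_error(p_distance(c(a = "--AA", b = "TT--")), "no comparable")
  # Poisson correction
  expect_equal(p_distance(c(a = "AAAA", b = "AATT"),
                          correction = "poisson")["a", "b"],
               -log(0.5))
  d <- p_distance(c(a = "ARND", b = "ARNE", c = "GRND"))
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("three-taxon neighbor joining matches the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  pl <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                        tr$tip.label)
  expect_equal(pl[["A"]], 1)
  expect_equal(pl[["B"]], 1)
  expect_equal(pl[["C"]], 3)
})

test_that("NJ recovers additive matrices exactly", {
  set.seed(61)
  for (rep in 1:100) {
    dm <- random_additive_matrix(sample(4:12, 1))
    tr <- neighbor_joining(dm)
    back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(back - dm)), 1e-9)
  }
})

test_that("NJ topology agrees with an independent implementation", {
  set.seed(62)
  for (rep in 1:10) {
    dm <- random_additive_matrix(sample(5:10, 1))
    mine <- neighbor_joining(dm)
    reference <- ape::nj(dm)
    expect_equal(ape::dist.topo(ape::unroot(mine),
                                ape::unroot(reference))[1], 0)
  }
})

test_that("NJ is deterministic under ties and handles tiny inputs", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- write_newick(neighbor_joining(d))
  t2 <- write_newick(neighbor_joining(d))
  expect_identical(t1, t2)
  expect_equal(ape::Ntip(neighbor_joining(d)), 4L)
  d2 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighbor_joining(d2)
  expect_equal(sort(tr2$edge.length), c(1.5, 1.5))
  expect_error(neighbor_joining(matrix(0, 1, 1,
                                       dimnames = list("A", "A"))),
               "two taxa")
})

test_that("Newick output round-trips and quotes awkward labels", {
  set.seed(63)
  dm <- random_additive_matrix(8)
  tr <- neighbor_joining(dm)
  nwk <- write_newick(tr)
  reparsed <- ape::read.tree(text = nwk)
  expect_equal(ape::dist.topo(tr, reparsed)[1], 0)
  expect_equal(ape::cophenetic.phylo(reparsed)[rownames(dm), colnames(dm)],
               dm, tolerance = 1e-4)
  d2 <- matrix(c(0, 3, 3, 0), 2, 2,
               dimnames = list(c("sp one", "sp two"), c("sp one", "sp two")))
  nwk2 <- write_newick(neighbor_joining(d2))
  expect_match(nwk2, "'sp one'", fixed = TRUE)
  # ape's parser warns on quoted labels but still reads the topology
  expect_equal(ape::Ntip(suppressWarnings(ape::read.tree(text = nwk2))),
               2L)
})

test_that("profile columns give frequencies and information in bits", {
  al <- c(a = "CAW-", b = "CCW-", c = "CGWF")
  pr <- profile_matrix(al)
  expect_equal(unname(pr$freq["C", 1]), 1)
  expect_equal(pr$info[1], log2(20))
  expect_equal(pr$info[3], log2(20))       # conserved W column
  expect_equal(pr$info[2], log2(20) - log2(3))  # three equifrequent aa
  expect_true(is.na(pr$info[4]) == FALSE)  # one residue, others gap
  expect_equal(pr$n_nongap[4], 1L)
  # all-gap columns are flagged with NA frequencies
  pr2 <- profile_matrix(c(a = "A-", b = "C-"))
  expect_true(pr2$all_gap[2])
  expect_true(all(is.na(pr2$freq[, 2])))
})

test_that("uniform 20-residue columns carry zero information", {
  al <- stats::setNames(AA20_T, paste0("s", 1:20))
  pr <- profile_matrix(al)
  expect_equal(pr$info[1], 0)
  expect_equal(sum(pr$freq[, 1]), 1, tolerance = 1e-12)
})

test_that("entropy matches a direct Shannon oracle on random columns", {
  set.seed(64)
  rows <- vapply(1:30, function(i) random_peptide(25), "")
  names(rows) <- paste0("r", 1:30)
  pr <- profile_matrix(rows)
  mat <- do.call(rbind, strsplit(rows, ""))
  for (k in seq_len(25)) {
    tab <- table(mat[, k]) / nrow(mat)
    h <- -sum(tab * log2(tab))
    expect_equal(pr$info[k], log2(20) - h, tolerance = 1e-12)
    expect_equal(sum(pr$freq[, k]), 1, tolerance = 1e-12)
    expect_true(pr$info[k] >= 0 && pr$info[k] <= log2(20))
  }
})

test_that("the global pairwise aligner returns a consistent alignment", {
  out <- align_global("HEVEIN", "HEVIN")
  expect_equal(nchar(out[["a"]]), nchar(out[["b"]]))
  expect_identical(gsub("-", "", out[["a"]]), "HEVEIN")
  expect_identical(gsub("-", "", out[["b"]]), "HEVIN")
  d <- p_distance(c(a = out[["a"]], b = out[["b"]]))
  expect_lt(d["a", "b"], 0.5)
})
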