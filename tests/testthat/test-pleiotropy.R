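test_that("T1 counts match hand enumeration", {
  net <- make_t1_network()
  expect_equal(cis_pleiotropy_count(net, "G1"), 2L)
  expect_equal(cis_pleiotropy_count(net, "G3"), 0L)
  expect_equal(trans_pair_pleiotropy_count(net, "G4", "G1"), 3L)
  expect_equal(trans_pair_pleiotropy_count(net, "G2", "G1"), 0L)
  expect_equal(parallel_pleiotropy_count(net, "G4", "G1"), 1L)  # only G5
  expect_equal(parallel_pleiotropy_count(net, "G4", "G3"), 3L)  # none nested
  expect_error(cis_pleiotropy_count(net, "G5"), "no deletion strain")
  expect_error(trans_pair_pleiotropy_count(net, "G3", "G1"), "not an edge")
  expect_error(parallel_pleiotropy_count(net, "G1", "G5"),
               "no deletion strain")
})

test_that("parallel + nested = trans count (set conservation, random nets)", {
  for (case in 1:30) {
    set.seed(1200 + case)
    n <- sample(5:60, 1)
    comp <- make_random_compendium(n, sample(n:100, 1))
    net <- suppressMessages(select_focal_genes(build_adjacency(comp)))
    if (length(net$focal_genes) == 0L) next
    pairs <- cis_trans_pairs(net, comp)
    for (i in seq_len(nrow(pairs))) {
      t <- pairs$trans[i]; f <- pairs$focal[i]
      expect_equal(pairs$trans_count[i], oracle_trans_count(net$A, t, f))
      expect_equal(pairs$parallel_count[i],
                   oracle_parallel_count(net$A, t, f))
      expect_equal(pairs$parallel_count[i] +
                     length(oracle_nested(net$A, t, f)),
                   pairs$trans_count[i])
    }
  }
})

test_that("a focal gene with zero cis targets has nothing nested", {
  net <- make_t1_network()  # G3 has cis count 0
  pairs <- cis_trans_pairs(net)
  g3 <- pairs[pairs$focal == "G3", ]
  expect_true(all(g3$parallel_count == g3$trans_count))
})

test_that("Euclidean pleiotropy is a distance from the wild-type origin", {
  comp <- make_t1_compendium()
  comp$M["G2::YPD", ] <- c(3, 4, 0, 0, 0)
  expect_equal(euclidean_pleiotropy(comp, "G2"), 5)
  comp$M["G3::YPD", ] <- 0
  expect_equal(euclidean_pleiotropy(comp, "G3"), 0)
  comp$M["G4::YPD", ] <- c(0, 0, 0, -6, 0)
  expect_equal(euclidean_pleiotropy(comp, "G4", exclude = "G4"), 0)
  # missing coordinates contribute nothing
  comp$M["G2::YPD", 2] <- NA
  expect_equal(euclidean_pleiotropy(comp, "G2"), 3)
  # linear coordinates put wild type at the all-ones point
  comp$M["G3::YPD", ] <- c(1, 0, 0, 0, 0)
  expect_equal(euclidean_pleiotropy(comp, "G3", coordinates = "linear"), 1)
  expect_error(euclidean_pleiotropy(comp, "G9"), "no deletion strain")
})

test_that("Euclidean pleiotropy is reorder-invariant and |M|-monotone", {
  set.seed(31)
  comp <- make_random_compendium(6, 30)
  comp$M[] <- rnorm(length(comp$M))
  d0 <- euclidean_pleiotropy(comp, comp$strains$deleted_gene[1])
  perm <- sample(length(comp$genes))
  comp2 <- expression_compendium(comp$strains, comp$genes[perm],
                                 comp$M[, perm], comp$P[, perm])
  expect_equal(euclidean_pleiotropy(comp2, comp$strains$deleted_gene[1]), d0)
  comp3 <- comp
  comp3$M[1, 5] <- comp3$M[1, 5] * 3  # inflate one |M|
  expect_gt(euclidean_pleiotropy(comp3, comp$strains$deleted_gene[1]), d0)
})

test_that("per-gene records agree with scalar operations", {
  set.seed(47)
  comp <- make_random_compendium(15, 40)
  net <- suppressMessages(select_focal_genes(build_adjacency(comp)))
  recs <- pleiotropy_records(net, comp)
  for (d in net$deletions) {
    expect_equal(recs$cis_count[recs$gene == d],
                 cis_pleiotropy_count(net, d))
    expect_equal(recs$cis_euclidean[recs$gene == d],
                 euclidean_pleiotropy(comp, d, exclude = d))
  }
  # self-coordinate retained on request
  recs_all <- pleiotropy_records(net, comp, exclude_self = FALSE)
  expect_equal(recs_all$cis_euclidean[1],
               euclidean_pleiotropy(comp, net$deletions[1]))
})

test_that("pair-level Euclidean distances exclude trans and focal coordinates", {
  comp <- make_t1_compendium()
  net <- make_t1_network()
  pairs <- cis_trans_pairs(net, comp)
  i <- which(pairs$trans == "G4" & pairs$focal == "G1")
  expect_equal(pairs$trans_euclidean[i],
               euclidean_pleiotropy(comp, "G4", exclude = c("G4", "G1")))
})

test_that("direction restriction keeps only focal-decreasing pairs", {
  comp <- make_t1_compendium(m_overrides = list("G4:G1" = 2, "G2:G1" = -2))
  net <- suppressMessages(select_focal_genes(build_adjacency(comp)))
  pairs <- cis_trans_pairs(net, comp)
  dec <- focal_decreasing_pairs(net, comp, pairs)
  g1 <- dec[dec$focal == "G1", ]
  expect_identical(g1$trans, "G2")
  expect_true(all(dec$focal_effect_sign == "decrease"))
  # all-negative effects: nothing filtered
  comp_neg <- make_t1_compendium()
  net_neg <- suppressMessages(select_focal_genes(build_adjacency(comp_neg)))
  pairs_neg <- cis_trans_pairs(net_neg, comp_neg)
  expect_equal(nrow(focal_decreasing_pairs(net_neg, comp_neg, pairs_neg)),
               nrow(pairs_neg))
  expect_error(focal_decreasing_pairs(net_neg, NULL, cis_trans_pairs(net_neg)),
               "no effect signs")
})
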