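test_that("out-degree histograms partition the deletions", {
  net <- make_t1_network()
  h <- outdegree_histogram(net)  # row sums with self: 3, 2, 1, 5
  expect_equal(h[["1"]], 1L)
  expect_equal(h[["2"]], 1L)
  expect_equal(h[["3"]], 1L)
  expect_equal(h[["5"]], 1L)
  expect_equal(h[["0"]], 0L)
  expect_equal(sum(h), length(net$deletions))
  h_noself <- outdegree_histogram(net, include_self = FALSE)
  expect_equal(h_noself[["0"]], 1L)  # G3 affects only itself
  expect_equal(sum(h_noself), length(net$deletions))
  # empty network: all mass at K = 0
  comp <- make_t1_compendium()
  comp$P[] <- 1
  empty <- suppressMessages(build_adjacency(comp))
  expect_equal(outdegree_histogram(empty), c("0" = 4L))
})

test_that("power-law fit is exact on noiseless input", {
  k <- 1:100
  f <- suppressMessages(fit_powerlaw(setNames(k^-0.75, k)))
  expect_equal(f$gamma, 0.75, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$n_points, 100L)
  f2 <- suppressMessages(fit_powerlaw(setNames((1:50)^-2, 1:50)))
  expect_equal(f2$gamma, 2, tolerance = 1e-10)
  expect_error(fit_powerlaw(c("1" = 5, "2" = 3)), "at least 3")
  # zero-degree nodes are excluded (log undefined) and reported
  expect_message(fit_powerlaw(setNames(c(7, (1:10)^-1), 0:10)),
                 "zero-out-degree")
})

test_that("power-law exponent is recovered from multinomial samples", {
  set.seed(4242)
  k <- 1:1000
  draws <- sample(k, 1e5, replace = TRUE, prob = k^-0.75)
  h <- table(draws)
  f <- fit_powerlaw(setNames(as.numeric(h), names(h)))
  expect_lt(abs(f$gamma - 0.75), 0.1)
})

test_that("fitness regression matches closed forms", {
  # noiseless linear relation in log10(count)
  recs <- data.frame(gene = sprintf("g%02d", 1:12),
                     cis_count = c(1, 2, 5, 10, 20, 50, 100, 3, 7, 30, 60, 90),
                     cis_euclidean = NA_real_)
  w <- fitness_table(setNames(1 - 0.1 * log10(recs$cis_count), recs$gene))
  fit <- fitness_vs_pleiotropy_regression(recs, w)
  expect_equal(fit$slope, -0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # constant fitness: no association
  w0 <- fitness_table(setNames(rep(0.9, 12), recs$gene))
  fit0 <- fitness_vs_pleiotropy_regression(recs, w0)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  # two-point closed form: slope = dy/dx through both points, r^2 = 1
  # (plus a third gene with zero count that must be excluded)
  recs2 <- data.frame(gene = c("a", "b", "z"), cis_count = c(10, 100, 0),
                      cis_euclidean = NA_real_)
  w2 <- fitness_table(c(a = 0.95, b = 0.80, z = 0.99))
  fit2 <- suppressMessages(fitness_vs_pleiotropy_regression(
    rbind(recs2, recs2[1:2, ])[c(1, 2, 4, 5, 3), ], w2))
  expect_equal(fit2$slope, (0.80 - 0.95) / (log10(100) - log10(10)))
  expect_equal(fit2$n, 4L)
  expect_error(fitness_vs_pleiotropy_regression(recs2, w2), "at least 3")
})

test_that("fitness cost pairs follow the worked example", {
  genes <- c("f", "t1", "t2")
  A <- matrix(0L, 3, 3, dimnames = list(genes, genes))
  A[cbind(1:3, 1:3)] <- 1L
  A["t1", "f"] <- 1L
  A["t2", "f"] <- 1L
  A["f", "t1"] <- 1L   # so t1 also gets an incoming edge
  net <- new_net_for_test(genes, genes, A)
  w <- fitness_table(c(f = 0.9, t1 = 0.7, t2 = 0.8))
  fc <- suppressMessages(fitness_cost_pairs(net, w))
  pf <- fc$per_focal[fc$per_focal$focal == "f", ]
  expect_equal(pf$cis_cost, 0.1)
  expect_equal(pf$median_trans_cost, 0.25)   # median of {0.3, 0.2}
  expect_equal(sort(fc$pairs$trans_cost[fc$pairs$focal == "f"]), c(0.2, 0.3))
  pp <- proportion_cis_cost_greater(fc, "per_pair")
  expect_equal(pp$numerator[1],
               sum(fc$pairs$cis_cost > fc$pairs$trans_cost))
  # focal gene "f": cis cost 0.1 never exceeds trans costs {0.3, 0.2}
  expect_equal(sum(fc$pairs$focal == "f" &
                     fc$pairs$cis_cost > fc$pairs$trans_cost), 0)
})

test_that("neutral deletions tie everywhere and swaps are antisymmetric", {
  set.seed(19)
  comp <- make_random_compendium(15, 40)
  net <- suppressMessages(select_focal_genes(build_adjacency(comp)))
  w1 <- fitness_table(setNames(rep(1, 15), net$deletions))
  fc1 <- suppressMessages(fitness_cost_pairs(net, w1))
  expect_equal(proportion_cis_cost_greater(fc1, "per_pair")$numerator, 0L)
  expect_equal(proportion_cis_cost_greater(fc1, "per_focal")$numerator, 0L)
  # antisymmetry: swapping cis and trans costs swaps greater with lesser
  w2 <- fitness_table(setNames(runif(15, 0.5, 1.1), net$deletions))
  fc2 <- suppressMessages(fitness_cost_pairs(net, w2))
  greater <- proportion_cis_cost_greater(fc2, "per_pair")$numerator
  swapped <- fc2
  tmp <- swapped$pairs$cis_cost
  swapped$pairs$cis_cost <- swapped$pairs$trans_cost
  swapped$pairs$trans_cost <- tmp
  lesser_after_swap <- proportion_cis_cost_greater(swapped, "per_pair")
  expect_equal(lesser_after_swap$numerator,
               sum(fc2$pairs$trans_cost > fc2$pairs$cis_cost))
  expect_equal(greater +
                 sum(fc2$pairs$trans_cost > fc2$pairs$cis_cost) +
                 sum(fc2$pairs$trans_cost == fc2$pairs$cis_cost),
               nrow(fc2$pairs))
})
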