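test_that("generators are bit-reproducible from the spec seed", {
  spec <- synthetic_spec(n_genes = 150, n_deletions = 60, k_max = 40,
                         seed = 12)
  expect_identical(sample_outdegrees(spec), sample_outdegrees(spec))
  n1 <- generate_planted_network(spec)
  n2 <- generate_planted_network(spec)
  expect_identical(n1$A, n2$A)
  expect_identical(generate_compendium(n1, spec)$M,
                   generate_compendium(n2, spec)$M)
  expect_identical(as.numeric(generate_fitness(n1, spec)),
                   as.numeric(generate_fitness(n2, spec)))
  spec2 <- synthetic_spec(n_genes = 150, n_deletions = 60, k_max = 40,
                          seed = 13)
  expect_false(identical(n1$A, generate_planted_network(spec2)$A))
})

test_that("out-degree draws follow the truncated power law", {
  # gamma large: mass collapses onto K = 1
  spec_steep <- synthetic_spec(n_genes = 200, n_deletions = 100,
                               gamma = 20, k_max = 50, seed = 3)
  expect_gt(mean(sample_outdegrees(spec_steep) == 1), 0.99)
  # draws stay inside the support
  spec <- synthetic_spec(n_genes = 300, n_deletions = 200, gamma = 0.75,
                         k_max = 120, seed = 4)
  k <- sample_outdegrees(spec)
  expect_true(all(k >= 1 & k <= 120))
})

test_that("planted networks have self-edges plus K distinct targets", {
  spec <- synthetic_spec(n_genes = 300, n_deletions = 120, k_max = 100,
                         seed = 6)
  net <- generate_planted_network(spec)
  K <- sample_outdegrees(spec)  # same seed, same draws
  expect_identical(unname(rowSums(net$A)), as.numeric(K + 1))
  self <- net$A[cbind(seq_len(120), seq_len(120))]
  expect_true(all(self == 1L))
  # every deletion has at least one non-self target (K >= 1)
  expect_true(all(rowSums(net$A) >= 2))
})

test_that("dense planting leaves most genes focal-eligible", {
  spec <- synthetic_spec(n_genes = 200, n_deletions = 200, gamma = 0.6,
                         k_max = 150, seed = 8)
  net <- suppressMessages(select_focal_genes(generate_planted_network(spec)))
  # occupancy oracle: P(gene misses all incoming edges) from the realized
  # degree draws, targets uniform over the n-1 non-self genes
  K <- rowSums(net$A) - 1
  p_miss <- prod(1 - K / (spec$n_genes - 1))
  frac_focal <- length(net$focal_genes) / spec$n_deletions
  expect_lt(abs((1 - frac_focal) - p_miss), 0.1)
  expect_gt(frac_focal, 0.9)
})

test_that("zero error rates make thresholding recover the planted network", {
  spec <- synthetic_spec(n_genes = 300, n_deletions = 100, k_max = 80,
                         seed = 21)
  planted <- generate_planted_network(spec)
  comp <- generate_compendium(planted, spec)
  rebuilt <- suppressMessages(build_adjacency(comp))
  expect_identical(rebuilt$A, planted$A)
  # self cells are always significant decreases: filter (ii) removes nothing
  net <- suppressMessages(select_focal_genes(rebuilt))
  expect_equal(net$filter_counts$no_self_decrease, 0L)
  expect_equal(net$filter_counts$unmeasured, 0L)
})

test_that("error rates inject the prescribed edge noise", {
  spec <- synthetic_spec(false_positive_rate = 0.01, seed = 33)
  planted <- generate_planted_network(spec)
  comp <- generate_compendium(planted, spec)
  rebuilt <- suppressMessages(build_adjacency(comp))
  spurious <- sum(rebuilt$A == 1L & planted$A == 0L) / sum(planted$A == 0L)
  expect_lt(abs(spurious - 0.01), 0.003)
  # false negatives knock out roughly the prescribed fraction of edges
  spec_fn <- synthetic_spec(n_genes = 800, n_deletions = 300, k_max = 400,
                            false_negative_rate = 0.1, seed = 34)
  planted_fn <- generate_planted_network(spec_fn)
  comp_fn <- generate_compendium(planted_fn, spec_fn)
  rebuilt_fn <- suppressMessages(build_adjacency(comp_fn))
  n_nonself <- sum(planted_fn$A) - length(planted_fn$deletions)
  lost <- sum(planted_fn$A == 1L & rebuilt_fn$A == 0L) / n_nonself
  expect_lt(abs(lost - 0.1), 0.02)
})

test_that("generated fitness follows the planted degree law", {
  # noiseless arithmetic: K = 9 gives fitness 1 - 0.1 * log10(10) = 0.9
  genes <- sprintf("g%05d", 1:20)
  A <- matrix(0L, 1, 20, dimnames = list(genes[1], genes))
  A[1, 1:10] <- 1L  # self + 9 targets
  net <- new_net_for_test(genes, genes[1], A)
  spec <- synthetic_spec(n_genes = 20, n_deletions = 1, k_max = 15,
                         fitness_slope = -0.1, fitness_noise_sd = 0, seed = 2)
  w <- generate_fitness(net, spec)
  expect_equal(unname(w[[genes[1]]]), 0.9)
  # noiseless generator: regression on log10(count) is near-perfect (the
  # generator's log10(K+1) regressor differs from log10(K) only slightly)
  spec0 <- synthetic_spec(n_genes = 500, n_deletions = 200, k_max = 100,
                          fitness_noise_sd = 0, seed = 9)
  net0 <- generate_planted_network(spec0)
  fit0 <- suppressMessages(fitness_vs_pleiotropy_regression(
    pleiotropy_records(net0), generate_fitness(net0, spec0)))
  expect_gt(fit0$r_squared, 0.99)
  expect_lt(fit0$slope, 0)
  # zero slope: estimated slope within 2 standard errors of 0
  spec_null <- synthetic_spec(n_genes = 500, n_deletions = 200, k_max = 100,
                              fitness_slope = 0, fitness_noise_sd = 0.05,
                              seed = 10)
  net_null <- generate_planted_network(spec_null)
  recs <- pleiotropy_records(net_null)
  w_null <- generate_fitness(net_null, spec_null)
  fitn <- suppressMessages(fitness_vs_pleiotropy_regression(recs, w_null))
  x <- log10(recs$cis_count[recs$cis_count > 0])
  y <- as.numeric(w_null)[match(recs$gene[recs$cis_count > 0],
                                names(w_null))]
  se <- summary(lm(y ~ x))$coefficients[2, 2]
  expect_lt(abs(fitn$slope), 2 * se)
})

test_that("synthetic outputs survive the file round trip", {
  spec <- synthetic_spec(n_genes = 80, n_deletions = 30, k_max = 20,
                         seed = 14)
  net <- generate_planted_network(spec)
  comp <- generate_compendium(net, spec)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_compendium(comp, f)
  back <- suppressMessages(read_expression_compendium(f))
  expect_equal(back$M, comp$M, tolerance = 1e-9)
  w <- generate_fitness(net, spec)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_fitness_table(w, f2)
  expect_equal(as.numeric(read_fitness_table(f2)), as.numeric(w),
               tolerance = 1e-12)
})
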