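# Seeded generator of planted perturbation networks, deleteome-dialect
# expression compendia and deletion-fitness tables. The defaults are the
# scaled-down study conditions used throughout the package's tests: a
# heavy-tailed (truncated power-law) out-degree distribution, a strongly
# negative planted self-effect for every deletion, thresholding that
# recovers the planted adjacency exactly at zero error rates, and fitness
# anti-correlated with out-degree.

#' Specification of a synthetic deleteome-like data set
#'
#' @param n_genes Number of measured genes.
#' @param n_deletions Number of deletion strains (first `n_deletions`
#'   genes are deleted).
#' @param gamma Target exponent of the truncated power-law out-degree
#'   distribution p(K) ~ K^-gamma on 1..k_max.
#' @param k_max Largest non-self out-degree.
#' @param self_effect_m Planted self log2 fold-change (< 0: a deletion
#'   abolishes its own gene's expression).
#' @param edge_effect_mean,edge_effect_sd Location/spread of planted
#'   |M| values on true edges (log2 scale).
#' @param edge_sign_prob_decrease Probability that a planted trans effect
#'   decreases the target's expression.
#' @param false_positive_rate Fraction of non-edge cells made significant.
#' @param false_negative_rate Fraction of planted (non-self) edges pushed
#'   below threshold.
#' @param fitness_slope Slope of fitness on log10(out-degree + 1);
#'   negative values reproduce the fitness-pleiotropy anti-correlation.
#' @param fitness_noise_sd Gaussian noise on fitness.
#' @param seed Integer seed; all generators are bit-reproducible from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 2000, n_deletions = 600,
                           gamma = 0.75, k_max = 1000,
                           self_effect_m = -6,
                           edge_effect_mean = 1.5, edge_effect_sd = 0.5,
                           edge_sign_prob_decrease = 0.5,
                           false_positive_rate = 0,
                           false_negative_rate = 0,
                           fitness_slope = -0.1,
                           fitness_noise_sd = 0.15,
                           seed = 1) {
  stopifnot(n_deletions <= n_genes, k_max < n_genes, gamma > 0,
            self_effect_m < 0,
            false_positive_rate >= 0, false_positive_rate < 1,
            false_negative_rate >= 0, false_negative_rate < 1,
            fitness_noise_sd >= 0, seed == as.integer(seed))
  structure(list(n_genes = as.integer(n_genes),
                 n_deletions = as.integer(n_deletions),
                 gamma = gamma, k_max = as.integer(k_max),
                 self_effect_m = self_effect_m,
                 edge_effect_mean = edge_effect_mean,
                 edge_effect_sd = edge_effect_sd,
                 edge_sign_prob_decrease = edge_sign_prob_decrease,
                 false_positive_rate = false_positive_rate,
                 false_negative_rate = false_negative_rate,
                 fitness_slope = fitness_slope,
                 fitness_noise_sd = fitness_noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

sample_outdegrees_impl <- function(spec, n = spec$n_deletions) {
  k <- seq_len(spec$k_max)
  sample(k, n, replace = TRUE, prob = k^(-spec$gamma))
}

#' Sample out-degrees from a truncated discrete power law
#'
#' Draws `n_deletions` values from p(K) ~ K^-gamma on 1..k_max, seeded
#' from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return Integer vector of out-degrees.
#' @export
sample_outdegrees <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  sample_outdegrees_impl(spec)
}

synthetic_gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Generate a planted perturbation network
#'
#' Each deletion receives its own self-edge plus K uniformly chosen
#' distinct non-self targets, with K drawn from the truncated power law.
#' Focal filters are not pre-applied. Self-effects are stored as
#' `self_effect_m` with a tiny p-value so that downstream focal selection
#' behaves as on thresholded data.
#'
#' @param spec A [synthetic_spec()].
#' @return A `perturbation_network`.
#' @export
generate_planted_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  genes <- synthetic_gene_names(spec$n_genes)
  deletions <- genes[seq_len(spec$n_deletions)]
  K <- sample_outdegrees_impl(spec)
  if (any(K >= spec$n_genes))
    stop("out-degree draw reached n_genes; lower k_max")
  A <- matrix(0L, spec$n_deletions, spec$n_genes,
              dimnames = list(deletions, genes))
  for (i in seq_len(spec$n_deletions)) {
    pool <- seq_len(spec$n_genes)[-i]
    A[i, sample(pool, K[i])] <- 1L
    A[i, i] <- 1L
  }
  self_m <- stats::setNames(rep(spec$self_effect_m, spec$n_deletions),
                            deletions)
  self_p <- stats::setNames(rep(1e-6, spec$n_deletions), deletions)
  new_perturbation_network(genes = genes, deletions = deletions, A = A,
                           thresholds = significance_thresholds(),
                           provenance = "synthetic",
                           self_m = self_m, self_p = self_p)
}

#' Generate an expression compendium realizing a planted network
#'
#' Planted edges receive |M| comfortably above the fold-change cutoff
#' (truncated at 1.1 x log2(fold_change_min)) with sign drawn per spec and
#' p below 0.05; non-edges receive sub-threshold M and p uniform on
#' (0.05, 1]; self cells get the planted self M with a tiny p. A
#' `false_negative_rate` fraction of non-self planted edges is pushed
#' sub-threshold (p above cutoff) and a `false_positive_rate` fraction of
#' non-edge cells is made significant. With both error rates zero,
#' thresholding this compendium reproduces the planted adjacency exactly.
#'
#' @param network A network from [generate_planted_network()].
#' @param spec The matching [synthetic_spec()].
#' @return A `compendium` whose strains delete the network's deletions.
#' @export
generate_compendium <- function(network, spec) {
  stopifnot(inherits(network, "perturbation_network"),
            inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  thr <- network$thresholds
  cutoff <- thr$m_cutoff
  p_max <- thr$p_max
  nd <- length(network$deletions); ng <- length(network$genes)
  n <- nd * ng
  is_edge <- network$A == 1L
  # baseline: sub-threshold noise everywhere
  M <- matrix(stats::rnorm(n, 0, 0.15), nd, ng)
  M <- pmin(pmax(M, -0.9 * cutoff), 0.9 * cutoff)
  P <- matrix(stats::runif(n, p_max + 1e-9, 1), nd, ng)
  # planted edges: clearly significant
  ne <- sum(is_edge)
  mag <- pmax(stats::rnorm(ne, spec$edge_effect_mean, spec$edge_effect_sd),
              1.1 * cutoff)
  sgn <- ifelse(stats::runif(ne) < spec$edge_sign_prob_decrease, -1, 1)
  M[is_edge] <- mag * sgn
  P[is_edge] <- stats::runif(ne, 0, 0.99 * p_max)
  # self cells: planted strong decrease
  self_idx <- cbind(seq_len(nd), match(network$deletions, network$genes))
  M[self_idx] <- spec$self_effect_m
  P[self_idx] <- 1e-6
  # false negatives among non-self planted edges
  if (spec$false_negative_rate > 0) {
    edge_cells <- which(is_edge)
    edge_cells <- setdiff(edge_cells, (self_idx[, 2L] - 1L) * nd +
                            self_idx[, 1L])
    fn <- edge_cells[stats::runif(length(edge_cells)) <
                       spec$false_negative_rate]
    P[fn] <- stats::runif(length(fn), p_max + 1e-9, 1)
  }
  # false positives among non-edge cells
  if (spec$false_positive_rate > 0) {
    non_edge <- which(!is_edge)
    fp <- non_edge[stats::runif(length(non_edge)) <
                     spec$false_positive_rate]
    fmag <- pmax(stats::rnorm(length(fp), spec$edge_effect_mean,
                              spec$edge_effect_sd), 1.1 * cutoff)
    fsgn <- ifelse(stats::runif(length(fp)) < spec$edge_sign_prob_decrease,
                   -1, 1)
    M[fp] <- fmag * fsgn
    P[fp] <- stats::runif(length(fp), 0, 0.99 * p_max)
  }
  dialect <- deleteome_dialect()
  strains <- data.frame(
    strain_id = paste(network$deletions, dialect$default_media,
                      sep = dialect$field_sep),
    deleted_gene = network$deletions,
    media = dialect$default_media,
    stringsAsFactors = FALSE)
  expression_compendium(strains = strains, genes = network$genes,
                        M = M, P = P)
}

#' Generate deletion fitness anti-correlated with out-degree
#'
#' fitness(d) = 1 + fitness_slope * log10(K_d + 1) + N(0, fitness_noise_sd)
#' where K_d is the deletion's non-self out-degree; a negative slope
#' reproduces the fitness-pleiotropy anti-correlation.
#'
#' @param network A `perturbation_network`.
#' @param spec The matching [synthetic_spec()].
#' @return A `fitness_table` over the network's deletions.
#' @export
generate_fitness <- function(network, spec) {
  stopifnot(inherits(network, "perturbation_network"),
            inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  K <- rowSums(network$A) - self_cell(network)
  w <- 1 + spec$fitness_slope * log10(K + 1) +
    stats::rnorm(length(K), 0, spec$fitness_noise_sd)
  fitness_table(stats::setNames(w, network$deletions))
}
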