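# Out-degree topology (power-law fit) and deletion-fitness integration.

#' Out-degree histogram of a perturbation network
#'
#' Counts deletions by out-degree K (row sum of the adjacency matrix).
#' Following the network convention here, K includes the self-edge by
#' default; `include_self = FALSE` subtracts it.
#'
#' @param network A `perturbation_network`.
#' @param include_self Count the self-edge in K?
#' @return Named integer vector mapping each K in `0:max(K)` to its count
#'   (zero-count K values included).
#' @export
outdegree_histogram <- function(network, include_self = TRUE) {
  stopifnot(inherits(network, "perturbation_network"))
  K <- rowSums(network$A)
  if (!include_self) K <- K - self_cell(network)
  top <- if (length(K) > 0L) max(K) else 0
  counts <- tabulate(K + 1L, nbins = top + 1L)
  stats::setNames(as.integer(counts), 0:top)
}

#' Least-squares power-law fit of a degree distribution
#'
#' Fits p(K) ~ K^-gamma by ordinary least squares of log10 p(K) on
#' log10 K. Empirical p(K) is count / total over K > 0; zero-degree nodes
#' cannot enter the log-log fit and their count is reported in a message.
#' The slope (hence gamma) and R^2 are invariant to the log base.
#'
#' @param histogram Named numeric vector mapping K to a count (names are
#'   the K values), e.g. from [outdegree_histogram()].
#' @return A `powerlaw_fit`: `gamma` (= minus the slope), `r_squared`,
#'   `n_points` (distinct K used), `slope`, `intercept`.
#' @export
fit_powerlaw <- function(histogram) {
  K <- as.numeric(names(histogram))
  cnt <- as.numeric(histogram)
  if (anyNA(K)) stop("histogram names must be numeric K values")
  n_zero <- sum(cnt[K == 0])
  keep <- K > 0 & cnt > 0
  K <- K[keep]; cnt <- cnt[keep]
  if (length(K) < 3L)
    stop("need at least 3 distinct K > 0 with nonzero counts")
  if (n_zero > 0)
    message(sprintf("%d zero-out-degree nodes excluded from the log-log fit",
                    n_zero))
  p <- cnt / sum(cnt)
  fit <- stats::lm(log10(p) ~ log10(K))
  slope <- unname(stats::coef(fit)[2L])
  # suppress summary.lm's note on numerically perfect fits (noiseless input)
  structure(list(gamma = -slope,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(K),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L])),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit p(K) ~ K^-gamma: gamma = %.4f, R^2 = %.4f (%d points)\n",
              x$gamma, x$r_squared, x$n_points))
  invisible(x)
}

#' Regression of fitness on log10 cis pleiotropy
#'
#' Ordinary least squares of relative fitness on log10 of the cis DE-gene
#' count, over the genes present in both inputs. Genes with a zero count
#' are excluded (log undefined) and their number reported.
#'
#' @param records A [pleiotropy_records()] table.
#' @param fitness A `fitness_table`.
#' @return List with `slope`, `intercept`, `r_squared`, `p` (slope
#'   p-value), `n`.
#' @export
fitness_vs_pleiotropy_regression <- function(records, fitness) {
  stopifnot(inherits(fitness, "fitness_table"))
  w <- as.numeric(fitness)[match(records$gene, names(fitness))]
  keep <- !is.na(w) & records$cis_count > 0
  n_zero <- sum(!is.na(w) & records$cis_count == 0)
  if (n_zero > 0)
    message(sprintf("%d genes with zero cis count excluded from regression",
                    n_zero))
  if (sum(keep) < 3L)
    stop("need at least 3 genes with fitness and a positive cis count")
  x <- log10(records$cis_count[keep])
  y <- w[keep]
  if (stats::sd(y) == 0)
    return(list(slope = 0, intercept = y[1L], r_squared = 0, p = 1,
                n = sum(keep)))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noiseless input trips summary.lm
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2L, 4L]),
       n = sum(keep))
}

#' Fitness costs of cis vs trans deletions per focal gene
#'
#' Fitness cost is one minus relative fitness (reference = 1); beneficial
#' deletions (fitness > 1) yield negative costs and are retained. Pairs
#' are restricted to focal and trans genes present in both the network and
#' the fitness table; dropped genes are counted in a message.
#'
#' @param network A `perturbation_network` with focal genes selected.
#' @param fitness A `fitness_table`.
#' @return A `fitness_comparison`: `pairs` (focal, trans, cis_cost,
#'   trans_cost) and `per_focal` (focal, cis_cost, median_trans_cost,
#'   n_trans).
#' @export
fitness_cost_pairs <- function(network, fitness) {
  stopifnot(inherits(network, "perturbation_network"),
            inherits(fitness, "fitness_table"))
  if (length(network$focal_genes) == 0L)
    stop("network has no focal genes; run select_focal_genes() first")
  cost <- 1 - as.numeric(fitness)
  names(cost) <- names(fitness)
  fg <- network$focal_genes
  rows <- list(); pf <- list()
  n_focal_nofit <- 0L; n_trans_nofit <- 0L
  for (f in fg) {
    if (!f %in% names(cost)) { n_focal_nofit <- n_focal_nofit + 1L; next }
    tr <- trans_regulators_of(network, f)
    tr_in <- tr[tr %in% names(cost)]
    n_trans_nofit <- n_trans_nofit + length(tr) - length(tr_in)
    if (length(tr_in) == 0L) next
    rows[[f]] <- data.frame(focal = f, trans = tr_in,
                            cis_cost = cost[[f]],
                            trans_cost = unname(cost[tr_in]),
                            stringsAsFactors = FALSE)
    pf[[f]] <- data.frame(focal = f, cis_cost = cost[[f]],
                          median_trans_cost = stats::median(cost[tr_in]),
                          n_trans = length(tr_in),
                          stringsAsFactors = FALSE)
  }
  message(sprintf(paste0("Fitness comparison: %d of %d focal genes usable ",
                         "(%d focal, %d trans deletions lacked fitness)"),
                  length(pf), length(fg), n_focal_nofit, n_trans_nofit))
  structure(list(pairs = do.call(rbind, c(rows, make.row.names = FALSE)),
                 per_focal = do.call(rbind, c(pf, make.row.names = FALSE))),
            class = "fitness_comparison")
}

#' Proportion of comparisons where the cis deletion is costlier
#'
#' Strict inequality; ties count as "not greater".
#'
#' @param comparison A [fitness_cost_pairs()] result.
#' @param mode `"per_pair"` compares each pair's costs; `"per_focal"`
#'   compares the cis cost with the per-focal median trans cost.
#' @return List with `numerator`, `denominator`, `proportion`.
#' @export
proportion_cis_cost_greater <- function(comparison,
                                        mode = c("per_pair", "per_focal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(comparison, "fitness_comparison"))
  tab <- if (mode == "per_pair") comparison$pairs else comparison$per_focal
  if (is.null(tab) || nrow(tab) == 0L) stop("empty fitness comparison")
  num <- if (mode == "per_pair") sum(tab$cis_cost > tab$trans_cost)
         else sum(tab$cis_cost > tab$median_trans_cost)
  list(numerator = as.integer(num), denominator = nrow(tab),
       proportion = num / nrow(tab))
}
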