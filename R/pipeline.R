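# End-to-end orchestration: read or simulate inputs, build and filter the
# network, compute pleiotropy tables, run the statistical contrasts, the
# permutation nulls, the power-law fit and the fitness analyses, and write
# a reproducible report bundle.

#' Configuration for the full pipeline
#'
#' Exactly one of `expression` (a file path read with
#' [read_expression_compendium()]) or `synthetic` (a [synthetic_spec()])
#' must be supplied.
#'
#' @param expression Optional path to an expression compendium file.
#' @param transformed_expression Optional path to a transformed compendium
#'   (e.g. with a slow-growth signature removed); Euclidean distances are
#'   recomputed from it.
#' @param fitness Optional path to a fitness table, or a `fitness_table`.
#'   For synthetic runs fitness is generated from the spec unless
#'   `fitness = FALSE`.
#' @param synthetic Optional [synthetic_spec()].
#' @param thresholds A [significance_thresholds()] object.
#' @param measures Pleiotropy measures to summarize.
#' @param n_permutations,permutation_seed Permutation-study settings (both
#'   schemes are run).
#' @param drop_nonstandard_media Passed to the compendium reader.
#' @param outdir Output directory for the report bundle.
#' @param dialect A [deleteome_dialect()] for file IO.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(expression = NULL, transformed_expression = NULL,
                            fitness = NULL, synthetic = NULL,
                            thresholds = significance_thresholds(),
                            measures = c("count", "parallel_count",
                                         "euclidean"),
                            n_permutations = 20, permutation_seed = 1,
                            drop_nonstandard_media = TRUE,
                            outdir = tempfile("pleionet_run_"),
                            dialect = deleteome_dialect()) {
  if (is.null(expression) == is.null(synthetic))
    stop("supply exactly one of 'expression' (file) or 'synthetic' (spec)")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  measures <- match.arg(measures, several.ok = TRUE)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  structure(list(expression = expression,
                 transformed_expression = transformed_expression,
                 fitness = fitness, synthetic = synthetic,
                 thresholds = thresholds, measures = measures,
                 n_permutations = as.integer(n_permutations),
                 permutation_seed = as.integer(permutation_seed),
                 drop_nonstandard_media = drop_nonstandard_media,
                 outdir = outdir, dialect = dialect),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full perturbation-network pleiotropy pipeline
#'
#' Sequences the analysis end to end: input (read or simulate) ->
#' adjacency -> focal-gene filters -> per-gene and per-pair pleiotropy
#' tables (optionally re-deriving Euclidean distances from a transformed
#' compendium) -> per-focal summaries, one-sided t test and
#' cis-greater proportions per measure -> permutation studies under both
#' null schemes -> out-degree power-law fit -> fitness analyses when a
#' fitness table is available. All tables are written as TSV, the summary
#' as JSON, plus a deterministic run log; rerunning with the same
#' configuration reproduces the bundle byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate and final results.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  note("pleionet %s | R %s.%s", as.character(utils::packageVersion("pleionet")),
       R.version$major, R.version$minor)
  note("thresholds: fold_change_min=%g (%s), p_max=%g",
       config$thresholds$fold_change_min, config$thresholds$scale,
       config$thresholds$p_max)

  fitness_tab <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    note("input: synthetic (n_genes=%d, n_deletions=%d, gamma=%g, k_max=%d, seed=%d)",
         spec$n_genes, spec$n_deletions, spec$gamma, spec$k_max, spec$seed)
    planted <- run_stage("simulate", generate_planted_network(spec))
    compendium <- run_stage("simulate", generate_compendium(planted, spec))
    if (!isFALSE(config$fitness))
      fitness_tab <- run_stage("simulate", generate_fitness(planted, spec))
    jsonlite::write_json(unclass(spec),
                         file.path(config$outdir, "synthetic_spec.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    note("input: %s", config$expression)
    compendium <- run_stage("read", read_expression_compendium(
      config$expression, dialect = config$dialect,
      drop_nonstandard_media = config$drop_nonstandard_media))
  }
  if (is.character(config$fitness))
    fitness_tab <- run_stage("read", read_fitness_table(config$fitness))
  if (inherits(config$fitness, "fitness_table"))
    fitness_tab <- config$fitness
  note("compendium: %d strains x %d genes", nrow(compendium$strains),
       length(compendium$genes))

  network <- run_stage("build_network",
                       build_adjacency(compendium, config$thresholds))
  network <- run_stage("select_focal", select_focal_genes(network))
  note("network: %d edges; focal filters removed %d/%d/%d; %d focal genes",
       sum(network$A), network$filter_counts$no_self_decrease,
       network$filter_counts$unmeasured,
       network$filter_counts$no_trans_regulator,
       length(network$focal_genes))
  write_edge_list(network, file.path(config$outdir, "edges.tsv"))

  records <- run_stage("pleiotropy",
                       pleiotropy_records(network, compendium))
  pairs <- run_stage("pleiotropy", cis_trans_pairs(network, compendium))
  write_tsv(records, file.path(config$outdir, "pleiotropy_records.tsv"))
  write_tsv(pairs, file.path(config$outdir, "cis_trans_pairs.tsv"))
  transformed <- NULL
  if (!is.null(config$transformed_expression)) {
    transformed <- run_stage("read_transformed", read_expression_compendium(
      config$transformed_expression, dialect = config$dialect,
      drop_nonstandard_media = config$drop_nonstandard_media))
    rec_tr <- run_stage("pleiotropy",
                        pleiotropy_records(network, transformed))
    pairs_tr <- run_stage("pleiotropy", cis_trans_pairs(network, transformed))
    write_tsv(rec_tr, file.path(config$outdir,
                                "pleiotropy_records_transformed.tsv"))
    write_tsv(pairs_tr, file.path(config$outdir,
                                  "cis_trans_pairs_transformed.tsv"))
  }

  comparison <- list()
  for (m in config$measures) {
    sm <- run_stage("compare", focal_summaries(pairs, records, measure = m))
    write_tsv(sm, file.path(config$outdir,
                            sprintf("focal_summary_%s.tsv", m)))
    tt <- run_stage("compare", one_sided_difference_test(sm$difference))
    pf <- proportion_cis_greater(sm, "per_focal", m)
    pp <- proportion_cis_greater(pairs, "per_pair", m, records = records)
    comparison[[m]] <- list(t_test = tt, per_focal = pf, per_pair = pp,
                            n_focal = nrow(sm))
    note("measure %s: median difference %.4g, t=%.4g (p=%.3g), cis-greater %d/%d focal, %d/%d pairs",
         m, stats::median(sm$difference), tt$t, tt$p,
         pf$numerator, pf$denominator, pp$numerator, pp$denominator)
  }

  perms <- list()
  perm_rows <- list()
  for (scheme in c("preserve_outdegree", "full_random")) {
    pr <- run_stage("permute", permutation_study(
      network, scheme = scheme, n_permutations = config$n_permutations,
      seed = config$permutation_seed))
    perms[[scheme]] <- pr
    perm_rows[[scheme]] <- data.frame(
      replicate = seq_len(pr$n_permutations), scheme = scheme,
      median_difference = pr$per_permutation_median_difference,
      n_focal = pr$per_permutation_focal_count, stringsAsFactors = FALSE)
    note("permutation %s: replicate medians in [%.4g, %.4g]", scheme,
         min(pr$per_permutation_median_difference),
         max(pr$per_permutation_median_difference))
  }
  write_tsv(do.call(rbind, c(perm_rows, make.row.names = FALSE)),
            file.path(config$outdir, "permutations.tsv"))

  pl_fit <- run_stage("topology",
                      fit_powerlaw(outdegree_histogram(network)))
  note("power law: gamma=%.4f, R^2=%.4f (%d points)", pl_fit$gamma,
       pl_fit$r_squared, pl_fit$n_points)

  fitness_res <- NULL
  if (!is.null(fitness_tab)) {
    reg <- run_stage("fitness",
                     fitness_vs_pleiotropy_regression(records, fitness_tab))
    fc <- run_stage("fitness", fitness_cost_pairs(network, fitness_tab))
    write_tsv(fc$pairs, file.path(config$outdir, "fitness_cost_pairs.tsv"))
    write_tsv(fc$per_focal,
              file.path(config$outdir, "fitness_cost_per_focal.tsv"))
    fitness_res <- list(
      regression = reg,
      per_pair = proportion_cis_cost_greater(fc, "per_pair"),
      per_focal = proportion_cis_cost_greater(fc, "per_focal"))
    note("fitness: slope=%.4g, R^2=%.4g (n=%d); cis costlier %d/%d pairs, %d/%d focal",
         reg$slope, reg$r_squared, reg$n, fitness_res$per_pair$numerator,
         fitness_res$per_pair$denominator, fitness_res$per_focal$numerator,
         fitness_res$per_focal$denominator)
  }

  report <- list(
    thresholds = list(fold_change_min = config$thresholds$fold_change_min,
                      p_max = config$thresholds$p_max,
                      scale = config$thresholds$scale),
    n_strains = nrow(compendium$strains),
    n_genes = length(compendium$genes),
    n_edges = sum(network$A),
    filter_counts = network$filter_counts,
    n_focal_genes = length(network$focal_genes),
    comparison = comparison,
    permutation = lapply(perms, function(p) list(
      scheme = p$scheme, seed = p$seed, n = p$n_permutations,
      median_differences = p$per_permutation_median_difference)),
    powerlaw = list(gamma = pl_fit$gamma, r_squared = pl_fit$r_squared,
                    n_points = pl_fit$n_points),
    fitness = fitness_res)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(list(compendium = compendium, network = network,
                 records = records, pairs = pairs, transformed = transformed,
                 comparison = comparison, permutations = perms,
                 powerlaw = pl_fit, fitness = fitness_res,
                 report = report, outdir = config$outdir))
}

#' Threshold sensitivity sweep
#'
#' Re-runs adjacency construction, focal selection and the per-focal
#' cis-greater proportion over a grid of fold-change and p cutoffs.
#' Relaxing either cutoff can only add edges.
#'
#' @param compendium A `compendium`.
#' @param fc_values Linear fold-change cutoffs to try.
#' @param p_values Adjusted-p cutoffs to try.
#' @param measure Pleiotropy measure for the proportion.
#' @return data.frame with one row per (fold_change, p_max) combination:
#'   `n_edges`, `n_focal`, `cis_greater_numerator`, `denominator`,
#'   `proportion`.
#' @export
threshold_sweep <- function(compendium, fc_values = c(1.5, 1.7, 2),
                            p_values = c(0.01, 0.05, 0.1),
                            measure = "count") {
  grid <- expand.grid(fold_change = fc_values, p_max = p_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    thr <- significance_thresholds(grid$fold_change[i], grid$p_max[i])
    net <- suppressMessages(select_focal_genes(
      build_adjacency(compendium, thr)))
    out <- data.frame(fold_change = grid$fold_change[i],
                      p_max = grid$p_max[i],
                      n_edges = sum(net$A),
                      n_focal = length(net$focal_genes),
                      cis_greater_numerator = NA_integer_,
                      denominator = NA_integer_,
                      proportion = NA_real_)
    if (length(net$focal_genes) > 0L) {
      pairs <- cis_trans_pairs(net, compendium)
      recs <- pleiotropy_records(net, compendium)
      sm <- focal_summaries(pairs, recs, measure = measure)
      pf <- proportion_cis_greater(sm, "per_focal", measure)
      out$cis_greater_numerator <- pf$numerator
      out$denominator <- pf$denominator
      out$proportion <- pf$proportion
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
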