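#' Significance thresholds for differential expression calls
#'
#' A gene is called significantly differentially expressed in a deletion
#' strain when its absolute M value (log2 fold-change) meets the fold-change
#' cutoff and its FDR-adjusted p-value is at most `p_max`. Both
#' inequalities are non-strict. By default the fold-change cutoff is on the
#' linear scale (|M| >= log2(fold_change_min)); `scale = "log2"` applies
#' the cutoff to |M| directly.
#'
#' @param fold_change_min Minimum fold change; must exceed 1 on the linear
#'   scale (or be positive on the log2 scale).
#' @param p_max Maximum adjusted p-value.
#' @param scale Scale on which `fold_change_min` is expressed.
#' @return A `sig_thresholds` object with the derived `m_cutoff`.
#' @export
significance_thresholds <- function(fold_change_min = 1.7, p_max = 0.05,
                                    scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (scale == "linear" && fold_change_min <= 1)
    stop("fold_change_min must exceed 1 on the linear scale")
  if (scale == "log2" && fold_change_min <= 0)
    stop("fold_change_min must be positive on the log2 scale")
  if (p_max < 0 || p_max > 1) stop("p_max must lie in [0,1]")
  m_cutoff <- if (scale == "linear") log2(fold_change_min) else fold_change_min
  structure(list(fold_change_min = fold_change_min, p_max = p_max,
                 scale = scale, m_cutoff = m_cutoff),
            class = "sig_thresholds")
}

#' Is an expression change significant?
#'
#' Vectorized over `m` and `p`. Missing values never produce a call.
#'
#' @param m Log2 fold-change(s).
#' @param p Adjusted p-value(s).
#' @param thresholds A [significance_thresholds()] object.
#' @return Logical vector: `abs(m) >= m_cutoff & p <= p_max`, `FALSE`
#'   wherever either input is missing.
#' @export
is_significant_change <- function(m, p, thresholds = significance_thresholds()) {
  stopifnot(inherits(thresholds, "sig_thresholds"))
  out <- !is.na(m) & !is.na(p) &
    abs(m) >= thresholds$m_cutoff & p <= thresholds$p_max
  out[is.na(out)] <- FALSE
  out
}

new_perturbation_network <- function(genes, deletions, A, thresholds,
                                     provenance, self_m, self_p,
                                     focal_genes = character(0),
                                     filter_counts = NULL) {
  structure(list(genes = genes, deletions = deletions, A = A,
                 focal_genes = focal_genes, thresholds = thresholds,
                 provenance = provenance, self_m = self_m, self_p = self_p,
                 filter_counts = filter_counts),
            class = "perturbation_network")
}

#' Threshold a compendium into a binary directed perturbation network
#'
#' Rows of the adjacency matrix are deleted genes, columns are all measured
#' genes; `A[d, g] = 1` iff deletion of `d` significantly changes the
#' expression of `g` under `thresholds`. An edge therefore points from the
#' deleted gene to the differentially expressed gene. Focal-gene filters
#' are applied separately by [select_focal_genes()].
#'
#' @param compendium A `compendium`.
#' @param thresholds A [significance_thresholds()] object.
#' @return A `perturbation_network` with empty `focal_genes`.
#' @export
build_adjacency <- function(compendium, thresholds = significance_thresholds()) {
  validate_compendium(compendium)
  del <- compendium$strains$deleted_gene
  if (any(is.na(del) | !nzchar(del))) {
    bad <- which(is.na(del) | !nzchar(del))[1L]
    stop(sprintf("deleted gene of strain '%s' is unidentifiable",
                 compendium$strains$strain_id[bad]))
  }
  if (anyDuplicated(del))
    stop("multiple strains delete gene ", del[duplicated(del)][1L],
         "; deduplicate (e.g. with drop_nonstandard_media) before building")
  sig <- is_significant_change(compendium$M, compendium$P, thresholds)
  A <- matrix(0L, nrow(compendium$M), ncol(compendium$M),
              dimnames = list(del, compendium$genes))
  A[sig] <- 1L
  self_col <- match(del, compendium$genes)
  measured <- !is.na(self_col)
  idx <- cbind(which(measured), self_col[measured])
  self_m <- stats::setNames(rep(NA_real_, length(del)), del)
  self_p <- self_m
  self_m[measured] <- compendium$M[idx]
  self_p[measured] <- compendium$P[idx]
  message(sprintf("Built perturbation network: %d deletions x %d genes, %d edges",
                  length(del), length(compendium$genes), sum(A)))
  new_perturbation_network(genes = compendium$genes, deletions = del, A = A,
                           thresholds = thresholds,
                           provenance = "compendium",
                           self_m = self_m, self_p = self_p)
}

#' @export
print.perturbation_network <- function(x, ...) {
  cat(sprintf(paste0("Perturbation network: %d deletions x %d genes, ",
                     "%d edges, %d focal genes\n"),
              length(x$deletions), length(x$genes), sum(x$A),
              length(x$focal_genes)))
  cat(sprintf("Thresholds: fold-change >= %g (%s scale), p <= %g\n",
              x$thresholds$fold_change_min, x$thresholds$scale,
              x$thresholds$p_max))
  invisible(x)
}

#' Apply the focal-gene filters
#'
#' A deleted gene qualifies as a focal gene when (i) its own deletion shows
#' a significant *decrease* of its expression (correct deletion, expressed
#' in wild type), (ii) it is measured on the array, and (iii) at least one
#' other deletion significantly changes its expression (it has a
#' trans-regulator). Filters are applied sequentially — self-decrease among
#' measured genes first, then the unmeasured exclusion, then the
#' trans-regulator requirement — and the count removed at each step is
#' reported. The operation is idempotent.
#'
#' @param network A `perturbation_network`.
#' @param compendium Optional source `compendium`; only consulted when the
#'   network does not already carry the self-effect M/p values.
#' @return The network with `focal_genes` and `filter_counts` filled in.
#' @export
select_focal_genes <- function(network, compendium = NULL) {
  stopifnot(inherits(network, "perturbation_network"))
  d <- network$deletions
  self_m <- network$self_m
  self_p <- network$self_p
  if ((is.null(self_m) || all(is.na(self_m))) && !is.null(compendium)) {
    col <- match(d, compendium$genes)
    row <- match(d, compendium$strains$deleted_gene)
    ok <- !is.na(col)
    self_m <- stats::setNames(rep(NA_real_, length(d)), d)
    self_p <- self_m
    self_m[ok] <- compendium$M[cbind(row[ok], col[ok])]
    self_p[ok] <- compendium$P[cbind(row[ok], col[ok])]
  }
  measured <- d %in% network$genes
  self_ok <- is_significant_change(self_m, self_p, network$thresholds) &
    !is.na(self_m) & self_m < 0
  # filter 1: measured genes lacking a significant self-decrease
  drop1 <- measured & !self_ok
  # filter 2: deleted genes not assayed on the array
  drop2 <- !measured & !drop1
  # filter 3: no trans-regulator among the remaining deletions
  cand <- !drop1 & !drop2
  col <- match(d, network$genes)
  indeg_other <- vapply(seq_along(d), function(i) {
    if (is.na(col[i])) return(0L)
    sum(network$A[-i, col[i]] == 1L)
  }, integer(1))
  drop3 <- cand & indeg_other < 1L
  focal <- d[cand & !drop3]
  counts <- list(no_self_decrease = sum(drop1), unmeasured = sum(drop2),
                 no_trans_regulator = sum(drop3))
  message(sprintf(paste0("Focal-gene filters: %d lacked a significant ",
                         "self-decrease, %d not measured on array, %d had ",
                         "no trans-regulator; %d focal genes retained"),
                  counts$no_self_decrease, counts$unmeasured,
                  counts$no_trans_regulator, length(focal)))
  network$focal_genes <- focal
  network$filter_counts <- counts
  network$self_m <- self_m
  network$self_p <- self_p
  network
}

#' Trans-regulators of a focal gene
#'
#' @param network A `perturbation_network` with focal genes selected.
#' @param focal A focal gene identifier.
#' @return Character vector of deletions `d != focal` with `A[d, focal] = 1`.
#' @export
trans_regulators_of <- function(network, focal) {
  stopifnot(inherits(network, "perturbation_network"))
  if (!focal %in% network$focal_genes)
    stop(sprintf("'%s' is not a focal gene of this network", focal))
  col <- network$A[, focal]
  network$deletions[col == 1L & network$deletions != focal]
}

#' Write a network as an edge-list TSV plus a JSON sidecar
#'
#' The sidecar records thresholds, the focal-gene list and filter counts.
#'
#' @param network A `perturbation_network`.
#' @param path Edge-list output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "perturbation_network"))
  idx <- which(network$A == 1L, arr.ind = TRUE)
  edges <- data.frame(source = network$deletions[idx[, 1L]],
                      target = network$genes[idx[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(thresholds = list(
                 fold_change_min = network$thresholds$fold_change_min,
                 p_max = network$thresholds$p_max,
                 scale = network$thresholds$scale),
               n_edges = sum(network$A),
               focal_genes = network$focal_genes,
               filter_counts = network$filter_counts)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
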