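# Pleiotropy measures: DE-gene counts, nested/parallel decomposition and
# Euclidean distances from wild type in expression space.

self_cell <- function(network) {
  # A[d, d] for measured deletions, 0 otherwise (named integer)
  col <- match(network$deletions, network$genes)
  out <- stats::setNames(integer(length(network$deletions)),
                         network$deletions)
  ok <- !is.na(col)
  out[ok] <- network$A[cbind(which(ok), col[ok])]
  out
}

#' Cis pleiotropy of a deletion
#'
#' Number of genes significantly differentially expressed upon deletion of
#' the focal gene, excluding the focal gene itself.
#'
#' @param network A `perturbation_network`.
#' @param focal A deleted gene identifier.
#' @return Integer count.
#' @export
cis_pleiotropy_count <- function(network, focal) {
  stopifnot(inherits(network, "perturbation_network"))
  if (!focal %in% network$deletions)
    stop(sprintf("'%s' has no deletion strain in this network", focal))
  row <- network$A[match(focal, network$deletions), ]
  self <- if (focal %in% network$genes) row[[focal]] else 0L
  as.integer(sum(row) - self)
}

#' Trans pleiotropy of one (trans-regulator, focal gene) pair
#'
#' Number of genes significantly differentially expressed upon deletion of
#' the trans-regulator, excluding the trans-regulator itself and the focal
#' gene.
#'
#' @param network A `perturbation_network`.
#' @param trans,focal Gene identifiers with `A[trans, focal] = 1`.
#' @return Integer count.
#' @export
trans_pair_pleiotropy_count <- function(network, trans, focal) {
  stopifnot(inherits(network, "perturbation_network"))
  if (!trans %in% network$deletions)
    stop(sprintf("'%s' has no deletion strain in this network", trans))
  row <- network$A[match(trans, network$deletions), ]
  if (!focal %in% network$genes || row[[focal]] != 1L)
    stop(sprintf("(%s -> %s) is not an edge of the network", trans, focal))
  self <- if (trans %in% network$genes) row[[trans]] else 0L
  as.integer(sum(row) - self - 1L)
}

#' Parallel trans pleiotropy (nested effects removed)
#'
#' Targets of the trans-regulator that are *not* significantly changed in
#' the focal gene's own deletion, i.e. the trans effects occurring in
#' parallel to the path through the focal gene.
#'
#' @inheritParams trans_pair_pleiotropy_count
#' @return Integer count, `<=` [trans_pair_pleiotropy_count()].
#' @export
parallel_pleiotropy_count <- function(network, trans, focal) {
  stopifnot(inherits(network, "perturbation_network"))
  if (!focal %in% network$deletions)
    stop(sprintf("'%s' has no deletion strain in this network", focal))
  n_trans <- trans_pair_pleiotropy_count(network, trans, focal)  # validates
  trow <- network$A[match(trans, network$deletions), ]
  frow <- network$A[match(focal, network$deletions), ]
  keep <- trow == 1L & frow == 0L
  drop <- network$genes %in% c(trans, focal)
  as.integer(sum(keep & !drop))
}

#' Euclidean pleiotropy of a deletion
#'
#' Distance of the deletion strain's expression profile from wild type:
#' the square root of the summed squared M values across all measured
#' genes, with no fold-change or significance cutoff. With
#' `coordinates = "log2"` wild type sits at the origin of M-space; with
#' `"linear"` the coordinates are fold changes `2^M` and wild type sits at
#' the all-ones point. Missing measurements and excluded genes contribute
#' nothing to the sum.
#'
#' @param compendium A `compendium`.
#' @param deletion A deleted gene with a strain in the compendium.
#' @param exclude Optional character vector of genes to drop from the sum.
#' @param coordinates Coordinate scale (see above).
#' @return Non-negative real distance.
#' @export
euclidean_pleiotropy <- function(compendium, deletion, exclude = NULL,
                                 coordinates = c("log2", "linear")) {
  coordinates <- match.arg(coordinates)
  validate_compendium(compendium)
  i <- which(compendium$strains$deleted_gene == deletion)
  if (length(i) == 0L)
    stop(sprintf("'%s' has no deletion strain in this compendium", deletion))
  v <- compendium$M[i[1L], ]
  if (!is.null(exclude)) v <- v[!compendium$genes %in% exclude]
  v <- v[!is.na(v)]
  if (coordinates == "linear") v <- 2^v - 1
  sqrt(sum(v^2))
}

#' Per-gene pleiotropy records
#'
#' One row per deletion with its cis DE-gene count and (when a compendium
#' is supplied) its cis Euclidean distance. By default the deleted gene's
#' own extreme self-coordinate is excluded from the distance; set
#' `exclude_self = FALSE` to keep it.
#'
#' @param network A `perturbation_network`.
#' @param compendium Optional matching `compendium` (for distances).
#' @param exclude_self Drop the self-coordinate from cis distances?
#' @param coordinates Coordinate scale for distances, see
#'   [euclidean_pleiotropy()].
#' @return data.frame with columns `gene`, `cis_count`, `cis_euclidean`.
#' @export
pleiotropy_records <- function(network, compendium = NULL,
                               exclude_self = TRUE,
                               coordinates = c("log2", "linear")) {
  coordinates <- match.arg(coordinates)
  stopifnot(inherits(network, "perturbation_network"))
  d <- network$deletions
  counts <- as.integer(rowSums(network$A) - self_cell(network))
  eu <- rep(NA_real_, length(d))
  if (!is.null(compendium)) {
    row <- match(d, compendium$strains$deleted_gene)
    if (anyNA(row)) stop("network deletions missing from compendium: ",
                         d[which(is.na(row))[1L]])
    M <- compendium$M[row, , drop = FALSE]
    if (coordinates == "linear") M <- 2^M - 1
    sq <- rowSums(M^2, na.rm = TRUE)
    if (exclude_self) {
      col <- match(d, compendium$genes)
      ok <- !is.na(col)
      selfsq <- numeric(length(d))
      selfsq[ok] <- M[cbind(which(ok), col[ok])]^2
      selfsq[is.na(selfsq)] <- 0
      sq <- sq - selfsq
    }
    eu <- sqrt(pmax(sq, 0))
  }
  data.frame(gene = d, cis_count = counts, cis_euclidean = eu,
             stringsAsFactors = FALSE)
}

#' All (trans-regulator, focal gene) pairs of a network
#'
#' One row per incoming edge of each focal gene, carrying the pair's trans
#' DE-gene count, its parallel count (nested effects removed), the sign of
#' the trans deletion's effect on the focal gene, and (when a compendium is
#' supplied) the trans Euclidean distance with the trans gene's own and the
#' focal gene's coordinates excluded, mirroring the count definition.
#'
#' @param network A `perturbation_network` with focal genes selected.
#' @param compendium Optional matching `compendium`.
#' @param coordinates Coordinate scale for distances.
#' @return data.frame with columns `focal`, `trans`, `trans_count`,
#'   `parallel_count`, `focal_effect_sign`, `trans_euclidean`.
#' @export
cis_trans_pairs <- function(network, compendium = NULL,
                            coordinates = c("log2", "linear")) {
  coordinates <- match.arg(coordinates)
  stopifnot(inherits(network, "perturbation_network"))
  if (length(network$focal_genes) == 0L)
    stop("network has no focal genes; run select_focal_genes() first")
  d <- network$deletions
  A <- network$A
  fg <- network$focal_genes
  frow_idx <- match(fg, d)
  fcol_idx <- match(fg, network$genes)
  t_idx <- integer(0); f_ord <- integer(0)
  for (k in seq_along(fg)) {
    tr <- which(A[, fcol_idx[k]] == 1L & d != fg[k])
    t_idx <- c(t_idx, tr)
    f_ord <- c(f_ord, rep.int(k, length(tr)))
  }
  if (length(t_idx) == 0L)
    return(data.frame(focal = character(0), trans = character(0),
                      trans_count = integer(0), parallel_count = integer(0),
                      focal_effect_sign = character(0),
                      trans_euclidean = numeric(0), stringsAsFactors = FALSE))
  R <- rowSums(A)
  selfa <- self_cell(network)
  trans_count <- as.integer(R[t_idx] - selfa[t_idx] - 1L)
  # parallel counts via one matrix product:
  # N[t, f] = sum_g A[t, g] * (1 - A[f, g])
  Af <- A[frow_idx, , drop = FALSE]
  N <- tcrossprod(A * 1.0, 1.0 - Af)   # deletions x focal
  tcol <- match(d, network$genes)
  flat <- cbind(t_idx, f_ord)
  # correction for g = trans: A[t,t] * (1 - A[f, t])
  corr_t <- numeric(length(t_idx))
  ok <- !is.na(tcol[t_idx])
  corr_t[ok] <- selfa[t_idx[ok]] *
    (1 - Af[cbind(f_ord[ok], tcol[t_idx[ok]])])
  # correction for g = focal: A[t,f]=1 times (1 - A[f, f])
  self_f <- selfa[frow_idx]
  corr_f <- 1 - self_f[f_ord]
  parallel <- as.integer(round(N[flat] - corr_t - corr_f))
  sign <- rep(NA_character_, length(t_idx))
  eu <- rep(NA_real_, length(t_idx))
  if (!is.null(compendium)) {
    srow <- match(d, compendium$strains$deleted_gene)
    if (anyNA(srow[unique(t_idx)]))
      stop("network deletions missing from compendium")
    M <- compendium$M
    if (coordinates == "linear") M <- 2^M - 1
    gcol <- match(network$genes, compendium$genes)
    m_tf <- M[cbind(srow[t_idx], gcol[fcol_idx[f_ord]])]
    sign <- ifelse(m_tf < 0, "decrease", "increase")
    sq <- rowSums(M^2, na.rm = TRUE)
    self_sq <- numeric(length(d))
    okc <- !is.na(tcol)
    self_sq[okc] <- M[cbind(srow[okc], gcol[tcol[okc]])]^2
    self_sq[is.na(self_sq)] <- 0
    m_tf0 <- m_tf; m_tf0[is.na(m_tf0)] <- 0
    eu <- sqrt(pmax(sq[srow[t_idx]] - self_sq[t_idx] - m_tf0^2, 0))
  }
  data.frame(focal = fg[f_ord], trans = d[t_idx],
             trans_count = trans_count, parallel_count = parallel,
             focal_effect_sign = sign, trans_euclidean = eu,
             stringsAsFactors = FALSE)
}

#' Restrict pairs to trans deletions that decrease focal expression
#'
#' Deletions can only decrease the focal gene's expression in cis, so this
#' restriction makes the trans set directionally comparable.
#'
#' @param network A `perturbation_network` with focal genes.
#' @param compendium Matching `compendium` (required for effect signs).
#' @param pairs Optional precomputed [cis_trans_pairs()] table.
#' @return The subset of pairs with `M[trans, focal] < 0`.
#' @export
focal_decreasing_pairs <- function(network, compendium, pairs = NULL) {
  if (is.null(pairs)) pairs <- cis_trans_pairs(network, compendium)
  if (all(is.na(pairs$focal_effect_sign)))
    stop("pairs carry no effect signs; supply the source compendium")
  pairs[!is.na(pairs$focal_effect_sign) &
          pairs$focal_effect_sign == "decrease", , drop = FALSE]
}
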