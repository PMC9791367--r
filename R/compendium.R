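#' Column dialect for deleteome-style expression tables
#'
#' The expression compendium is stored as a tab-separated table with one row
#' per measured gene and, for every deletion strain, one column of M values
#' (log2 fold-change versus wild type) and one column of adjusted p-values.
#' Strain columns are labelled `<deleted gene><sep><media><sep><M|p>`, e.g.
#' `YML054C::YPD::M`. The dialect object records how those pieces are
#' encoded so that format drift stays isolated from the analysis code.
#'
#' @param gene_column Name of the column holding measured-gene identifiers.
#' @param field_sep Separator between deleted gene, media label and value
#'   kind in strain column names.
#' @param m_label,p_label Tokens marking M and adjusted-p columns.
#' @param default_media Media label treated as the standard rich-media
#'   condition when `drop_nonstandard_media` is requested.
#' @return A `deleteome_dialect` object.
#' @export
deleteome_dialect <- function(gene_column = "systematic_name",
                              field_sep = "::",
                              m_label = "M",
                              p_label = "p",
                              default_media = "YPD") {
  stopifnot(nzchar(gene_column), nzchar(field_sep), m_label != p_label)
  structure(list(gene_column = gene_column, field_sep = field_sep,
                 m_label = m_label, p_label = p_label,
                 default_media = default_media),
            class = "deleteome_dialect")
}

#' Construct an expression compendium
#'
#' Container for per-(strain, gene) matrices of M values (log2 fold-change
#' versus wild type) and Benjamini-Hochberg-adjusted p-values, plus strain
#' metadata. Missing measurements are `NA` and are never dropped silently.
#'
#' @param strains data.frame with columns `strain_id`, `deleted_gene`,
#'   `media` (one row per strain, file order preserved).
#' @param genes Character vector of measured gene identifiers, file order.
#' @param M,P Numeric matrices, strains x genes. `P` entries must lie in
#'   \[0, 1\] or be `NA`.
#' @return A validated `compendium` object.
#' @export
expression_compendium <- function(strains, genes, M, P) {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  genes <- as.character(genes)
  M <- as.matrix(M); P <- as.matrix(P)
  if (nrow(M) == 0L) {
    M <- matrix(numeric(0), 0L, length(genes))
    P <- matrix(numeric(0), 0L, length(genes))
  }
  dimnames(M) <- dimnames(P) <- list(strains$strain_id, genes)
  obj <- structure(list(strains = strains, genes = genes, M = M, P = P),
                   class = "compendium")
  validate_compendium(obj)
}

validate_compendium <- function(x) {
  stopifnot(inherits(x, "compendium"))
  req <- c("strain_id", "deleted_gene", "media")
  if (!all(req %in% names(x$strains)))
    stop("strain table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(x$strains$strain_id))
    stop("duplicated strain identifiers: ",
         paste(unique(x$strains$strain_id[duplicated(x$strains$strain_id)]),
               collapse = ", "))
  if (anyDuplicated(x$genes))
    stop("duplicated gene identifiers: ",
         paste(unique(x$genes[duplicated(x$genes)]), collapse = ", "))
  if (!identical(dim(x$M), dim(x$P)))
    stop("M and P must have identical dimensions")
  if (nrow(x$M) != nrow(x$strains) || ncol(x$M) != length(x$genes))
    stop("matrix dimensions do not match strain/gene lists")
  bad <- which(!is.na(x$P) & (x$P < 0 | x$P > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("adjusted p-value outside [0,1] at strain '%s', gene '%s'",
                 x$strains$strain_id[bad[1L, 1L]], x$genes[bad[1L, 2L]]))
  x
}

#' @export
print.compendium <- function(x, ...) {
  n_meas <- sum(x$strains$deleted_gene %in% x$genes)
  cat(sprintf(paste0("Expression compendium: %d strains x %d genes ",
                     "(%d deleted genes measured on array)\n"),
              nrow(x$strains), length(x$genes), n_meas))
  invisible(x)
}

parse_strain_columns <- function(cols, dialect) {
  parts <- strsplit(cols, dialect$field_sep, fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L)
    stop(sprintf("malformed strain column header '%s' (expected %s)",
                 cols[bad[1L]],
                 paste("gene", "media", "M|p", sep = dialect$field_sep)))
  kind <- vapply(parts, `[[`, "", 3L)
  ok <- kind %in% c(dialect$m_label, dialect$p_label)
  if (!all(ok))
    stop(sprintf("malformed strain column header '%s': value kind '%s'",
                 cols[which(!ok)[1L]], kind[which(!ok)[1L]]))
  data.frame(column = cols,
             deleted_gene = vapply(parts, `[[`, "", 1L),
             media = vapply(parts, `[[`, "", 2L),
             kind = kind, stringsAsFactors = FALSE)
}

check_numeric_column <- function(values, colname) {
  if (is.numeric(values)) return(as.numeric(values))
  num <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(num) & !is.na(values) & values != "NA")
  if (length(bad) > 0L)
    stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                 values[bad[1L]], bad[1L], colname))
  num
}

#' Read a deleteome-style expression compendium
#'
#' @param path Path to a tab-separated expression table.
#' @param dialect A [deleteome_dialect()] describing the column layout.
#' @param drop_nonstandard_media If `TRUE`, strains whose media label
#'   differs from `dialect$default_media` are removed (with a message
#'   reporting retained/dropped counts).
#' @return A `compendium` object; strain and gene order follow the file.
#' @export
read_expression_compendium <- function(path, dialect = deleteome_dialect(),
                                       drop_nonstandard_media = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (!dialect$gene_column %in% names(tab))
    stop(sprintf("gene column '%s' not found in header", dialect$gene_column))
  genes <- as.character(tab[[dialect$gene_column]])
  strain_cols <- setdiff(names(tab), dialect$gene_column)
  if (length(strain_cols) == 0L) {
    comp <- expression_compendium(
      strains = data.frame(strain_id = character(0),
                           deleted_gene = character(0),
                           media = character(0), stringsAsFactors = FALSE),
      genes = genes,
      M = matrix(numeric(0), 0L, length(genes)),
      P = matrix(numeric(0), 0L, length(genes)))
    message(sprintf("Read compendium: 0 strains, %d genes", length(genes)))
    return(comp)
  }
  info <- parse_strain_columns(strain_cols, dialect)
  info$strain_id <- paste(info$deleted_gene, info$media,
                          sep = dialect$field_sep)
  strain_ids <- unique(info$strain_id)
  m_of <- info$column[match(paste0(strain_ids, "\r", dialect$m_label),
                            paste0(info$strain_id, "\r", info$kind))]
  p_of <- info$column[match(paste0(strain_ids, "\r", dialect$p_label),
                            paste0(info$strain_id, "\r", info$kind))]
  if (anyNA(m_of) || anyNA(p_of)) {
    miss <- strain_ids[which(is.na(m_of) | is.na(p_of))[1L]]
    stop(sprintf("strain '%s' lacks a paired %s/%s column", miss,
                 dialect$m_label, dialect$p_label))
  }
  M <- vapply(m_of, function(cn) check_numeric_column(tab[[cn]], cn),
              numeric(nrow(tab)))
  P <- vapply(p_of, function(cn) check_numeric_column(tab[[cn]], cn),
              numeric(nrow(tab)))
  if (nrow(tab) == 1L) { M <- rbind(M); P <- rbind(P) }
  strains <- data.frame(
    strain_id = strain_ids,
    deleted_gene = info$deleted_gene[match(strain_ids, info$strain_id)],
    media = info$media[match(strain_ids, info$strain_id)],
    stringsAsFactors = FALSE)
  n_all <- nrow(strains)
  keep <- rep(TRUE, n_all)
  if (drop_nonstandard_media) keep <- strains$media == dialect$default_media
  comp <- expression_compendium(strains = strains[keep, , drop = FALSE],
                                genes = genes,
                                M = t(M)[keep, , drop = FALSE],
                                P = t(P)[keep, , drop = FALSE])
  message(sprintf("Read compendium: %d of %d strains retained (%d dropped by media filter), %d genes",
                  sum(keep), n_all, n_all - sum(keep), length(genes)))
  comp
}

#' Write an expression compendium in the deleteome dialect
#'
#' Output round-trips through [read_expression_compendium()] under the same
#' dialect; values are written at full double precision.
#'
#' @param compendium A `compendium` object.
#' @param path Output file path.
#' @param dialect A [deleteome_dialect()].
#' @return `path`, invisibly.
#' @export
write_expression_compendium <- function(compendium, path,
                                        dialect = deleteome_dialect()) {
  validate_compendium(compendium)
  cols <- list()
  cols[[dialect$gene_column]] <- compendium$genes
  for (i in seq_len(nrow(compendium$strains))) {
    base <- paste(compendium$strains$deleted_gene[i],
                  compendium$strains$media[i], sep = dialect$field_sep)
    cols[[paste(base, dialect$m_label, sep = dialect$field_sep)]] <-
      format(compendium$M[i, ], digits = 17, trim = TRUE, scientific = NA)
    cols[[paste(base, dialect$p_label, sep = dialect$field_sep)]] <-
      format(compendium$P[i, ], digits = 17, trim = TRUE, scientific = NA)
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE,
                      optional = TRUE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Column dialect for deletion-fitness tables
#'
#' @param gene_column,fitness_column Column names holding the deleted-gene
#'   identifier and the relative fitness (reference strain = 1).
#' @param sep Field separator (`"\t"` or `","`).
#' @return A `fitness_dialect` object.
#' @export
fitness_dialect <- function(gene_column = "gene",
                            fitness_column = "fitness", sep = "\t") {
  structure(list(gene_column = gene_column, fitness_column = fitness_column,
                 sep = sep), class = "fitness_dialect")
}

#' Construct a deletion-fitness table
#'
#' @param values Numeric vector of relative fitness values (reference = 1),
#'   named by deleted-gene identifier.
#' @return A `fitness_table` (named numeric vector).
#' @export
fitness_table <- function(values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("fitness values must be named by gene")
  if (anyDuplicated(names(values)))
    stop("duplicate gene identifier in fitness table: ",
         names(values)[duplicated(names(values))][1L])
  if (any(!is.finite(values)))
    stop("non-finite fitness value for gene ",
         names(values)[which(!is.finite(values))[1L]])
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), class = "fitness_table")
}

#' Read a deletion-fitness table
#'
#' @param path Path to a delimited table with one row per deleted gene.
#' @param dialect A [fitness_dialect()].
#' @return A `fitness_table`.
#' @export
read_fitness_table <- function(path, dialect = fitness_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = dialect$sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (cn in c(dialect$gene_column, dialect$fitness_column))
    if (!cn %in% names(tab))
      stop(sprintf("fitness dialect column '%s' not found in header", cn))
  w <- check_numeric_column(tab[[dialect$fitness_column]],
                            dialect$fitness_column)
  fitness_table(stats::setNames(w, as.character(tab[[dialect$gene_column]])))
}

#' Write a deletion-fitness table
#'
#' @param fitness A `fitness_table`.
#' @param path Output file path.
#' @param dialect A [fitness_dialect()].
#' @return `path`, invisibly.
#' @export
write_fitness_table <- function(fitness, path, dialect = fitness_dialect()) {
  stopifnot(inherits(fitness, "fitness_table"))
  df <- data.frame(names(fitness),
                   format(as.numeric(fitness), digits = 17, trim = TRUE),
                   stringsAsFactors = FALSE)
  names(df) <- c(dialect$gene_column, dialect$fitness_column)
  utils::write.table(df, path, sep = dialect$sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
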