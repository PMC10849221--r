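#' Read an expression table
#'
#' Tab-separated, first column `gene_id`, remaining columns one numeric
#' value per condition/replicate.
#'
#' @param path path to the file.
#' @return A tibble with `gene_id` plus numeric columns.
#' @export
read_expression_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()))
  if (!"gene_id" %in% names(tbl)) stop("expression table needs a gene_id column")
  validate_expression_table(tbl)
  tbl
}

validate_expression_table <- function(tbl) {
  vals <- as.matrix(tbl[setdiff(names(tbl), "gene_id")])
  if (any(vals < 0, na.rm = TRUE)) stop("expression values must be non-negative")
  if (anyDuplicated(tbl$gene_id)) stop("duplicate gene_id in expression table")
  invisible(tbl)
}

#' Average replicate columns into per-condition means
#'
#' @param table expression tibble (`gene_id` + numeric replicate columns).
#' @param grouping either a named character vector `column -> condition` or
#'   a two-column data frame with columns `column` and `condition`.
#' @return An expression tibble with one column per condition holding the
#'   arithmetic mean of its replicates (missing cells excluded).
#' @export
aggregate_replicates <- function(table, grouping) {
  if (is.data.frame(grouping)) {
    grouping <- setNames(grouping$condition, grouping$column)
  }
  value_cols <- setdiff(names(table), "gene_id")
  unassigned <- setdiff(value_cols, names(grouping))
  if (length(unassigned)) {
    stop("columns not assigned to a condition: ", paste(unassigned, collapse = ", "))
  }
  conditions <- unique(unname(grouping[value_cols]))
  out <- tibble::tibble(gene_id = table$gene_id)
  for (cond in conditions) {
    cols <- value_cols[grouping[value_cols] == cond]
    if (length(cols) == 0) stop("condition with zero replicate columns: ", cond)
    out[[cond]] <- rowMeans(as.matrix(table[cols]), na.rm = TRUE)
  }
  out
}

#' Quantile-normalize an expression table across columns
#'
#' Standard quantile normalization: within each column the k-th smallest
#' value is replaced by the mean across columns of the k-th smallest
#' values; per-column rank order is preserved and ties within a column
#' receive the mean of the reference values they span.
#'
#' @param table expression tibble with at least two numeric columns.
#' @return The normalized tibble (same shape).
#' @export
quantile_normalize <- function(table) {
  value_cols <- setdiff(names(table), "gene_id")
  if (length(value_cols) < 2) stop("quantile normalization needs at least 2 columns")
  m <- as.matrix(table[value_cols])
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  out <- table
  out[value_cols] <- as.data.frame(norm)
  out
}

#' Build the PA / PA-per-mRNA response table
#'
#' Inner-joins a single-column protein-abundance table with an aggregated,
#' normalized mRNA table; the mRNA summary is the row mean across condition
#' columns. Genes with zero (or missing) protein or mRNA are removed.
#'
#' @param pa_table tibble `gene_id` plus exactly one abundance column.
#' @param mrna_table tibble `gene_id` plus one column per condition.
#' @return A tibble `gene_id`, `pa`, `mrna`, `pa_per_mrna`.
#' @export
build_response <- function(pa_table, mrna_table) {
  pa_cols <- setdiff(names(pa_table), "gene_id")
  if (length(pa_cols) != 1) stop("pa_table must have exactly one value column")
  mrna_cols <- setdiff(names(mrna_table), "gene_id")
  mrna <- tibble::tibble(
    gene_id = mrna_table$gene_id,
    mrna = rowMeans(as.matrix(mrna_table[mrna_cols]), na.rm = TRUE))
  out <- dplyr::inner_join(
    tibble::tibble(gene_id = pa_table$gene_id, pa = pa_table[[pa_cols]]),
    mrna, by = "gene_id")
  if (nrow(out) == 0) stop("empty join between protein and mRNA tables")
  out <- dplyr::filter(out, !is.na(.data$pa), !is.na(.data$mrna),
                       .data$pa > 0, .data$mrna > 0)
  dplyr::mutate(out, pa_per_mrna = .data$pa / .data$mrna)
}
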