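#' Read an expression matrix and sample metadata from TSV
#'
#' The expression file is tab-separated, UTF-8, '.' decimal: first column the
#' feature id, remaining columns one per sample, header row with sample ids.
#' The metadata file has columns `sample` and `group` (case/control). No CSV
#' autodetection is attempted: anything other than this dialect fails loudly.
#'
#' @param expr_path Path to the expression TSV.
#' @param meta_path Path to the sample metadata TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(expr_path, meta_path) {
  tab <- utils::read.delim(expr_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a feature column plus >=1 sample")
  ids <- as.character(tab[[1]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature ids in ", expr_path, ": ", paste(dup, collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))
    # locate the first offending cell for the error message
    col <- names(tab)[-1][bad[1]]
    raw <- tab[[bad[1] + 1L]]
    row <- which(is.na(suppressWarnings(as.numeric(raw))))[1]
    stop(sprintf("non-numeric value in %s at row %s, sample column '%s'",
                 expr_path, ifelse(is.na(row), "?", row), col))
  }
  rownames(vals) <- ids
  meta <- read_metadata(meta_path)
  missing <- setdiff(colnames(vals), meta$sample)
  if (length(missing))
    stop("samples without a group label in ", meta_path, ": ",
         paste(missing, collapse = ", "))
  groups <- meta$group[match(colnames(vals), meta$sample)]
  expression_matrix(vals, groups)
}

#' Read a sample metadata TSV (columns: sample, group)
#'
#' @param path Path to the TSV.
#' @return Data frame with character columns `sample` and `group`.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(meta)))
    stop("metadata file must have columns 'sample' and 'group'")
  meta$sample <- as.character(meta$sample)
  meta$group <- as.character(meta$group)
  if (!all(meta$group %in% c("case", "control")))
    stop("metadata group labels must be 'case' or 'control'")
  meta
}

#' Write an expression matrix (and optionally its metadata) as TSV
#'
#' @param x An `expr_matrix`.
#' @param expr_path Output path for the expression TSV.
#' @param meta_path Optional output path for the metadata TSV.
#' @param id_col Name for the feature-id column header.
#' @return `expr_path`, invisibly.
#' @export
write_expression <- function(x, expr_path, meta_path = NULL, id_col = "feature") {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(rownames(x$values), x$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1] <- id_col
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- data.frame(sample = colnames(x$values), group = unname(x$groups),
                       stringsAsFactors = FALSE)
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(expr_path)
}

#' Read a miRNA->gene target-prediction table from TSV
#'
#' Two columns, `mirna` and `gene`; duplicate rows are collapsed.
#'
#' @param path Path to the TSV.
#' @return Data frame with character columns `mirna`, `gene`, deduplicated.
#' @export
read_predictions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("mirna", "gene") %in% names(tab)))
    stop("prediction table must have columns 'mirna' and 'gene'")
  tab$mirna <- as.character(tab$mirna)
  tab$gene <- as.character(tab$gene)
  unique(tab[c("mirna", "gene")])
}

#' @rdname read_predictions
#' @param predictions Data frame with columns `mirna`, `gene`.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions[c("mirna", "gene")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic result table as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
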