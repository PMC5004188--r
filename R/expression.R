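#' Construct an expression matrix with group labels
#'
#' The unit of all screening in the pipeline: a features x samples matrix of
#' log2-scale expression values (RMA-style output) together with a case/control
#' label per sample.
#'
#' @param values Numeric matrix, features in rows, samples in columns. Row and
#'   column names are required and must be unique; all values must be finite.
#' @param groups Character vector (or factor) of length `ncol(values)` with
#'   entries `"case"` or `"control"`, in column order.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the matrix) and `groups` (named character vector, names = sample ids).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("case", "case", "control", "control"))
#' em
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (feature) and column (sample) names")
  dup_f <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup_f))
    stop("duplicate feature ids: ", paste(dup_f, collapse = ", "))
  dup_s <- unique(colnames(values)[duplicated(colnames(values))])
  if (length(dup_s))
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries")
  groups <- as.character(groups)
  if (length(groups) != ncol(values))
    stop("`groups` must have one label per sample column")
  if (!all(groups %in% c("case", "control")))
    stop("group labels must be 'case' or 'control'")
  names(groups) <- colnames(values)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d case, %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "case"), sum(x$groups == "control")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by feature and/or sample ids
#'
#' @param x An `expr_matrix`.
#' @param features,samples Character vectors of ids to keep (default: all).
#' @return An `expr_matrix` restricted to the requested ids, in the
#'   requested order.
#' @export
subset_features <- function(x, features = rownames(x$values),
                            samples = colnames(x$values)) {
  stopifnot(inherits(x, "expr_matrix"))
  missing_f <- setdiff(features, rownames(x$values))
  if (length(missing_f))
    stop("unknown feature ids: ", paste(utils::head(missing_f, 5), collapse = ", "))
  missing_s <- setdiff(samples, colnames(x$values))
  if (length(missing_s))
    stop("unknown sample ids: ", paste(utils::head(missing_s, 5), collapse = ", "))
  expression_matrix(x$values[features, samples, drop = FALSE], x$groups[samples])
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray matrices often carry several probes per gene. For each gene the
#' probe with the highest mean expression is retained (ties broken by the
#' lexicographically smallest probe id), and the row is renamed to the gene id.
#'
#' @param x An `expr_matrix` whose rows are probes.
#' @param probe_to_gene Named character vector mapping probe id -> gene id.
#'   Probes absent from the map are dropped with a warning.
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(x, probe_to_gene) {
  stopifnot(inherits(x, "expr_matrix"))
  probes <- rownames(x$values)
  mapped <- probes[probes %in% names(probe_to_gene)]
  if (length(mapped) < length(probes))
    warning(length(probes) - length(mapped), " probes without a gene mapping dropped")
  if (!length(mapped)) stop("no probes could be mapped to genes")
  gene <- probe_to_gene[mapped]
  means <- rowMeans(x$values[mapped, , drop = FALSE])
  ord <- order(gene, -means, mapped)   # per gene: highest mean, then smallest id
  keep <- mapped[ord][!duplicated(gene[ord])]
  out <- x$values[keep, , drop = FALSE]
  rownames(out) <- probe_to_gene[keep]
  expression_matrix(out, x$groups)
}
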