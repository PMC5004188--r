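#' Signed fold change on the log2 scale
#'
#' Computes `log2fc = mean(case) - mean(control)` per feature and reports the
#' linear ratio with the field's signed convention: a ratio R >= 1 is reported
#' as +R, a ratio R < 1 as -1/R, so a gene at 1/7.7 of control level prints as
#' -7.70 rather than 0.13.
#'
#' @param x An [expression_matrix()] (log2-scale values).
#' @return Data frame: `feature`, `log2fc`, `fold_change`.
#' @export
fold_change <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  case <- x$values[, x$groups == "case", drop = FALSE]
  ctrl <- x$values[, x$groups == "control", drop = FALSE]
  if (!ncol(case) || !ncol(ctrl))
    stop("both groups must be present to compute a fold change")
  l2 <- rowMeans(case) - rowMeans(ctrl)
  r <- 2^l2
  data.frame(feature = rownames(x$values),
             log2fc = l2,
             fold_change = ifelse(r >= 1, r, -1 / r),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment `q(i) = min_{j >= i} p(j) m / j` over the sorted
#' p-values, capped at 1 and mapped back to input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of BH-adjusted values, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Partition differential results into up/down/ns calls
#'
#' A feature is called up when `fold_change >= fc_min` with `fdr < fdr_max`
#' and `p < p_max`; down when `fold_change <= -fc_min` under the same
#' statistical gates; otherwise ns. Defaults are the conventional small-array
#' thresholds: 1.5-fold, FDR < 0.1, p < 0.05.
#'
#' @param result Data frame with columns `feature`, `fold_change`, `p`, `fdr`.
#' @param fc_min Minimum signed fold-change magnitude (> 1).
#' @param fdr_max,p_max Statistical gates (both in (0, 1]).
#' @return List: `up` and `down` feature-id vectors (disjoint) and `table`,
#'   the input with a `direction` column in {up, down, ns}.
#' @export
select_de <- function(result, fc_min = 1.5, fdr_max = 0.1, p_max = 0.05) {
  need <- c("feature", "fold_change", "p", "fdr")
  if (!all(need %in% names(result)))
    stop("result must have columns: ", paste(need, collapse = ", "))
  if (!nrow(result)) stop("empty result table")
  if (fc_min <= 0 || fdr_max <= 0 || p_max <= 0)
    stop("thresholds must be positive")
  gate <- result$fdr < fdr_max & result$p < p_max
  direction <- rep("ns", nrow(result))
  direction[gate & result$fold_change >= fc_min] <- "up"
  direction[gate & result$fold_change <= -fc_min] <- "down"
  result$direction <- direction
  list(up = result$feature[direction == "up"],
       down = result$feature[direction == "down"],
       table = result)
}

#' RVM differential expression of a grouped expression matrix
#'
#' One-call wrapper chaining [fit_rvm_prior()] on the pooled variances,
#' [rvm_t_test()], [fold_change()], [bh_fdr()] and [select_de()].
#'
#' @inheritParams select_de
#' @param x An [expression_matrix()].
#' @param prior Optional pre-fitted [fit_rvm_prior()]; fitted from `x` when
#'   `NULL`.
#' @return Data frame of class `de_result`: `feature`, `fold_change`,
#'   `log2fc`, `t`, `df_eff`, `p`, `fdr`, `direction`, with the fitted prior
#'   in `attr(, "prior")`.
#' @examples
#' sim <- simulate_cohort(simulation_config(n_mirna = 200, n_mrna = 200,
#'                                          n_true_pairs = 0, seed = 3))
#' de <- differential_expression(sim$mirna)
#' table(de$direction)
#' @export
differential_expression <- function(x, prior = NULL, fc_min = 1.5,
                                    fdr_max = 0.1, p_max = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(prior)) {
    pv <- pooled_variances(x)
    prior <- fit_rvm_prior(pv$variances, pv$df)
  }
  tt <- rvm_t_test(x, prior)
  fc <- fold_change(x)
  out <- data.frame(feature = tt$feature,
                    fold_change = fc$fold_change,
                    log2fc = fc$log2fc,
                    t = tt$t, df_eff = tt$df_eff, p = tt$p,
                    fdr = bh_fdr(tt$p),
                    stringsAsFactors = FALSE)
  out <- select_de(out, fc_min = fc_min, fdr_max = fdr_max, p_max = p_max)$table
  attr(out, "prior") <- prior
  class(out) <- c("de_result", "data.frame")
  out
}

#' Write / read a differential-expression result table
#'
#' @param de A `de_result` (or compatible data frame).
#' @param path TSV path.
#' @export
write_de_result <- function(de, path) {
  cols <- c("feature", "fold_change", "log2fc", "t", "df_eff", "p", "fdr",
            "direction")
  write_tsv(as.data.frame(de)[cols], path)
}

#' @rdname write_de_result
#' @export
read_de_result <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("feature", "fold_change", "direction")
  if (!all(need %in% names(tab)))
    stop("not a differential-result table: missing ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$feature <- as.character(tab$feature)
  tab
}
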