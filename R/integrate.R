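#' Pearson anti-correlation screen of DE-miRNA x DE-mRNA pairs
#'
#' For every combination of a differentially expressed miRNA and mRNA, the
#' Pearson correlation of their log2 profiles is computed across all matched
#' samples (cases and controls pooled, mirroring a typical 12 + 6 design) with
#' the exact t-transform p-value at n - 2 df. Pairs with negative r below the
#' significance gate are retained: a miRNA that represses its target should
#' track it inversely across subjects regardless of group.
#'
#' @param mirna,mrna [expression_matrix()] objects sharing the same ordered
#'   samples.
#' @param de_mirnas,de_mrnas Either character id vectors or differential
#'   result data frames (with `feature` and `direction`; only up/down rows
#'   are used).
#' @param p_max Correlation p-value gate.
#' @param min_abs_r Optional |r| floor for stricter screening (default 0).
#' @param require_concordant If `TRUE`, additionally require the miRNA and
#'   gene direction calls to be opposite (up/down or down/up). Off by
#'   default: the negative-r gate subsumes it.
#' @return Data frame of candidate pairs: `mirna`, `gene`, `r`, `p`,
#'   `mirna_direction`, `gene_direction` (directions `NA` when plain id
#'   vectors were supplied).
#' @export
pearson_screen <- function(mirna, mrna, de_mirnas, de_mrnas, p_max = 0.05,
                           min_abs_r = 0, require_concordant = FALSE) {
  stopifnot(inherits(mirna, "expr_matrix"), inherits(mrna, "expr_matrix"))
  if (!identical(colnames(mirna$values), colnames(mrna$values)))
    stop("miRNA and mRNA matrices must share the same ordered samples")
  if (!identical(unname(mirna$groups), unname(mrna$groups)))
    stop("miRNA and mRNA matrices must share the same group labels")

  dir_of <- function(de) {
    if (is.data.frame(de)) {
      keep <- de$direction %in% c("up", "down")
      stats::setNames(de$direction[keep], de$feature[keep])
    } else stats::setNames(rep(NA_character_, length(de)), de)
  }
  mdir <- dir_of(de_mirnas); gdir <- dir_of(de_mrnas)
  m_ids <- names(mdir); g_ids <- names(gdir)
  if (!length(m_ids) || !length(g_ids))
    stop("both DE lists must be non-empty")
  missing_m <- setdiff(m_ids, rownames(mirna$values))
  missing_g <- setdiff(g_ids, rownames(mrna$values))
  if (length(missing_m) || length(missing_g))
    stop("DE features absent from their matrix: ",
         paste(utils::head(c(missing_m, missing_g), 5), collapse = ", "))
  n <- ncol(mirna$values)
  if (n < 4) stop("need at least 4 samples for a correlation p-value")

  X <- t(mirna$values[m_ids, , drop = FALSE])
  Y <- t(mrna$values[g_ids, , drop = FALSE])
  sd0_m <- apply(X, 2, stats::sd) == 0
  sd0_g <- apply(Y, 2, stats::sd) == 0
  if (any(sd0_m) || any(sd0_g)) {
    warning(sum(sd0_m) + sum(sd0_g),
            " zero-variance features skipped in correlation screen")
    X <- X[, !sd0_m, drop = FALSE]; Y <- Y[, !sd0_g, drop = FALSE]
    m_ids <- m_ids[!sd0_m]; g_ids <- g_ids[!sd0_g]
    if (!ncol(X) || !ncol(Y))
      return(data.frame(mirna = character(0), gene = character(0),
                        r = numeric(0), p = numeric(0),
                        mirna_direction = character(0),
                        gene_direction = character(0),
                        stringsAsFactors = FALSE))
  }
  R <- stats::cor(X, Y)
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), df = n - 2)
  P[abs(R) >= 1] <- 0

  keep <- which(R < 0 & P < p_max & abs(R) >= min_abs_r, arr.ind = TRUE)
  out <- data.frame(mirna = m_ids[keep[, 1]], gene = g_ids[keep[, 2]],
                    r = R[keep], p = P[keep],
                    mirna_direction = unname(mdir[m_ids[keep[, 1]]]),
                    gene_direction = unname(gdir[g_ids[keep[, 2]]]),
                    stringsAsFactors = FALSE)
  if (require_concordant) {
    conc <- !is.na(out$mirna_direction) & !is.na(out$gene_direction) &
      out$mirna_direction != out$gene_direction
    out <- out[conc, , drop = FALSE]
  }
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict candidate pairs to database-predicted target relationships
#'
#' Keeps exactly the anti-correlated candidates whose (miRNA, gene) pair
#' appears in the prediction table (a TargetScan-style two-column list), the
#' final screening step that turns anti-correlation into a putative direct
#' target relationship.
#'
#' @param candidates Data frame from [pearson_screen()].
#' @param predictions Data frame with columns `mirna`, `gene` (duplicates
#'   collapsed internally).
#' @return The retained pairs, with `predicted = TRUE`, sorted by miRNA then
#'   gene.
#' @export
intersect_predictions <- function(candidates, predictions) {
  predictions <- unique(predictions[c("mirna", "gene")])
  key_c <- paste(candidates$mirna, candidates$gene, sep = "\r")
  key_p <- paste(predictions$mirna, predictions$gene, sep = "\r")
  out <- candidates[key_c %in% key_p, , drop = FALSE]
  out <- out[!duplicated(paste(out$mirna, out$gene, sep = "\r")), , drop = FALSE]
  out$predicted <- rep(TRUE, nrow(out))
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a target-relationship pair list
#'
#' @param pairs Data frame with columns `mirna`, `gene`.
#' @return Named integer vector: `n_mirnas` (distinct miRNAs), `n_genes`
#'   (distinct target genes), `n_relationships` (pairs).
#' @export
summarize_relationships <- function(pairs) {
  c(n_mirnas = length(unique(pairs$mirna)),
    n_genes = length(unique(pairs$gene)),
    n_relationships = nrow(pairs))
}

#' Full target-relationship screen
#'
#' Convenience wrapper: anti-correlation screen of the up/down features in
#' two differential results, then prediction intersection.
#'
#' @inheritParams pearson_screen
#' @param mirna_de,mrna_de `de_result` data frames from
#'   [differential_expression()].
#' @param predictions Prediction table (`mirna`, `gene`).
#' @return Pair data frame as from [intersect_predictions()].
#' @export
screen_target_pairs <- function(mirna, mrna, mirna_de, mrna_de, predictions,
                                p_max = 0.05, min_abs_r = 0,
                                require_concordant = FALSE) {
  cand <- pearson_screen(mirna, mrna, mirna_de, mrna_de, p_max = p_max,
                         min_abs_r = min_abs_r,
                         require_concordant = require_concordant)
  intersect_predictions(cand, predictions)
}
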