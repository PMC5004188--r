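#' Relative expression by the 2^-ddCt method
#'
#' Per subject, `dCt = Ct_target - Ct_reference` (normalisation to a
#' reference transcript such as U6 or GAPDH); `ddCt` subtracts the mean dCt
#' of the calibrator group (typically the normal controls); relative
#' expression is `2^-ddCt`, so a subject matching the calibrator average is
#' exactly 1.
#'
#' @param ct Data frame with columns `subject`, `group`, `ct_target`,
#'   `ct_reference` (cycle numbers, finite and positive).
#' @param calibrator_group Group label used as calibrator (must be non-empty).
#' @return The input with added columns `dct`, `ddct`, `relative_expression`.
#' @examples
#' ct <- data.frame(subject = c("p1", "c1"), group = c("case", "control"),
#'                  ct_target = c(25, 24), ct_reference = c(20, 20))
#' ddct_relative_expression(ct, "control")
#' @export
ddct_relative_expression <- function(ct, calibrator_group = "control") {
  need <- c("subject", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  vals <- c(ct$ct_target, ct$ct_reference)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Ct values must be finite and > 0")
  cal <- ct$group == calibrator_group
  if (!any(cal)) stop("calibrator group '", calibrator_group, "' is empty")
  ct$dct <- ct$ct_target - ct$ct_reference
  ct$ddct <- ct$dct - mean(ct$dct[cal])
  ct$relative_expression <- 2^(-ct$ddct)
  ct
}

#' Pearson or Spearman correlation with t-transform p-value
#'
#' Pearson is the standard product-moment coefficient; Spearman applies the
#' same computation to average ranks (ties averaged). Both use the exact
#' two-sided t transform `t = r sqrt((n-2)/(1-r^2))` at n - 2 df for the
#' p-value (p = 0 when |r| = 1).
#'
#' @param x,y Numeric vectors of equal length >= 4, neither constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  if (method == "spearman") {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, method = method)
}

#' Two-sample t-test or one-way ANOVA group comparison
#'
#' `two_sample_t` is the pooled-variance (Student) test, two-sided; Welch is
#' available via `var_equal = FALSE`. `one_way_anova` is the classical F test
#' with (k - 1, N - k) df.
#'
#' @param values Numeric response vector.
#' @param groups Group label per observation; >= 2 groups, each with >= 2
#'   observations.
#' @param design `"two_sample_t"` (exactly 2 groups) or `"one_way_anova"`.
#' @param var_equal Pooled (TRUE, default) or Welch t-test.
#' @return List with `statistic` (t or F), `p`, `df`, `design`.
#' @export
compare_groups <- function(values, groups,
                           design = c("two_sample_t", "one_way_anova"),
                           var_equal = TRUE) {
  design <- match.arg(design)
  groups <- as.factor(as.character(groups))
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2)) stop("every group needs at least 2 observations")
  if (design == "two_sample_t") {
    if (length(sizes) != 2) stop("two_sample_t needs exactly 2 groups")
    if (var_equal) {
      x <- values[groups == levels(groups)[1]]
      y <- values[groups == levels(groups)[2]]
      n1 <- length(x); n2 <- length(y)
      d <- n1 + n2 - 2
      s2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / d
      diff <- mean(x) - mean(y)
      if (s2 == 0) {
        # degenerate: identical values within groups
        tstat <- if (diff == 0) 0 else sign(diff) * Inf
      } else {
        tstat <- diff / sqrt(s2 * (1 / n1 + 1 / n2))
      }
      list(statistic = tstat, p = 2 * stats::pt(-abs(tstat), d), df = d,
           design = design)
    } else {
      ht <- stats::t.test(values ~ groups, var.equal = FALSE)
      list(statistic = unname(ht$statistic), p = ht$p.value,
           df = unname(ht$parameter), design = design)
    }
  } else {
    ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
    list(statistic = unname(ht$statistic), p = ht$p.value,
         df = unname(ht$parameter), design = design)
  }
}

#' Proliferation inhibition rate from WST-type optical densities
#'
#' Implemented exactly as conventionally printed for viability assays:
#' `(OD_treated(t) - OD_blank) / (OD_untreated(0) - OD_blank)`. Note this is
#' a viability-style ratio (1 = no inhibition, 0 = full suppression); callers
#' wanting a "fraction inhibited" should take 1 minus the value.
#'
#' @param od_treated_t OD of the treated well at the time point.
#' @param od_untreated_0 OD of the untreated well at the original point.
#' @param od_blank Blank-well OD.
#' @return The ratio (vectorised).
#' @export
inhibition_rate <- function(od_treated_t, od_untreated_0, od_blank) {
  denom <- od_untreated_0 - od_blank
  if (any(denom <= 0)) stop("untreated minus blank OD must be positive")
  (od_treated_t - od_blank) / denom
}

#' Relative mean fluorescence intensity
#'
#' Antigen-stain MFI divided by the isotype-matched negative-control MFI.
#'
#' @param mfi_stain Stain MFI (>= 0).
#' @param mfi_isotype Isotype-control MFI (> 0).
#' @return The ratio (vectorised).
#' @export
rmfi <- function(mfi_stain, mfi_isotype) {
  if (any(mfi_isotype <= 0)) stop("isotype MFI must be positive")
  mfi_stain / mfi_isotype
}

#' Read a qRT-PCR Ct table from TSV
#'
#' @param path TSV with columns `subject`, `group`, `ct_target`,
#'   `ct_reference`.
#' @return Data frame with those columns.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("subject", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  tab
}
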