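#' Configuration for a synthetic paired miRNA/mRNA cohort
#'
#' Defaults emulate the study design the pipeline targets: Affymetrix-scale
#' arrays (~2,500 miRNA probes, ~20,000 gene probes) over 12 cases and 6
#' matched controls, with a small set of genuinely repressive miRNA->target
#' relationships planted on a null background.
#'
#' @param n_case,n_control Samples per group.
#' @param n_mirna,n_mrna Number of miRNA / mRNA features.
#' @param n_true_pairs Number of planted repressive miRNA->gene pairs.
#' @param de_mirna_frac Fraction of miRNAs given a planted group effect.
#' @param mirna_logfc_effect Planted miRNA group shift, log2 units.
#' @param repression_slope Negative linear coefficient linking a target gene's
#'   log2 expression to its miRNA's deviation from baseline.
#' @param noise_sd Additive Gaussian noise SD, log2 units.
#' @param baseline_mean_range Range (low, high) for per-feature baseline
#'   means, log2 units.
#' @param one_per_gene If `TRUE` (default) each synthetic gene is targeted by
#'   at most one planted miRNA, keeping recovery metrics unambiguous.
#' @param seed Integer seed; the generator derives one sub-stream per step so
#'   that enlarging one feature class does not perturb draws in another.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(n_case = 12, n_control = 6,
                              n_mirna = 2500, n_mrna = 20000,
                              n_true_pairs = 50,
                              de_mirna_frac = 0.02,
                              mirna_logfc_effect = 1.5,
                              repression_slope = -0.8,
                              noise_sd = 0.3,
                              baseline_mean_range = c(4, 12),
                              one_per_gene = TRUE,
                              seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_true_pairs = as.integer(n_true_pairs),
              de_mirna_frac = de_mirna_frac,
              mirna_logfc_effect = mirna_logfc_effect,
              repression_slope = repression_slope,
              noise_sd = noise_sd,
              baseline_mean_range = as.numeric(baseline_mean_range),
              one_per_gene = isTRUE(one_per_gene),
              seed = as.integer(seed))
  counts <- c("n_case", "n_control", "n_mirna", "n_mrna", "n_true_pairs")
  if (any(vapply(cfg[counts], function(v) is.na(v) || v < 0, logical(1))))
    stop("all counts must be non-negative")
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd <= 0)
    stop("noise_sd must be > 0")
  if (!is.finite(cfg$repression_slope) || cfg$repression_slope >= 0)
    stop("repression_slope must be < 0")
  if (cfg$de_mirna_frac < 0 || cfg$de_mirna_frac > 1)
    stop("de_mirna_frac must lie in [0, 1]")
  if (length(cfg$baseline_mean_range) != 2 ||
      diff(cfg$baseline_mean_range) < 0)
    stop("baseline_mean_range must be (low, high)")
  if (as.double(cfg$n_true_pairs) > as.double(cfg$n_mirna) * cfg$n_mrna)
    stop("n_true_pairs exceeds the number of possible miRNA-gene pairs")
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic per-step sub-seed: keeps independent RNG streams per
# generation step while staying below .Machine$integer.max.
.stream_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 1000003) * 2011 + k)
}

# sample() that never treats a length-1 vector as 1:n
.resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Simulate a paired miRNA/mRNA cohort with planted repression
#'
#' miRNA values are drawn as per-feature baseline + planted group shift (for
#' differentially expressed miRNAs) + Gaussian noise. Each planted target gene
#' follows its miRNA linearly in log2 space:
#' `gene = baseline_g + repression_slope * (mirna - baseline_m) + noise`,
#' which induces both a negative cross-sample Pearson correlation and (when
#' the miRNA carries a group shift) an opposite-direction group effect in the
#' gene. All other features are i.i.d. noise around their baselines.
#'
#' @param config A [simulation_config()].
#' @return List with elements `mirna` and `mrna` (both [expression_matrix()]
#'   sharing the same ordered samples) and `truth`, a list with `true_pairs`
#'   (data frame `mirna`, `gene`), `de_mirnas`, and `de_genes` (genes whose
#'   expression inherits a group effect through a DE miRNA).
#' @examples
#' sim <- simulate_cohort(simulation_config(n_mirna = 50, n_mrna = 200,
#'                                          n_true_pairs = 5, seed = 7))
#' sim$truth$true_pairs
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (cfg$n_case == 0 || cfg$n_control == 0)
    stop("degenerate design: both groups need at least one sample")
  n_samp <- cfg$n_case + cfg$n_control
  samples <- c(sprintf("case%02d", seq_len(cfg$n_case)),
               sprintf("ctrl%02d", seq_len(cfg$n_control)))
  groups <- rep(c("case", "control"), c(cfg$n_case, cfg$n_control))
  mirna_ids <- sprintf("miR-%04d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("GENE%05d", seq_len(cfg$n_mrna))

  # stream 1: miRNA baselines
  set.seed(.stream_seed(cfg$seed, 1L))
  base_m <- stats::runif(cfg$n_mirna, cfg$baseline_mean_range[1],
                         cfg$baseline_mean_range[2])
  # stream 2: DE miRNA selection and effect signs
  set.seed(.stream_seed(cfg$seed, 2L))
  n_de <- round(cfg$de_mirna_frac * cfg$n_mirna)
  de_idx <- if (n_de > 0) sort(sample.int(cfg$n_mirna, n_de)) else integer(0)
  de_sign <- if (n_de > 0) sample(c(-1, 1), n_de, replace = TRUE) else numeric(0)
  # stream 3: planted pair selection
  set.seed(.stream_seed(cfg$seed, 3L))
  if (cfg$n_true_pairs > 0) {
    pool <- if (length(de_idx)) de_idx else seq_len(cfg$n_mirna)
    if (cfg$one_per_gene) {
      if (cfg$n_true_pairs > cfg$n_mrna)
        stop("n_true_pairs exceeds n_mrna with one_per_gene = TRUE")
      pair_m <- .resample(pool, cfg$n_true_pairs, replace = TRUE)
      pair_g <- sample.int(cfg$n_mrna, cfg$n_true_pairs)
    } else {
      pair_m <- integer(0); pair_g <- integer(0)
      seen <- character(0)
      while (length(pair_m) < cfg$n_true_pairs) {
        m <- .resample(pool, 1); g <- sample.int(cfg$n_mrna, 1)
        key <- paste(m, g)
        if (!key %in% seen) {
          seen <- c(seen, key); pair_m <- c(pair_m, m); pair_g <- c(pair_g, g)
        }
      }
    }
  } else {
    pair_m <- integer(0); pair_g <- integer(0)
  }
  # stream 4: miRNA noise
  set.seed(.stream_seed(cfg$seed, 4L))
  noise_m <- matrix(stats::rnorm(cfg$n_mirna * n_samp, sd = cfg$noise_sd),
                    cfg$n_mirna, n_samp)
  effect <- numeric(cfg$n_mirna)
  effect[de_idx] <- de_sign * cfg$mirna_logfc_effect
  X <- base_m + outer(effect, as.numeric(groups == "case")) + noise_m
  dimnames(X) <- list(mirna_ids, samples)

  # stream 5: mRNA baselines
  set.seed(.stream_seed(cfg$seed, 5L))
  base_g <- stats::runif(cfg$n_mrna, cfg$baseline_mean_range[1],
                         cfg$baseline_mean_range[2])
  # stream 6: mRNA noise
  set.seed(.stream_seed(cfg$seed, 6L))
  noise_g <- matrix(stats::rnorm(cfg$n_mrna * n_samp, sd = cfg$noise_sd),
                    cfg$n_mrna, n_samp)
  Y <- base_g + noise_g
  if (length(pair_g)) {
    dev <- X[pair_m, , drop = FALSE] - base_m[pair_m]
    Y[pair_g, ] <- base_g[pair_g] + cfg$repression_slope * dev +
      noise_g[pair_g, , drop = FALSE]
  }
  dimnames(Y) <- list(gene_ids, samples)

  de_mirnas <- mirna_ids[de_idx]
  true_pairs <- data.frame(mirna = mirna_ids[pair_m], gene = gene_ids[pair_g],
                           stringsAsFactors = FALSE)
  de_genes <- unique(true_pairs$gene[true_pairs$mirna %in% de_mirnas])
  list(mirna = expression_matrix(X, groups),
       mrna = expression_matrix(Y, groups),
       truth = list(true_pairs = true_pairs,
                    de_mirnas = de_mirnas,
                    de_genes = de_genes))
}

#' Simulate a target-prediction table (TargetScan stand-in)
#'
#' Each planted true pair enters the table independently with probability
#' `sensitivity`; spurious non-true pairs are added at `false_pair_rate`
#' times the true-pair count, sampled uniformly without duplicates.
#'
#' @param truth Ground-truth list from [simulate_cohort()].
#' @param all_mirnas,all_genes Full feature id vectors (non-empty).
#' @param sensitivity Inclusion probability for each true pair.
#' @param false_pair_rate Spurious pairs per true pair.
#' @param seed Integer seed.
#' @return Data frame with character columns `mirna`, `gene`; no duplicates.
#' @export
simulate_predictions <- function(truth, all_mirnas, all_genes,
                                 sensitivity = 0.8, false_pair_rate = 0.2,
                                 seed = 1L) {
  if (!length(all_mirnas) || !length(all_genes))
    stop("all_mirnas and all_genes must be non-empty")
  if (sensitivity < 0 || sensitivity > 1 || false_pair_rate < 0)
    stop("sensitivity must lie in [0,1] and false_pair_rate be >= 0")
  tp <- truth$true_pairs
  set.seed(.stream_seed(seed, 11L))
  keep <- if (nrow(tp)) stats::runif(nrow(tp)) < sensitivity else logical(0)
  out <- tp[keep, , drop = FALSE]
  n_false <- round(false_pair_rate * nrow(tp))
  if (n_false > 0) {
    true_key <- paste(tp$mirna, tp$gene)
    seen <- character(0)
    fm <- character(0); fg <- character(0)
    while (length(fm) < n_false) {
      m <- .resample(all_mirnas, 1); g <- .resample(all_genes, 1)
      key <- paste(m, g)
      if (!key %in% true_key && !key %in% seen) {
        seen <- c(seen, key); fm <- c(fm, m); fg <- c(fg, g)
      }
    }
    out <- rbind(out, data.frame(mirna = fm, gene = fg, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  unique(out)
}

#' Simulate pathway/GO-style gene-set collections
#'
#' Produces `n_sets` uniformly sampled gene sets over the given universe. If
#' `planted_set_genes` is non-empty the first set is guaranteed to contain all
#' of them (padded with random genes up to a size within `size_range` when
#' possible), making it detectably enriched for a target list drawn from the
#' planted genes.
#'
#' @param all_genes Universe of gene ids.
#' @param n_sets Number of sets (0 gives an empty collection).
#' @param size_range Integer (min, max) set sizes; max must not exceed the
#'   universe size.
#' @param planted_set_genes Genes forced into the first set (may be empty).
#' @param seed Integer seed.
#' @param prefix Set-id prefix (e.g. `"PATH"` or `"GO"`).
#' @return A [geneset_collection()].
#' @export
simulate_genesets <- function(all_genes, n_sets = 30, size_range = c(10, 100),
                              planted_set_genes = character(0), seed = 1L,
                              prefix = "SET") {
  if (!length(all_genes)) stop("all_genes must be non-empty")
  size_range <- as.integer(size_range)
  if (max(size_range) > length(all_genes))
    stop("maximum set size exceeds the universe")
  if (n_sets == 0)
    return(geneset_collection(list(), universe = all_genes))
  bad <- setdiff(planted_set_genes, all_genes)
  if (length(bad))
    stop("planted_set_genes not in universe: ", paste(bad, collapse = ", "))
  set.seed(.stream_seed(seed, 21L))
  sizes <- .resample(seq(size_range[1], size_range[2]), n_sets, replace = TRUE)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i == 1 && length(planted_set_genes)) {
      pad <- max(0, sizes[1] - length(planted_set_genes))
      filler <- .resample(setdiff(all_genes, planted_set_genes),
                          min(pad, length(all_genes) - length(planted_set_genes)))
      sets[[i]] <- unique(c(planted_set_genes, filler))
    } else {
      sets[[i]] <- .resample(all_genes, sizes[i])
    }
  }
  names(sets) <- sprintf("%s_%03d", prefix, seq_len(n_sets))
  geneset_collection(sets, universe = all_genes,
                     descriptions = sprintf("simulated gene set %d", seq_len(n_sets)))
}
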