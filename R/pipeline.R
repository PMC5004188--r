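#' Configure an end-to-end integration run
#'
#' A run either simulates its cohort (pass a [simulation_config()] as
#' `simulate`) or reads the five standard inputs from files. All module
#' thresholds are collected here so a run is fully described by one object.
#'
#' @param out_dir Output directory for all intermediates and the report.
#' @param simulate Optional [simulation_config()]; when supplied, the cohort,
#'   prediction table and gene-set collections are generated and written
#'   under `out_dir/inputs`.
#' @param inputs Named list of paths (`mirna_expr`, `mirna_meta`,
#'   `mrna_expr`, `mrna_meta`, `predictions`, `pathway_gmt`, `go_gmt`);
#'   required when `simulate` is NULL.
#' @param fc_min,fdr_max,p_max Differential-expression gates.
#' @param corr_p_max Anti-correlation screen p gate.
#' @param enrich_p_cut Enrichment significance tier.
#' @param enrich_use_fdr Use the FDR tier for the `enriched` flag.
#' @param min_degree,hub_degree Regulator / hub degree calls.
#' @param weight_mode Network edge weighting, `"binary"` or `"abs_r"`.
#' @param sensitivity,false_pair_rate Prediction-table generator settings
#'   (simulation mode only).
#' @param n_pathway_sets,n_go_sets Simulated collection sizes (simulation
#'   mode only).
#' @param seed Integer seed for all simulated inputs.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, inputs = NULL,
                            fc_min = 1.5, fdr_max = 0.1, p_max = 0.05,
                            corr_p_max = 0.05, enrich_p_cut = 0.05,
                            enrich_use_fdr = FALSE,
                            min_degree = 4, hub_degree = 10,
                            weight_mode = "binary",
                            sensitivity = 0.8, false_pair_rate = 0.2,
                            n_pathway_sets = 30, n_go_sets = 60,
                            seed = 1L) {
  if (is.null(simulate)) {
    need <- c("mirna_expr", "mirna_meta", "mrna_expr", "mrna_meta",
              "predictions", "pathway_gmt", "go_gmt")
    if (is.null(inputs) || !all(need %in% names(inputs)))
      stop("without `simulate`, `inputs` must name: ",
           paste(need, collapse = ", "))
  } else stopifnot(inherits(simulate, "sim_config"))
  if (fc_min <= 1) stop("fc_min must exceed 1")
  probs <- c(fdr_max = fdr_max, p_max = p_max, corr_p_max = corr_p_max,
             enrich_p_cut = enrich_p_cut)
  if (any(probs <= 0 | probs > 1))
    stop("probability thresholds must lie in (0, 1]")
  if (min_degree < 1 || hub_degree < min_degree)
    stop("need min_degree >= 1 and hub_degree >= min_degree")
  weight_mode <- match.arg(weight_mode, c("binary", "abs_r"))
  structure(list(out_dir = out_dir, simulate = simulate, inputs = inputs,
                 fc_min = fc_min, fdr_max = fdr_max, p_max = p_max,
                 corr_p_max = corr_p_max, enrich_p_cut = enrich_p_cut,
                 enrich_use_fdr = enrich_use_fdr,
                 min_degree = min_degree, hub_degree = hub_degree,
                 weight_mode = weight_mode,
                 sensitivity = sensitivity, false_pair_rate = false_pair_rate,
                 n_pathway_sets = n_pathway_sets, n_go_sets = n_go_sets,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, quiet, expr) {
  if (!quiet) message("[", name, "] running")
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full miRNA-mRNA integration pipeline
#'
#' Chains simulate (or load) -> differential expression -> anti-correlation
#' and prediction screening -> direction-stratified pathway/GO enrichment ->
#' bipartite network and regulated-pathway records, writing every
#' intermediate TSV, a summary table and a machine-readable JSON manifest to
#' `config$out_dir`. Identical config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage log lines (written to stderr).
#' @return Invisibly, a list with the main in-memory results: `mirna_de`,
#'   `mrna_de`, `pairs`, `pair_summary`, `enrichment` (pathway/GO, up/down),
#'   `network`, `regulators`, `regulated_pathways`, `key_targets`, `summary`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  in_dir <- file.path(out, "inputs")

  dat <- .stage("inputs", quiet, {
    if (!is.null(config$simulate)) {
      dir.create(in_dir, showWarnings = FALSE)
      sim <- simulate_cohort(config$simulate)
      preds <- simulate_predictions(
        sim$truth, rownames(sim$mirna$values), rownames(sim$mrna$values),
        sensitivity = config$sensitivity,
        false_pair_rate = config$false_pair_rate, seed = config$seed)
      genes <- rownames(sim$mrna$values)
      pathway <- simulate_genesets(genes, n_sets = config$n_pathway_sets,
                                   size_range = c(20, 200),
                                   planted_set_genes = sim$truth$de_genes,
                                   seed = config$seed, prefix = "PATH")
      go <- simulate_genesets(genes, n_sets = config$n_go_sets,
                              size_range = c(10, 150),
                              planted_set_genes = sim$truth$de_genes,
                              seed = config$seed + 1L, prefix = "GO")
      write_expression(sim$mirna, file.path(in_dir, "mirna_expr.tsv"),
                       file.path(in_dir, "samples.tsv"))
      write_expression(sim$mrna, file.path(in_dir, "mrna_expr.tsv"))
      write_predictions(preds, file.path(in_dir, "predictions.tsv"))
      write_gmt(pathway, file.path(in_dir, "pathway.gmt"))
      write_gmt(go, file.path(in_dir, "go.gmt"))
      write_tsv(sim$truth$true_pairs, file.path(in_dir, "true_pairs.tsv"))
      list(mirna = sim$mirna, mrna = sim$mrna, predictions = preds,
           pathway = pathway, go = go, truth = sim$truth)
    } else {
      mirna <- read_expression(config$inputs$mirna_expr, config$inputs$mirna_meta)
      mrna <- read_expression(config$inputs$mrna_expr, config$inputs$mrna_meta)
      list(mirna = mirna, mrna = mrna,
           predictions = read_predictions(config$inputs$predictions),
           pathway = read_gmt(config$inputs$pathway_gmt,
                              universe = rownames(mrna$values)),
           go = read_gmt(config$inputs$go_gmt,
                         universe = rownames(mrna$values)),
           truth = NULL)
    }
  })

  de <- .stage("diffexpr", quiet, {
    mirna_de <- differential_expression(dat$mirna, fc_min = config$fc_min,
                                        fdr_max = config$fdr_max,
                                        p_max = config$p_max)
    mrna_de <- differential_expression(dat$mrna, fc_min = config$fc_min,
                                       fdr_max = config$fdr_max,
                                       p_max = config$p_max)
    write_de_result(mirna_de, file.path(out, "mirna_de.tsv"))
    write_de_result(mrna_de, file.path(out, "mrna_de.tsv"))
    list(mirna = mirna_de, mrna = mrna_de)
  })

  pairs <- .stage("integrate", quiet, {
    if (!nrow(dat$predictions)) stop("prediction table is empty")
    p <- screen_target_pairs(dat$mirna, dat$mrna, de$mirna, de$mrna,
                             dat$predictions, p_max = config$corr_p_max)
    write_tsv(p, file.path(out, "pairs.tsv"))
    p
  })
  pair_summary <- summarize_relationships(pairs)

  enr <- .stage("enrich", quiet, {
    pw <- enrich_by_direction(pairs, dat$pathway, p_cut = config$enrich_p_cut,
                              use_fdr = config$enrich_use_fdr)
    go <- enrich_by_direction(pairs, dat$go, p_cut = config$enrich_p_cut,
                              use_fdr = config$enrich_use_fdr)
    write_tsv(pw$up, file.path(out, "pathway_up.tsv"))
    write_tsv(pw$down, file.path(out, "pathway_down.tsv"))
    write_tsv(go$up, file.path(out, "go_up.tsv"))
    write_tsv(go$down, file.path(out, "go_down.tsv"))
    list(pathway = pw, go = go)
  })

  key_targets <- .stage("key_targets", quiet, {
    kt <- key_target_overlap(rbind(enr$pathway$up, enr$pathway$down),
                             rbind(enr$go$up, enr$go$down), pairs,
                             dat$pathway, dat$go)
    writeLines(kt, file.path(out, "key_targets.txt"))
    kt
  })

  net <- .stage("network", quiet, {
    nw <- build_network(pairs, weight_mode = config$weight_mode)
    write_network(nw, out, prefix = "network")
    regs <- find_regulators(nw, min_degree = config$min_degree,
                            hub_degree = config$hub_degree)
    write_tsv(regs, file.path(out, "regulators.tsv"))
    # regulated pathways joined on an all-target pathway enrichment
    path_all <- fisher_enrichment(unique(pairs$gene), dat$pathway,
                                  p_cut = config$enrich_p_cut,
                                  use_fdr = config$enrich_use_fdr)
    records <- identify_regulated_pathways(pairs, de$mirna, path_all,
                                           dat$pathway)
    write_tsv(records, file.path(out, "regulated_pathways.tsv"))
    list(network = nw, regulators = regs, records = records)
  })

  summary_tab <- data.frame(
    metric = c("n_de_mirna_up", "n_de_mirna_down",
               "n_de_mrna_up", "n_de_mrna_down",
               "n_pair_mirnas", "n_pair_genes", "n_relationships",
               "n_pathway_up_p05", "n_pathway_down_p05",
               "n_go_up_p05", "n_go_down_p05",
               "n_key_targets", "n_regulators", "n_hubs",
               "n_regulated_pathway_records", "n_regulated_pathways"),
    value = c(sum(de$mirna$direction == "up"),
              sum(de$mirna$direction == "down"),
              sum(de$mrna$direction == "up"),
              sum(de$mrna$direction == "down"),
              unname(pair_summary["n_mirnas"]),
              unname(pair_summary["n_genes"]),
              unname(pair_summary["n_relationships"]),
              sum(enr$pathway$up$sig_p05), sum(enr$pathway$down$sig_p05),
              sum(enr$go$up$sig_p05), sum(enr$go$down$sig_p05),
              length(key_targets),
              nrow(net$regulators), sum(net$regulators$hub),
              nrow(net$records),
              length(unique(net$records$pathway))),
    stringsAsFactors = FALSE)
  write_tsv(summary_tab, file.path(out, "summary.tsv"))

  manifest <- list(
    package = "mirpath",
    version = as.character(utils::packageVersion("mirpath")),
    seed = config$seed,
    simulated = !is.null(config$simulate),
    thresholds = config[c("fc_min", "fdr_max", "p_max", "corr_p_max",
                          "enrich_p_cut", "enrich_use_fdr", "min_degree",
                          "hub_degree", "weight_mode")],
    inputs = if (is.null(config$simulate)) config$inputs else
      list(simulation = unclass(config$simulate)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  if (!quiet) message("[done] report written to ", out)
  invisible(list(mirna_de = de$mirna, mrna_de = de$mrna, pairs = pairs,
                 pair_summary = pair_summary, enrichment = enr,
                 network = net$network, regulators = net$regulators,
                 regulated_pathways = net$records,
                 key_targets = key_targets, truth = dat$truth,
                 summary = summary_tab))
}
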