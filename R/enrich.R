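#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (members); names are set ids.
#' @param universe Character vector of background gene ids. Set members are
#'   restricted to the universe; sets left empty by the restriction are
#'   dropped with a warning.
#' @param descriptions Optional character vector of set names/descriptions
#'   (defaults to the set ids).
#' @return Object of class `geneset_collection`: list with `sets` (named list
#'   of unique member vectors), `descriptions` (named), `universe`.
#' @export
geneset_collection <- function(sets, universe, descriptions = NULL) {
  universe <- unique(as.character(universe))
  if (length(sets)) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("sets must have unique names (set ids)")
    if (is.null(descriptions)) descriptions <- names(sets)
    descriptions <- stats::setNames(as.character(descriptions), names(sets))
    sets <- lapply(sets, function(g) intersect(unique(as.character(g)), universe))
    empty <- lengths(sets) == 0
    if (any(empty)) {
      warning(sum(empty), " gene sets empty after restriction to the universe; dropped")
      sets <- sets[!empty]
      descriptions <- descriptions[names(sets)]
    }
  } else {
    sets <- stats::setNames(list(), character(0))
    descriptions <- stats::setNames(character(0), character(0))
  }
  structure(list(sets = sets, descriptions = descriptions, universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `set_id`, `description`,
#' then member gene ids. Blank lines are ignored; duplicate genes within a
#' set are collapsed; a line with fewer than three fields (no genes) is an
#' error reported with its line number.
#'
#' @param path Path to the GMT file.
#' @param universe Optional background; defaults to the union of all members.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  sets <- list(); descs <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": expected set id, description, genes")
    id <- fields[1]
    if (id %in% names(sets)) stop("duplicate set id '", id, "' at line ", i)
    sets[[id]] <- unique(fields[-(1:2)])
    descs[id] <- fields[2]
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  geneset_collection(sets, universe = universe, descriptions = descs)
}

#' @rdname read_gmt
#' @param collection A [geneset_collection()] to write.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Two-tailed Fisher exact p for a 2x2 enrichment table
#'
#' Minimum-likelihood convention (the dominant one in enrichment tools): the
#' p-value is the sum of all hypergeometric point probabilities that do not
#' exceed the probability of the observed table. A relative tolerance of
#' 1e-7 guards floating-point ties, matching `stats::fisher.test`.
#'
#' @param k Observed overlap (target genes in the set); vectorised.
#' @param n Target-list size.
#' @param K Set size in the universe.
#' @param N Universe size.
#' @return Vector of two-tailed p-values.
#' @export
fisher_exact_p <- function(k, n, K, N) {
  ln <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, ln); n <- rep_len(n, ln)
  K <- rep_len(K, ln); N <- rep_len(N, ln)
  if (any(k < 0 | n < 0 | K < 0 | N < 0) ||
      any(n - k < 0 | K - k < 0 | N - n - K + k < 0))
    stop("negative cell in 2x2 table")
  vapply(seq_len(ln), function(i) {
    lo <- max(0, n[i] + K[i] - N[i]); hi <- min(n[i], K[i])
    d <- stats::dhyper(lo:hi, K[i], N[i] - K[i], n[i])
    obs <- d[k[i] - lo + 1]
    min(1, sum(d[d <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

# Pearson chi-squared p (1 df, no continuity correction); NA when a margin
# is empty (expected counts undefined).
.chi2_p <- function(k, n, K, N) {
  k <- as.double(k); n <- as.double(n); K <- as.double(K); N <- as.double(N)
  a <- k; b <- n - k; c <- K - k; d <- N - n - K + k
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  bad <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  stat <- ifelse(bad, NA_real_,
                 N * (a * d - b * c)^2 / (r1 * r2 * c1 * c2))
  ifelse(bad, NA_real_, stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fisher / chi-squared gene-set enrichment of a target list
#'
#' For each set the 2x2 table (k targets in the set, n - k out, K - k set
#' genes not targeted, N - n - K + k remainder) is tested with the two-tailed
#' Fisher exact test and the 1-df Pearson chi-squared test (no continuity
#' correction); BH FDR is computed over the collection from the Fisher p.
#' Significance is emitted on both conventional tiers, p < 0.05 and
#' FDR < 0.05.
#'
#' @param targets Character vector of target gene ids. Duplicates are
#'   collapsed; ids outside the universe are dropped with a warning.
#' @param collection A [geneset_collection()] (universe >= 2 genes).
#' @param p_cut p-value tier for the `enriched` flag.
#' @param use_fdr If `TRUE` the `enriched` flag uses `fdr < p_cut` (strict
#'   mode) instead of `fisher_p < p_cut`.
#' @return Data frame: `set_id`, `name`, `k`, `n`, `K`, `N`, `fisher_p`,
#'   `chi2_p`, `fdr`, `sig_p05`, `sig_fdr05`, `enriched`.
#' @examples
#' coll <- geneset_collection(list(A = c("g1", "g2", "g3")),
#'                            universe = paste0("g", 1:20))
#' fisher_enrichment(c("g1", "g2"), coll)
#' @export
fisher_enrichment <- function(targets, collection, p_cut = 0.05,
                              use_fdr = FALSE) {
  stopifnot(inherits(collection, "geneset_collection"))
  N <- length(collection$universe)
  if (N < 2) stop("universe must contain at least 2 genes")
  targets <- unique(as.character(targets))
  outside <- setdiff(targets, collection$universe)
  if (length(outside)) {
    warning(length(outside), " target ids outside the universe dropped")
    targets <- setdiff(targets, outside)
  }
  n <- length(targets)
  ids <- names(collection$sets)
  k <- vapply(collection$sets, function(s) length(intersect(targets, s)),
              integer(1))
  K <- lengths(collection$sets)
  fisher_p <- if (length(ids)) fisher_exact_p(k, n, K, N) else numeric(0)
  chi2_p <- if (length(ids)) .chi2_p(k, n, K, N) else numeric(0)
  fdr <- if (length(ids)) bh_fdr(fisher_p) else numeric(0)
  out <- data.frame(set_id = ids,
                    name = unname(collection$descriptions[ids]),
                    k = unname(k), n = n, K = unname(K), N = N,
                    fisher_p = unname(fisher_p), chi2_p = unname(chi2_p),
                    fdr = unname(fdr),
                    sig_p05 = unname(fisher_p < 0.05),
                    sig_fdr05 = unname(fdr < 0.05),
                    stringsAsFactors = FALSE)
  out$enriched <- if (use_fdr) out$fdr < p_cut else out$fisher_p < p_cut
  out[order(out$fisher_p, out$set_id), , drop = FALSE]
}

#' Direction-stratified enrichment of miRNA targets
#'
#' Runs [fisher_enrichment()] separately on the deduplicated gene lists
#' targeted by up-regulated and by down-regulated miRNAs, as pathway/GO
#' analyses of miRNA targets are conventionally reported.
#'
#' @param pairs Pair data frame with `gene` and `mirna_direction` columns.
#' @param collection A [geneset_collection()].
#' @param ... Passed to [fisher_enrichment()].
#' @return List with elements `up` and `down`, each an enrichment table.
#' @export
enrich_by_direction <- function(pairs, collection, ...) {
  if (!all(c("gene", "mirna_direction") %in% names(pairs)))
    stop("pairs must carry 'gene' and 'mirna_direction' columns")
  up_genes <- unique(pairs$gene[pairs$mirna_direction == "up"])
  down_genes <- unique(pairs$gene[pairs$mirna_direction == "down"])
  list(up = fisher_enrichment(up_genes, collection, ...),
       down = fisher_enrichment(down_genes, collection, ...))
}

#' Key targets shared by significant pathway and GO categories
#'
#' Returns the target genes that belong to at least one significant pathway
#' set and at least one significant GO set — the genes sitting at the
#' intersection of both annotation systems.
#'
#' @param pathway_results,go_results Enrichment tables from
#'   [fisher_enrichment()] (or a row-bound pair of directional runs).
#' @param pairs Pair data frame (`gene` column) defining the target genes.
#' @param pathway_collection,go_collection The collections the results were
#'   computed on (needed for set membership).
#' @param tier `"p"` to define significance as `sig_p05`, `"fdr"` for
#'   `sig_fdr05`.
#' @return Sorted character vector of gene ids.
#' @export
key_target_overlap <- function(pathway_results, go_results, pairs,
                               pathway_collection, go_collection,
                               tier = c("p", "fdr")) {
  tier <- match.arg(tier)
  col <- if (tier == "p") "sig_p05" else "sig_fdr05"
  members <- function(results, collection) {
    ids <- results$set_id[results[[col]]]
    as.character(unlist(collection$sets[ids], use.names = FALSE))
  }
  targets <- unique(as.character(pairs$gene))
  hit <- intersect(intersect(targets, members(pathway_results, pathway_collection)),
                   members(go_results, go_collection))
  sort(unique(hit))
}
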