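#' Build a bipartite miRNA-gene network from screened pairs
#'
#' One edge per screened target-relationship pair. The adjacency matrix
#' A = [a_ij] has genes in rows and miRNAs in columns; `binary` mode sets
#' a_ij = 1 for every pair, `abs_r` weights each edge by |Pearson r| (degree
#' is a count of incident edges in either mode).
#'
#' @param pairs Data frame with columns `mirna`, `gene` (and `r` for
#'   `weight_mode = "abs_r"`); duplicate pairs are collapsed.
#' @param weight_mode `"binary"` or `"abs_r"`.
#' @return Object of class `mirna_network`: list with sorted `mirna_nodes`,
#'   `gene_nodes`, `adjacency` (genes x miRNAs), and `edges` (data frame
#'   `mirna`, `gene`, `weight`).
#' @export
build_network <- function(pairs, weight_mode = c("binary", "abs_r")) {
  weight_mode <- match.arg(weight_mode)
  pairs <- pairs[!duplicated(paste(pairs$mirna, pairs$gene, sep = "\r")), ,
                 drop = FALSE]
  mirna_nodes <- sort(unique(as.character(pairs$mirna)))
  gene_nodes <- sort(unique(as.character(pairs$gene)))
  A <- matrix(0, length(gene_nodes), length(mirna_nodes),
              dimnames = list(gene_nodes, mirna_nodes))
  w <- if (weight_mode == "binary") rep(1, nrow(pairs)) else {
    if (is.null(pairs$r)) stop("abs_r weighting needs an 'r' column")
    abs(pairs$r)
  }
  if (nrow(pairs))
    A[cbind(as.character(pairs$gene), as.character(pairs$mirna))] <- w
  edges <- data.frame(mirna = as.character(pairs$mirna),
                      gene = as.character(pairs$gene),
                      weight = w, stringsAsFactors = FALSE)
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(mirna_nodes = mirna_nodes, gene_nodes = gene_nodes,
                 adjacency = A, edges = edges, weight_mode = weight_mode),
            class = "mirna_network")
}

#' @export
print.mirna_network <- function(x, ...) {
  cat(sprintf("mirna_network: %d miRNAs, %d genes, %d edges (%s weights)\n",
              length(x$mirna_nodes), length(x$gene_nodes), nrow(x$edges),
              x$weight_mode))
  invisible(x)
}

#' Node degrees of a bipartite network
#'
#' Degree counts incident edges (weight-independent): for a miRNA, the number
#' of genes it reaches; for a gene, the number of miRNAs pointing at it. The
#' two side-sums both equal the edge count.
#'
#' @param network A [build_network()] result.
#' @return Data frame: `node`, `type` ("mirna"/"gene"), `degree`, sorted by
#'   type then descending degree.
#' @export
node_degree <- function(network) {
  stopifnot(inherits(network, "mirna_network"))
  inc <- network$adjacency > 0
  md <- stats::setNames(colSums(inc), network$mirna_nodes)
  gd <- stats::setNames(rowSums(inc), network$gene_nodes)
  out <- data.frame(node = c(names(md), names(gd)),
                    type = rep(c("mirna", "gene"), c(length(md), length(gd))),
                    degree = as.integer(c(md, gd)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$type == "gene", -out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call regulator and hub miRNAs by network degree
#'
#' A miRNA is a regulator when it targets more than `min_degree - 1` genes
#' (default: over 3, i.e. degree >= 4) and a key hub when its degree exceeds
#' `hub_degree` (default: over 10).
#'
#' @param network A [build_network()] result.
#' @param min_degree Minimum degree for the regulator call (default 4).
#' @param hub_degree Degree a hub must exceed (default 10).
#' @return Data frame sorted by descending degree: `mirna`, `degree`, `hub`.
#' @export
find_regulators <- function(network, min_degree = 4, hub_degree = 10) {
  deg <- node_degree(network)
  deg <- deg[deg$type == "mirna" & deg$degree >= min_degree, , drop = FALSE]
  out <- data.frame(mirna = deg$node, degree = deg$degree,
                    hub = deg$degree > hub_degree, stringsAsFactors = FALSE)
  out[order(-out$degree, out$mirna), , drop = FALSE]
}

#' Join pairs with enriched pathways into regulated-pathway records
#'
#' Emits one record per (pair, pathway) combination where the pair's target
#' gene belongs to a significantly enriched pathway, carrying the miRNA's
#' direction ("Up"/"Down") and signed fold change from its differential
#' result. Distinct (miRNA, gene, pathway) triples are the
#' "miRNA-mRNA-regulated pathways" of the analysis.
#'
#' @param pairs Pair data frame (`mirna`, `gene`).
#' @param mirna_de Differential result for miRNAs (`feature`, `fold_change`,
#'   `direction`); every miRNA in `pairs` must be present.
#' @param enriched Enrichment table from [fisher_enrichment()]; rows with
#'   `enriched == TRUE` define the significant pathways.
#' @param collection The [geneset_collection()] the enrichment was run on.
#' @return Data frame sorted by (mirna, gene, pathway): `mirna`, `style`,
#'   `fold_change`, `gene`, `pathway`.
#' @export
identify_regulated_pathways <- function(pairs, mirna_de, enriched, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  missing <- setdiff(unique(pairs$mirna), mirna_de$feature)
  if (length(missing))
    stop("miRNAs missing from the differential results: ",
         paste(missing, collapse = ", "))
  sig <- enriched[enriched$enriched %in% TRUE, , drop = FALSE]
  recs <- list()
  for (i in seq_len(nrow(sig))) {
    members <- collection$sets[[sig$set_id[i]]]
    hit <- pairs[pairs$gene %in% members, c("mirna", "gene"), drop = FALSE]
    if (nrow(hit)) {
      hit$pathway <- sig$name[i]
      recs[[length(recs) + 1]] <- hit
    }
  }
  if (!length(recs))
    return(data.frame(mirna = character(0), style = character(0),
                      fold_change = numeric(0), gene = character(0),
                      pathway = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  idx <- match(out$mirna, mirna_de$feature)
  out$style <- ifelse(mirna_de$direction[idx] == "up", "Up",
                      ifelse(mirna_de$direction[idx] == "down", "Down", "ns"))
  out$fold_change <- mirna_de$fold_change[idx]
  out <- out[c("mirna", "style", "fold_change", "gene", "pathway")]
  out <- out[!duplicated(paste(out$mirna, out$gene, out$pathway, sep = "\r")), ,
             drop = FALSE]
  out <- out[order(out$mirna, out$gene, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a bipartite network to an igraph object
#'
#' @param network A [build_network()] result.
#' @return An `igraph` graph with a logical `type` vertex attribute
#'   (TRUE = gene) and edge `weight`s.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "mirna_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[c("mirna", "gene", "weight")], directed = FALSE,
    vertices = data.frame(
      name = c(network$mirna_nodes, network$gene_nodes),
      type = rep(c(FALSE, TRUE),
                 c(length(network$mirna_nodes), length(network$gene_nodes))),
      stringsAsFactors = FALSE))
  g
}

#' Export a network as edge-list TSV, degree TSV and GraphML
#'
#' @param network A [build_network()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_network <- function(network, dir, prefix = "network") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(edges = file.path(dir, paste0(prefix, "_edges.tsv")),
             degrees = file.path(dir, paste0(prefix, "_degrees.tsv")),
             graphml = file.path(dir, paste0(prefix, ".graphml")))
  write_tsv(network$edges, paths["edges"])
  write_tsv(node_degree(network), paths["degrees"])
  igraph::write_graph(as_igraph(network), paths["graphml"], format = "graphml")
  invisible(paths)
}
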