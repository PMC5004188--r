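#' Published MDS miRNA-gene-pathway associations
#'
#' A small table of dysregulated miRNAs in CD34+ cells of myelodysplastic
#' syndromes, with their signed fold changes (MDS/control), anti-correlated
#' predicted target genes, and the enriched KEGG pathway each target belongs
#' to, as printed in a published integration study of this design. Useful as
#' a realistic fixture for the network module: rebuilding the bipartite
#' network from these rows gives, e.g., degree 7 for miR-19a.
#'
#' @return Data frame: `mirna`, `style` (Up/Down), `fold_change` (signed
#'   ratio), `gene`, `pathway`; one row per miRNA-gene-pathway association.
#' @examples
#' tab <- mds_pathway_table()
#' nw <- build_network(tab)
#' find_regulators(nw)
#' @export
mds_pathway_table <- function() {
  path <- system.file("extdata", "mds_mirna_pathway_table.tsv",
                      package = "mirpath", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
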