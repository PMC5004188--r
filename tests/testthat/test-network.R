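test_that("network rebuilt from the published MDS table has the known degrees", {
  tab <- mds_pathway_table()
  nw <- build_network(tab)
  expect_length(nw$mirna_nodes, 7)
  # 21 distinct genes (TNF is shared by miR-19a and miR-19b), 22 edges
  expect_length(nw$gene_nodes, 21)
  expect_identical(nrow(nw$edges), 22L)

  deg <- node_degree(nw)
  mdeg <- setNames(deg$degree[deg$type == "mirna"],
                   deg$node[deg$type == "mirna"])
  expect_equal(mdeg[["miR-19a"]], 7)
  expect_equal(mdeg[["miR-148a"]], 4)
  expect_equal(mdeg[["miR-195"]], 4)
  expect_equal(mdeg[["miR-145"]], 2)
  expect_equal(mdeg[["miR-19b"]], 2)
  expect_equal(mdeg[["miR-200c"]], 2)
  expect_equal(mdeg[["miR-17"]], 1)
  gdeg <- deg[deg$type == "gene", ]
  expect_equal(gdeg$degree[gdeg$node == "TNF"], 2)

  regs <- find_regulators(nw)
  expect_setequal(regs$mirna, c("miR-19a", "miR-148a", "miR-195"))
  expect_false(any(regs$hub))   # no degree exceeds 10 in this table
  # relaxing the gate returns every connected miRNA
  expect_length(find_regulators(nw, min_degree = 1)$mirna, 7)
})

test_that("degenerate and weighted constructions behave", {
  empty <- build_network(data.frame(mirna = character(0), gene = character(0)))
  expect_identical(nrow(empty$edges), 0L)
  expect_identical(nrow(node_degree(empty)), 0L)
  expect_identical(nrow(find_regulators(empty)), 0L)

  pairs <- data.frame(mirna = c("m1", "m1"), gene = c("g1", "g2"),
                      r = c(-0.837, -0.5), stringsAsFactors = FALSE)
  bin <- build_network(pairs)
  expect_equal(unname(bin$adjacency["g1", "m1"]), 1)
  expect_equal(unname(bin$adjacency["g2", "m1"]), 1)
  wts <- build_network(pairs, weight_mode = "abs_r")
  expect_equal(unname(wts$adjacency["g1", "m1"]), 0.837)
  # degree is weight-independent
  expect_equal(node_degree(wts), node_degree(bin))
  # duplicated pairs collapse to one edge
  dup <- build_network(rbind(pairs, pairs))
  expect_identical(nrow(dup$edges), 2L)
})

test_that("degree sums on both sides equal the edge count (conservation)", {
  set.seed(71)
  for (i in 1:25) {
    n_edge <- sample(1:40, 1)
    pairs <- unique(data.frame(
      mirna = sample(sprintf("m%02d", 1:8), n_edge, replace = TRUE),
      gene = sample(sprintf("g%02d", 1:25), n_edge, replace = TRUE),
      stringsAsFactors = FALSE))
    nw <- build_network(pairs)
    deg <- node_degree(nw)
    expect_equal(sum(deg$degree[deg$type == "mirna"]), nrow(nw$edges))
    expect_equal(sum(deg$degree[deg$type == "gene"]), nrow(nw$edges))
  }
})

test_that("regulated-pathway records join pairs, DE calls and enrichment", {
  tab <- mds_pathway_table()
  pairs <- unique(tab[c("mirna", "gene")])
  de <- data.frame(feature = unique(tab$mirna),
                   fold_change = tab$fold_change[match(unique(tab$mirna), tab$mirna)],
                   direction = tolower(tab$style[match(unique(tab$mirna), tab$mirna)]),
                   stringsAsFactors = FALSE)
  sets <- split(tab$gene, tab$pathway)
  coll <- geneset_collection(sets, universe = unique(tab$gene))
  enr <- fisher_enrichment(unique(tab$gene), coll)
  enr$enriched <- TRUE   # toy enrichment: every pathway significant
  recs <- identify_regulated_pathways(pairs, de, enr, coll)

  # the canonical record: miR-195 (Up, 6.04) targets DLL1 in Notch signaling
  hit <- recs[recs$mirna == "miR-195" & recs$gene == "DLL1", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$style, "Up")
  expect_equal(hit$fold_change, 6.04)
  expect_identical(hit$pathway, "Notch signaling pathway")
  # the full join contains every printed (miRNA, gene, pathway) triple; it
  # may add cross records for genes annotated to more than one pathway
  # (TNF sits in both MAPK signaling and Proteoglycans in cancer), where the
  # printed table lists a single pathway per row
  expect_true(all(paste(tab$mirna, tab$gene, tab$pathway, sep = "|") %in%
                    paste(recs$mirna, recs$gene, recs$pathway, sep = "|")))
  # and every record is a (pair, member-pathway) combination
  for (i in seq_len(nrow(recs))) {
    expect_true(recs$gene[i] %in% coll$sets[[recs$pathway[i]]])
  }

  # no enriched sets -> empty record list
  enr0 <- enr; enr0$enriched <- FALSE
  expect_identical(nrow(identify_regulated_pathways(pairs, de, enr0, coll)), 0L)

  # a gene in two enriched pathways yields two records
  coll2 <- geneset_collection(list(A = "g1", B = "g1"), universe = c("g1", "g2"))
  enr2 <- fisher_enrichment("g1", coll2); enr2$enriched <- TRUE
  de2 <- data.frame(feature = "m1", fold_change = 2, direction = "up",
                    stringsAsFactors = FALSE)
  p2 <- data.frame(mirna = "m1", gene = "g1", stringsAsFactors = FALSE)
  expect_identical(nrow(identify_regulated_pathways(p2, de2, enr2, coll2)), 2L)

  # a pair miRNA missing from the DE table is an error
  expect_error(identify_regulated_pathways(
    data.frame(mirna = "mX", gene = "g1"), de2, enr2, coll2), "missing")

  # removing a non-enriched set never changes the output
  coll3 <- geneset_collection(list(A = "g1", B = "g1", C = "g2"),
                              universe = c("g1", "g2"))
  enr3 <- fisher_enrichment("g1", coll3)
  enr3$enriched <- enr3$set_id %in% c("A", "B")
  expect_equal(identify_regulated_pathways(p2, de2, enr3, coll3),
               identify_regulated_pathways(p2, de2, enr2, coll2))
})

test_that("igraph conversion and file export are consistent", {
  tab <- mds_pathway_table()
  nw <- build_network(tab)
  g <- as_igraph(nw)
  expect_equal(igraph::vcount(g), 7 + 21)
  expect_equal(igraph::ecount(g), 22)
  expect_true(igraph::bipartite_mapping(g)$res)

  dir <- tempfile()
  paths <- write_network(nw, dir)
  expect_true(all(file.exists(paths)))
  edges_back <- read.delim(paths[["edges"]], stringsAsFactors = FALSE)
  expect_equal(nrow(edges_back), 22)
})
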