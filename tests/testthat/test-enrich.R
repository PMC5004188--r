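test_that("two-tailed Fisher p matches enumeration and fisher.test", {
  expect_equal(fisher_exact_p(3, 10, 20, 100), fisher_oracle(3, 10, 20, 100),
               tolerance = 1e-12)
  # cross-check against the independent stats implementation
  tab <- matrix(c(3, 7, 17, 73), 2)
  expect_equal(fisher_exact_p(3, 10, 20, 100),
               fisher.test(tab)$p.value, tolerance = 1e-9)

  set.seed(51)
  for (i in 1:50) {
    N <- sample(10:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(n, K)
    k <- lo + sample.int(hi - lo + 1, 1) - 1

    expect_equal(fisher_exact_p(k, n, K, N), fisher_oracle(k, n, K, N),
                 tolerance = 1e-10)
  }
  expect_error(fisher_exact_p(5, 4, 10, 100), "negative cell")
})

test_that("forced tables give p = 1", {
  # target list = set = universe
  expect_equal(fisher_exact_p(7, 7, 7, 7), 1)
  # empty target list against any set
  expect_equal(fisher_exact_p(0, 0, 10, 50), 1)
})

test_that("chi-squared p agrees with stats and with Fisher asymptotically", {
  # against chisq.test without continuity correction
  k <- 30; n <- 80; K <- 90; N <- 250
  tab <- matrix(c(k, n - k, K - k, N - n - K + k), 2)
  expect_equal(mirpath:::.chi2_p(k, n, K, N),
               chisq.test(tab, correct = FALSE)$p.value, tolerance = 1e-12)
  # all expected cells >= 20: the two tests agree within 0.02
  for (k2 in c(40, 50, 60)) {
    f <- fisher_exact_p(k2, 100, 100, 200)
    c2 <- mirpath:::.chi2_p(k2, 100, 100, 200)
    expect_lt(abs(f - c2), 0.02)
  }
})

test_that("fisher_enrichment builds correct tables and flags", {
  universe <- sprintf("g%04d", 1:2000)
  planted <- universe[1:20]
  coll <- geneset_collection(
    list(planted_set = c(planted, universe[100:119]),
         other = universe[500:549]),
    universe = universe)
  res <- fisher_enrichment(planted, coll)
  row <- res[res$set_id == "planted_set", ]
  expect_equal(row$k, 20)
  expect_equal(row$K, 40)
  expect_equal(row$N, 2000)
  # hypergeometric tail: all 20 targets inside a 40-gene set is astronomical
  expect_lt(row$fisher_p, 1e-6)
  expect_true(row$sig_p05)
  expect_true(row$enriched)

  # invariant to target order and duplication
  res2 <- fisher_enrichment(rep(rev(planted), 2), coll)
  expect_equal(res2$fisher_p, res$fisher_p)

  # empty target list: k = 0 everywhere, p = 1
  res0 <- fisher_enrichment(character(0), coll)
  expect_true(all(res0$k == 0))
  expect_true(all(res0$fisher_p == 1))

  expect_warning(fisher_enrichment(c(planted, "not_a_gene"), coll), "outside")
})

test_that("directional enrichment separates up and down target lists", {
  universe <- sprintf("g%03d", 1:500)
  coll <- geneset_collection(list(s1 = universe[1:30], s2 = universe[31:60]),
                             universe = universe)
  pairs <- data.frame(
    mirna = c("m1", "m1", "m2"),
    gene = c("g001", "g002", "g031"),
    mirna_direction = c("up", "up", "down"),
    stringsAsFactors = FALSE)
  res <- enrich_by_direction(pairs, coll)
  expect_equal(res$up[res$up$set_id == "s1", "k"], 2)
  expect_equal(res$down[res$down$set_id == "s2", "k"], 1)

  # removing down pairs leaves the up results unchanged
  res_up_only <- enrich_by_direction(pairs[pairs$mirna_direction == "up", ], coll)
  expect_equal(res_up_only$up, res$up)
  # all pairs up: down side runs on the empty list, every p = 1
  expect_true(all(res_up_only$down$fisher_p == 1))
})

test_that("key targets must sit in significant pathway AND GO sets", {
  universe <- sprintf("g%02d", 1:50)
  path_coll <- geneset_collection(list(P = c("g01", "g02")), universe = universe)
  go_coll <- geneset_collection(list(G = c("g01", "g03")), universe = universe)
  pairs <- data.frame(mirna = "m1", gene = c("g01", "g02", "g03"),
                      stringsAsFactors = FALSE)
  mk <- function(id, sig) data.frame(set_id = id, sig_p05 = sig,
                                     sig_fdr05 = sig, stringsAsFactors = FALSE)
  # g01 in significant P and significant G -> returned; g02 only in P -> not
  out <- key_target_overlap(mk("P", TRUE), mk("G", TRUE), pairs,
                            path_coll, go_coll)
  expect_identical(out, "g01")
  # no significant sets on either side -> empty
  expect_length(key_target_overlap(mk("P", FALSE), mk("G", FALSE), pairs,
                                   path_coll, go_coll), 0)
})

test_that("GMT round trip preserves sets; malformed input is rejected", {
  universe <- sprintf("g%03d", 1:100)
  coll <- simulate_genesets(universe, n_sets = 5, size_range = c(3, 10),
                            seed = 61, prefix = "GS")
  path <- tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  back <- read_gmt(path, universe = universe)
  expect_identical(back$sets, coll$sets)
  expect_identical(back$descriptions, coll$descriptions)

  # blank lines ignored, duplicate genes within a set collapsed
  writeLines(c("s1\tdesc\tg1\tg2\tg2\tg3", "", "s2\tdesc\tg2\tg4"), path)
  mixed <- read_gmt(path)
  expect_identical(mixed$sets$s1, c("g1", "g2", "g3"))
  expect_length(mixed$sets, 2)

  writeLines(c("s1\tdesc\tg1", "broken_line_no_tabs"), path)
  expect_error(read_gmt(path), "line 2")

  # sets emptied by universe restriction are dropped with a warning
  expect_warning(
    coll2 <- geneset_collection(list(a = c("x", "y"), b = c("g001")),
                                universe = c("g001", "g002")),
    "dropped")
  expect_identical(names(coll2$sets), "b")
})
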