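four_sample_pair <- function(m_profile, g_profile) {
  mirna <- matrix(m_profile, 1, 4, dimnames = list("m1", paste0("s", 1:4)))
  mrna <- matrix(g_profile, 1, 4, dimnames = list("g1", paste0("s", 1:4)))
  groups <- c("case", "case", "control", "control")
  list(mirna = expression_matrix(mirna, groups),
       mrna = expression_matrix(mrna, groups))
}

test_that("pearson_screen reproduces the hand-computed correlation", {
  d <- four_sample_pair(c(1, 2, 3, 4), c(10, 8, 9, 5))
  out <- pearson_screen(d$mirna, d$mrna, "m1", "g1", p_max = 1)
  expect_identical(nrow(out), 1L)
  expect_equal(out$r, -7 / sqrt(70), tolerance = 1e-12)
  expect_equal(out$r, pearson_oracle(c(1, 2, 3, 4), c(10, 8, 9, 5)),
               tolerance = 1e-15)
})

test_that("sign and significance gates act as specified", {
  # exact anti-correlation: retained with r = -1 even at a strict p gate
  d <- four_sample_pair(c(1, 2, 3, 4), c(9, 8, 7, 6))
  out <- pearson_screen(d$mirna, d$mrna, "m1", "g1", p_max = 0.05)
  expect_identical(nrow(out), 1L)
  expect_equal(out$r, -1)
  expect_equal(out$p, 0)

  # positive correlation excluded regardless of p
  d2 <- four_sample_pair(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(nrow(pearson_screen(d2$mirna, d2$mrna, "m1", "g1",
                                       p_max = 1)), 0L)

  # negative but insignificant: excluded at the default gate
  d3 <- four_sample_pair(c(1, 2, 3, 4), c(10, 8, 9, 5))
  expect_identical(nrow(pearson_screen(d3$mirna, d3$mrna, "m1", "g1",
                                       p_max = 0.05)), 0L)
})

test_that("mismatched samples and zero-variance features are handled", {
  d <- four_sample_pair(c(1, 2, 3, 4), c(9, 8, 7, 6))
  shuffled <- expression_matrix(d$mrna$values[, c(2, 1, 3, 4), drop = FALSE],
                                d$mrna$groups[c(2, 1, 3, 4)])
  expect_error(pearson_screen(d$mirna, shuffled, "m1", "g1"), "same ordered")

  flat <- four_sample_pair(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_warning(
    out <- pearson_screen(flat$mirna, flat$mrna, "m1", "g1", p_max = 1),
    "zero-variance")
  expect_identical(nrow(out), 0L)
})

test_that("screen r values agree with the direct formula on random data", {
  set.seed(31)
  n <- 18
  X <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(sprintf("m%d", 1:5), sprintf("s%02d", 1:n)))
  Y <- matrix(rnorm(7 * n), 7, n,
              dimnames = list(sprintf("g%d", 1:7), sprintf("s%02d", 1:n)))
  groups <- rep(c("case", "control"), c(12, 6))
  out <- pearson_screen(expression_matrix(X, groups),
                        expression_matrix(Y, groups),
                        rownames(X), rownames(Y), p_max = 1)
  for (i in seq_len(nrow(out))) {
    expect_equal(out$r[i],
                 pearson_oracle(X[out$mirna[i], ], Y[out$gene[i], ]),
                 tolerance = 1e-12)
    ct <- cor.test(X[out$mirna[i], ], Y[out$gene[i], ])
    expect_equal(out$p[i], ct$p.value, tolerance = 1e-12)
  }
})

test_that("prediction intersection has set semantics", {
  cand <- data.frame(mirna = c("m1", "m1", "m2"), gene = c("g1", "g2", "g2"),
                     r = c(-0.9, -0.8, -0.7), p = c(0.01, 0.02, 0.03),
                     mirna_direction = "up", gene_direction = "down",
                     stringsAsFactors = FALSE)
  expect_identical(nrow(intersect_predictions(
    cand, data.frame(mirna = character(0), gene = character(0)))), 0L)

  preds <- data.frame(mirna = c("m1", "m2", "m2", "m3"),
                      gene = c("g2", "g2", "g2", "g9"),
                      stringsAsFactors = FALSE)
  kept <- intersect_predictions(cand, preds)
  expect_identical(pair_keys(kept), c("m1\rg2", "m2\rg2"))
  expect_true(all(kept$predicted))
})

test_that("relationship summaries count distinct ids and pairs", {
  empty <- data.frame(mirna = character(0), gene = character(0))
  expect_equal(unname(summarize_relationships(empty)), c(0L, 0L, 0L))
  pairs <- data.frame(mirna = c("m1", "m1", "m2"), gene = c("g1", "g2", "g2"))
  s <- summarize_relationships(pairs)
  expect_equal(unname(s), c(2L, 2L, 3L))
  # pair count dominates both distinct counts whenever non-empty
  expect_gte(s[["n_relationships"]], max(s[["n_mirnas"]], s[["n_genes"]]))
})

test_that("planted pairs are recovered end-to-end with high precision", {
  sim <- simulate_cohort(small_config(seed = 41, n_true_pairs = 30))
  de_m <- differential_expression(sim$mirna)
  de_g <- differential_expression(sim$mrna)
  preds <- simulate_predictions(sim$truth, rownames(sim$mirna$values),
                                rownames(sim$mrna$values), 1, 0, seed = 41)
  pairs <- screen_target_pairs(sim$mirna, sim$mrna, de_m, de_g, preds)
  truth_keys <- pair_keys(sim$truth$true_pairs)
  found_keys <- pair_keys(pairs)
  expect_gte(mean(truth_keys %in% found_keys), 0.9)   # recall
  expect_gte(mean(found_keys %in% truth_keys), 0.9)   # precision
  # retained pairs are all anti-correlated and predicted
  expect_true(all(pairs$r < 0))
  expect_true(all(pairs$predicted))
})
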