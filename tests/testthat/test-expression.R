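test_that("CPM and TPM obey their contracts", {
  cts <- matrix(c(100L, 900L, 50L, 50L), 2,
                dimnames = list(c("G1", "G2"), c("s1", "s2")))
  cp <- cpm(cts)
  expect_equal(cp[, "s1"], c(G1 = 1e5, G2 = 9e5))
  expect_equal(colSums(cp), c(s1 = 1e6, s2 = 1e6))

  # equal counts, equal lengths -> equal TPM; doubling a length halves its
  # pre-scaling rate
  tp <- tpm(matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s")),
            c(1000, 1000))
  expect_equal(tp[1, ], tp[2, ])
  tp2 <- tpm(matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s")),
             c(2000, 1000))
  expect_equal(unname(tp2[2, ] / tp2[1, ]), 2)
  expect_error(cpm(matrix(0L, 2, 1, dimnames = list(NULL, "bad"))), "bad")

  # random-matrix property: column sums invariant
  set.seed(1)
  m <- matrix(rpois(60, 40), 10, dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(unname(colSums(cpm(m))), rep(1e6, 6))
  expect_equal(unname(colSums(tpm(m, runif(10, 500, 3000)))), rep(1e6, 6))
})

test_that("TMM factors: identity, pure depth, and agreement with edgeR", {
  set.seed(8)
  base <- rpois(500, 100)
  cts <- cbind(s1 = base, s2 = base)
  expect_equal(unname(tmm_factors(cts)), c(1, 1), tolerance = 1e-9)

  # pure depth change: all M-values zero after depth division
  cts2 <- cbind(s1 = base, s2 = 3L * base)
  expect_equal(unname(tmm_factors(cts2)), c(1, 1), tolerance = 1e-9)

  # composition bias: cross-check against the reference implementation
  skip_if_not_installed("edgeR")
  set.seed(9)
  cts3 <- cbind(s1 = rpois(2000, exp(rnorm(2000, 4, 1))),
                s2 = rpois(2000, exp(rnorm(2000, 4, 1))),
                s3 = rpois(2000, exp(rnorm(2000, 4, 1))))
  cts3[1:40, 3] <- cts3[1:40, 3] * 20L   # a few very high genes distort s3
  ours <- tmm_factors(cts3)
  ref <- edgeR::calcNormFactors(cts3, method = "TMM")
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("expressed filter needs TPM above threshold in two samples of the stage", {
  tpm_mat <- rbind(G1 = c(1.5, 1.2, 0.1, 0.2),
                   G2 = c(0, 0, 0, 0),
                   G3 = c(1.0, 1.0, 1.0, 1.0),
                   G4 = c(5, 0.2, 0.3, 0.1))
  colnames(tpm_mat) <- paste0("s", 1:4)
  stages <- rep("ESC", 4)
  cfg <- pipeline_config()
  kept <- expressed_filter(tpm_mat, stages, "ESC", cfg)
  expect_true("G1" %in% kept)        # two samples above 1
  expect_false("G2" %in% kept)       # silent
  expect_false("G3" %in% kept)       # exactly 1.0: strict inequality
  expect_false("G4" %in% kept)       # only one sample above
})

test_that("NB exact test: identical groups are null, Poisson limit matches closed form", {
  grp <- rep(c("androgenetic", "parthenogenetic"), each = 4)
  # identical per-group count multisets with equal library sizes
  cts_id <- cbind(a1 = c(10L, 20L), a2 = c(30L, 15L),
                  p1 = c(10L, 20L), p2 = c(30L, 15L))
  rownames(cts_id) <- c("g1", "g2")
  res <- nb_exact_test(cts_id, c("androgenetic", "androgenetic",
                                 "parthenogenetic", "parthenogenetic"),
                       norm_factors = rep(1, 4))
  expect_equal(res$log2fc_pg_over_ag, c(0, 0), tolerance = 1e-9)
  expect_equal(res$p_value, c(1, 1), tolerance = 1e-9)

  # dispersion -> 0: conditional test equals the exact binomial test
  p_impl <- uniprint:::exact_nb_p(30, 10, 2, 2, 0)
  d <- dbinom(0:40, 40, 0.5)
  p_oracle <- sum(d[d <= dbinom(30, 40, 0.5) * (1 + 1e-8)])
  expect_equal(p_impl, p_oracle, tolerance = 1e-12)

  # all-zero gene is a clean null
  cts0 <- rbind(z = rep(0L, 8), ok = rep(20L, 8))
  colnames(cts0) <- paste0("s", 1:8)
  res0 <- nb_exact_test(cts0, grp, norm_factors = rep(1, 8))
  expect_equal(res0[res0$gene_id == "z", ]$p_value, 1)
  expect_equal(res0[res0$gene_id == "z", ]$log2fc_pg_over_ag, 0)
})

test_that("label swap negates fold changes and preserves p; sample order irrelevant", {
  sim <- simulate_counts(simulation_scenario(seed = 31, n_genes = 300,
                                             n_meg = 8, n_peg = 8,
                                             n_dmr_paternal = 4,
                                             n_ase_biallelic = 4))
  esc <- sim$col_data[stage == "ESC" & origin != "biparental"]
  cts <- sim$counts[, esc$sample_id]
  grp <- esc$origin
  a <- nb_exact_test(cts, grp)
  swapped <- ifelse(grp == "androgenetic", "parthenogenetic", "androgenetic")
  b <- nb_exact_test(cts, swapped)
  expect_equal(a$log2fc_pg_over_ag, -b$log2fc_pg_over_ag, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)

  perm <- sample(ncol(cts))
  c_res <- nb_exact_test(cts[, perm], grp[perm])
  expect_equal(a$p_value, c_res$p_value, tolerance = 1e-9)
  expect_equal(a$log2fc_pg_over_ag, c_res$log2fc_pg_over_ag, tolerance = 1e-9)
})

test_that("imprinted-like classes follow the q and sign rules", {
  tests <- data.table(gene_id = c("A", "B", "C", "D"),
                      log2fc_pg_over_ag = c(2, -2, 0.5, 3),
                      p_value = c(1e-5, 1e-5, 0.6, 1e-4))
  calls <- classify_imprinted_expression(tests, expressed_genes = c("A", "B", "C"),
                                         stage = "ESC")
  expect_equal(calls[gene_id == "A", class], "MEG_like")
  expect_equal(calls[gene_id == "B", class], "PEG_like")
  expect_equal(calls[gene_id == "C", class], "not_imprinted_like")
  expect_equal(calls[gene_id == "D", class], "not_expressed")
  expect_true(is.na(calls[gene_id == "D", q_value]))
})

test_that("planted imprinted genes rank by true direction on synthetic counts", {
  sim <- simulate_counts(simulation_scenario(seed = 17, n_genes = 400,
                                             n_meg = 10, n_peg = 10,
                                             n_dmr_paternal = 4,
                                             n_ase_biallelic = 4))
  esc <- sim$col_data[stage == "ESC" & origin != "biparental"]
  res <- nb_exact_test(sim$counts[, esc$sample_id], esc$origin)
  truth <- sim$truth
  megs <- truth[is_meg == TRUE, gene_id]
  pegs <- truth[is_peg == TRUE, gene_id]
  expect_gt(min(res[res$gene_id %in% megs, ]$log2fc_pg_over_ag), 0)
  expect_lt(max(res[res$gene_id %in% pegs, ]$log2fc_pg_over_ag), 0)
})
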