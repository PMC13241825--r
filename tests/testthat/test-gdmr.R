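toy_cluster_ann <- function() {
  gene_annotation(data.table(
    gene_id = c("A1", "A2"), transcript_id = c("A1.t1", "A2.t1"),
    chrom = "chr19", start = c(1000000L, 1260000L),
    end = c(1040000L, 1300000L), strand = "+"))
}

test_that("scan region spans the anchors plus flanks and rejects mixed chromosomes", {
  ann <- toy_cluster_ann()
  r <- make_scan_region(c("A1", "A2"), ann, 200000L)
  expect_equal(c(r$start, r$end), c(800000, 1500000))
  r0 <- make_scan_region(c("A1", "A2"), ann, 0L)
  expect_equal(c(r0$start, r0$end), c(1000000, 1300000))
  r1 <- make_scan_region("A1", ann, 50000L)
  expect_equal(c(r1$start, r1$end), c(950000, 1090000))

  bad <- gene_annotation(data.table(
    gene_id = c("A1", "B1"), transcript_id = c("A1.t1", "B1.t1"),
    chrom = c("chr19", "chr3"), start = c(1L, 1L), end = c(10L, 10L),
    strand = "+"))
  expect_error(make_scan_region(c("A1", "B1"), bad, 0L), "different chromosomes")
  expect_error(make_scan_region("ZZ", ann, 0L), "anchor")
})

test_that("windows tile the region exactly, last tile may be short", {
  r <- genomic_interval("chr19", 0, 3500)
  w <- make_windows(r, 1000L)
  expect_equal(nrow(w), 4)
  expect_equal(w$end[4] - w$start[4], 500)
  expect_equal(sum(w$end - w$start), 3500)     # conservation
  expect_true(all(w$start[-1] == w$end[-nrow(w)]))  # no gaps or overlap

  w1 <- make_windows(genomic_interval("chr19", 0, 1000), 1000L)
  expect_equal(nrow(w1), 1)

  # unaligned region start: first tile short, tiles still reassemble exactly
  w2 <- make_windows(genomic_interval("chr19", 250, 2250), 1000L)
  expect_equal(sum(w2$end - w2$start), 2000)
  expect_equal(w2$start[1], 250)
})

test_that("exact permutation p equals brute-force enumeration over many group sizes", {
  set.seed(21)
  for (na in 2:5) {
    for (nb in 2:5) {
      if (choose(na + nb, na) > 1000) next
      a <- runif(na, 0, 100)
      b <- runif(nb, 0, 100)
      res <- permutation_test(a, b, max_exact = 20000L)
      expect_true(res$exact)
      expect_equal(res$p_value, brute_force_perm_p(a, b), tolerance = 1e-12,
                   label = sprintf("%dv%d", na, nb))
    }
  }
})

test_that("the 4-sperm/3-oocyte fixture yields the minimum attainable p of 1/35", {
  sperm <- c(80, 85, 90, 82)
  oocyte <- c(10, 12, 8)
  res <- permutation_test(sperm, oocyte)
  expect_true(res$exact)
  expect_equal(res$n_assignments, 35)
  expect_equal(res$p_value, 1 / 35, tolerance = 1e-12)
  # identical constants -> p = 1
  expect_equal(permutation_test(rep(5, 4), rep(5, 3))$p_value, 1)
  # label exchange invariance
  expect_equal(permutation_test(oocyte, sperm)$p_value, res$p_value)
  expect_error(permutation_test(numeric(), oocyte), "non-empty")
})

test_that("Monte-Carlo permutation agrees with exact within 3 binomial SEs", {
  sperm <- c(80, 85, 90, 82)
  oocyte <- c(10, 12, 8)
  exact_p <- permutation_test(sperm, oocyte)$p_value
  set.seed(33)
  mc <- permutation_test(sperm, oocyte, max_exact = 1L, n_mc = 10000L)
  expect_false(mc$exact)
  se <- sqrt(exact_p * (1 - exact_p) / 10000)
  expect_lt(abs(mc$p_value - exact_p), 3 * se + 1 / 10001)
})

test_that("BH over scan windows cannot be beaten by a single 4v3 window", {
  # one extreme window among 35 tested: q = 35 * (1/35) / 1 = 1
  p <- c(1 / 35, rep(1, 34))
  q <- p.adjust(p, "BH")
  expect_equal(q[1], 1)
  # three adjacent extreme windows among 35: best q ~ 0.33, still above 0.05
  p3 <- c(rep(1 / 35, 3), rep(1, 32))
  q3 <- p.adjust(p3, "BH")
  expect_equal(min(q3), 35 / 3 * (1 / 35), tolerance = 1e-9)
  expect_gt(min(q3), 0.05)
})

test_that("gDMR scan flags planted windows as nominal and persistence is concordant", {
  sc <- simulation_scenario(seed = 41, n_genes = 150, n_dmr_paternal = 4,
                            n_meg = 4, n_peg = 4, n_ase_biallelic = 4,
                            n_covered_windows = 12)
  germ <- simulate_germ(sc)
  meth <- simulate_methylomes(sc)
  cfg <- pipeline_config()
  scan <- scan_gdmrs(germ$samples, germ$windows, cfg)
  truth <- germ$win_truth
  planted <- truth[is_gdmr == TRUE, window_id]
  expect_true(all(planted %in% scan$window_id))
  expect_true(all(scan[window_id %in% planted, nominal]))
  expect_true(all(scan[window_id %in% planted, germ_direction] ==
                    "oocyte_methylated"))
  # the 4v3 panel cannot clear BH: the q-gated call set is empty
  expect_equal(nrow(call_gdmrs(scan, cfg)), 0)
  put <- call_gdmrs(scan, cfg, use_nominal = TRUE)
  pers <- persistence_check(put, meth$samples, germ$windows, cfg)
  expect_equal(sort(pers[persistent == TRUE, window_id]),
               sort(truth[persistent == TRUE, window_id]))
  expect_true(all(pers[persistent == TRUE, origin_class] == "germline_candidate"))
  expect_true(all(pers[window_id %in% truth[is_gdmr == TRUE & persistent == FALSE,
                                            window_id],
                       origin_class] == "germline_non_persistent"))
})

test_that("promoter DMRs with no germline window are secondary", {
  dmrs <- data.table(gene_id = c("G1", "G2"), chrom = "chr1",
                     win_start = c(1000L, 50000L), win_end = c(2000L, 51000L),
                     direction = c("maternal", "paternal"))
  # no germ windows at all -> everything secondary
  res <- classify_dmr_origin(dmrs, data.table())
  expect_equal(res$dmr_origin$origin_class, c("secondary", "secondary"))
  # concordant overlapping window -> germline-derived; the other stays secondary
  gw <- data.table(window_id = "chr1:1000-2000", chrom = "chr1",
                   start = 1000, end = 2000,
                   germ_direction = "oocyte_methylated")
  res2 <- classify_dmr_origin(dmrs, gw)
  expect_equal(res2$dmr_origin$origin_class, c("germline_derived", "secondary"))
  expect_equal(nrow(res2$orphan_gdmrs), 0)
  # discordant overlap stays secondary and the window is orphaned
  gw2 <- copy(gw)[, germ_direction := "sperm_methylated"]
  res3 <- classify_dmr_origin(dmrs, gw2)
  expect_equal(res3$dmr_origin$origin_class, c("secondary", "secondary"))
  expect_equal(nrow(res3$orphan_gdmrs), 1)
})
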