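make_ann <- function(chrom = "chr5", start = 10000L, end = 12000L, strand = "+",
                     gene = "G1") {
  gene_annotation(data.table(gene_id = gene, transcript_id = paste0(gene, ".t1"),
                             chrom = chrom, start = start, end = end,
                             strand = strand))
}

test_that("promoter windows are TSS +/- flank, strand-aware and clipped", {
  ann <- make_ann(start = 10000L, strand = "+")
  w <- promoter_window(ann, "G1.t1", 500L)
  expect_equal(c(w$start, w$end), c(9500, 10500))

  ann_m <- make_ann(start = 1000L, end = 2000L, strand = "-")
  w <- promoter_window(ann_m, "G1.t1", 500L)
  expect_equal(c(w$start, w$end), c(1999 - 500, 1999 + 500))  # centred on 1999

  ann_edge <- make_ann(start = 200L, end = 900L, strand = "+")
  w <- promoter_window(ann_edge, "G1.t1", 500L)
  expect_equal(c(w$start, w$end), c(0, 700))  # clipped at chromosome start

  expect_error(promoter_window(ann, "nope", 500L), "unknown transcript")
})

test_that("promoter summaries pool counts and gate on coverage", {
  ann <- make_ann(start = 10000L)
  wins <- promoter_windows(ann, 500L)
  s <- make_meth_sample("s", "androgenetic",
                        data.table(chrom = "chr5",
                                   pos = c(9600L, 9700L, 9800L, 20000L),
                                   meth = c(0L, 10L, 2L, 9L),
                                   unmeth = c(10L, 0L, 1L, 1L)))
  cfg <- pipeline_config(min_cpgs_per_region = 2L)
  sm <- summarize_promoter(s, wins, cfg)
  # CpG (2/3) is under min_cov 5 and excluded; outside-window CpG ignored
  expect_equal(sm$n_cpgs, 2L)
  expect_equal(sm$mean_meth_percent, 50)
  expect_equal(sm$total_reads, 20L)

  s_empty <- make_meth_sample("e", "androgenetic",
                              data.table(chrom = "chr9", pos = 1L,
                                         meth = 5L, unmeth = 5L))
  sm2 <- summarize_promoter(s_empty, wins, cfg)
  expect_equal(sm2$n_cpgs, 0L)
  expect_true(is.na(sm2$mean_meth_percent))
})

test_that("sample-mean rank test reproduces exact enumeration on the 4v4 fixture", {
  ag <- c(90, 92, 88, 91)
  pg <- c(10, 12, 8, 11)
  res <- test_promoter(ag, pg, mode = "sample_mean")
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res$delta_pp, mean(ag) - mean(pg))
  # full 70-partition oracle
  expect_equal(res$p_value, rank_sum_exact_p(ag, pg), tolerance = 1e-12)
  # and on a non-separated fixture the two routes still agree
  set.seed(3)
  x <- rnorm(4, 50, 20); y <- rnorm(4, 55, 20)
  expect_equal(test_promoter(x, y, mode = "sample_mean")$p_value,
               rank_sum_exact_p(x, y), tolerance = 1e-10)
})

test_that("identical groups give p = 1 and zero delta; cpg mode separates strongly", {
  same <- c(40, 41, 42, 43)
  res <- test_promoter(same, same, ag_levels = same / 100, pg_levels = same / 100,
                       mode = "sample_mean")
  expect_equal(res$delta_pp, 0)
  expect_equal(res$p_value, 1)

  set.seed(11)
  ag_lv <- rep(runif(20, 0.8, 1.0), 4)   # 20 CpGs x 4 samples
  pg_lv <- rep(runif(20, 0.0, 0.2), 4)
  res <- test_promoter(c(90, 91, 89, 92), c(10, 9, 11, 8),
                       ag_levels = ag_lv, pg_levels = pg_lv, mode = "cpg_level")
  expect_lt(res$p_value, 1e-10)
})

test_that("swapping group labels flips deltas and directions, not p-values", {
  sc <- simulation_scenario(seed = 5, n_genes = 150, n_dmr_paternal = 4,
                            n_meg = 4, n_peg = 4, n_ase_biallelic = 4,
                            n_covered_windows = 6)
  sim <- simulate_methylomes(sc)
  swap <- lapply(sim$samples, function(s) {
    if (s$origin == "androgenetic") s$origin <- "parthenogenetic"
    else if (s$origin == "parthenogenetic") s$origin <- "androgenetic"
    s
  })
  cfg <- pipeline_config()
  a <- call_promoter_dmrs(sim$samples, sim$layout$annotation, config = cfg)
  b <- call_promoter_dmrs(swap, sim$layout$annotation, config = cfg)
  m <- merge(a$tests[, .(gene_id, delta_pp, p_value)],
             b$tests[, .(gene_id, delta_pp, p_value)], by = "gene_id")
  expect_equal(m$delta_pp.x, -m$delta_pp.y, tolerance = 1e-9)
  expect_equal(m$p_value.x, m$p_value.y, tolerance = 1e-9)
  if (nrow(a$calls) && nrow(b$calls)) {
    mc <- merge(a$calls[, .(gene_id, direction)],
                b$calls[, .(gene_id, direction)], by = "gene_id")
    expect_true(all(mc$direction.x != mc$direction.y))
  }
})

test_that("BH q-values and the effect-size gate control promoter calls", {
  # hand-computed BH on [0.001, 0.02, 0.9] -> [0.003, 0.03, 0.9]
  p <- c(0.001, 0.02, 0.9)
  expect_equal(p.adjust(p, "BH"), c(0.003, 0.03, 0.9))

  sc <- simulation_scenario(seed = 23, n_genes = 200, n_dmr_paternal = 6,
                            n_meg = 4, n_peg = 4, n_ase_biallelic = 4,
                            n_covered_windows = 6)
  sim <- simulate_methylomes(sc)
  res <- call_promoter_dmrs(sim$samples, sim$layout$annotation,
                            config = pipeline_config())
  expect_true(all(res$tests$q_value >= res$tests$p_value - 1e-12))
  # q monotone non-decreasing in sorted-p order
  ord <- order(res$tests$p_value)
  expect_true(all(diff(res$tests$q_value[ord]) >= -1e-12))
  # every call passes both gates
  expect_true(all(res$calls$q_value <= 0.05))
  expect_true(all(abs(res$calls$delta_pp) >= 25))
  # a significant q with a sub-threshold delta is not a call
  strict <- pipeline_config(dmr_min_delta_pp = 99)
  res99 <- call_promoter_dmrs(sim$samples, sim$layout$annotation,
                              config = strict)
  expect_equal(nrow(res99$calls), 0)
})
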