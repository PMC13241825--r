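test_that("coverage dialect maps fields directly and converts coordinates", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr19\t1000\t1000\t75.0\t3\t1",
               "chr19\t5000\t5000\t0.0\t0\t4"), f)
  s <- read_cytosine_report(f, "coverage", merge_strands = FALSE)
  expect_equal(nrow(s$calls), 2)
  expect_equal(s$calls$pos, c(999L, 4999L))  # 1-based file, 0-based internal
  expect_equal(s$calls$meth, c(3L, 0L))
  expect_equal(s$calls$unmeth, c(1L, 4L))
})

test_that("cytosine report keeps only CpG context and zero-coverage sites survive", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t100\t+\t5\t5\tCpG\tCGA",
               "chr1\t200\t+\t9\t1\tCHH\tCAA",
               "chr1\t300\t+\t0\t0\tCpG\tCGT"), f)
  s <- read_cytosine_report(f, "cytosine_report")
  expect_equal(nrow(s$calls), 2)          # CHH dropped
  expect_true(299L %in% s$calls$pos)      # 0-total call retained
})

test_that("opposite-strand dyad calls merge by count summing", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t1000\t+\t3\t1\tCpG\tCGA",
               "chr1\t1001\t-\t2\t4\tCpG\tCGT",
               "chr1\t2000\t+\t7\t0\tCpG\tCGC",
               "chr1\t2001\t-\t1\t2\tCpG\tCGG"), f)
  merged <- read_cytosine_report(f, "cytosine_report", merge_strands = TRUE)
  expect_equal(nrow(merged$calls), 2)
  # oracle: plain sums of the 4-line fixture
  expect_equal(merged$calls[pos == 999L, meth], 3L + 2L)
  expect_equal(merged$calls[pos == 999L, unmeth], 1L + 4L)
  expect_equal(merged$calls[pos == 1999L, meth], 7L + 1L)
  unmerged <- read_cytosine_report(f, "cytosine_report", merge_strands = FALSE)
  expect_equal(nrow(unmerged$calls), 4)
  expect_equal(sum(unmerged$calls$meth), sum(merged$calls$meth))
})

test_that("coverage dialect merges adjacent dyad positions when asked", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr19\t1000\t1000\t75.0\t3\t1",
               "chr19\t1001\t1001\t50.0\t2\t2"), f)
  s <- read_cytosine_report(f, "coverage", merge_strands = TRUE)
  expect_equal(nrow(s$calls), 1)
  expect_equal(s$calls$meth, 5L)
  expect_equal(s$calls$unmeth, 3L)
})

test_that("malformed methylation lines fail with a line number", {
  f <- withr::local_tempfile(fileext = ".cov")
  writeLines(c("chr19\t1000\t1000\t75.0\t3\t1", "chr19\tbroken"), f)
  expect_error(read_cytosine_report(f, "coverage"), "line 2")
})

test_that("coordinate conversion is its own inverse", {
  pos <- sample.int(1e8, 200)
  expect_equal(uniprint:::pos_to_report(uniprint:::pos_to_internal(pos)), pos)
})

test_that("counts matrix round-trips and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  mat <- matrix(c(10L, 0L, 3L, 7L), 2, dimnames = list(c("G1", "G2"), c("s1", "s2")))
  write_counts_matrix(mat, f)
  expect_identical(read_counts_matrix(f), mat)

  writeLines(c("gene_id\ts1", "G1\t-3"), f)
  expect_error(read_counts_matrix(f), "negative")
  writeLines(c("gene_id\ts1", "G1\t2", "G1\t5"), f)
  expect_error(read_counts_matrix(f), "G1")
  writeLines(c("gene_id\ts1\ts2", "G1\t1\t2"), f)
  manifest <- data.table(sample_id = "s1", origin = "biparental", stage = "ESC")
  expect_error(read_counts_matrix(f, manifest), "s2")
})

test_that("ASE reader derives totals and ratios; empty file warns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgene_id\tchrom\tpos\tref_count\talt_count",
               "s1\tG1\tchr19\t100\t17\t3"), f)
  ase <- read_ase_table(f)
  expect_equal(ase$total, 20L)
  expect_equal(ase$allelic_ratio, 0.15)
  expect_equal(ase$cell_type, "s1")  # defaults to sample

  writeLines("sample_id\tgene_id\tchrom\tpos\tref_count\talt_count", f)
  expect_warning(res <- read_ase_table(f), "empty")
  expect_equal(nrow(res), 0)

  writeLines(c("sample_id\tgene_id\tchrom\tpos\tref_count\talt_count",
               "s1\tG1\tchr19\t100\t1.5\t3"), f)
  expect_error(read_ase_table(f), "ref_count")
})

test_that("annotation dialects agree on strand-aware TSS", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t1000\t2000\tGP|GP.t1\t0\t+",
               "chr2\t1000\t2000\tGM|GM.t1\t0\t-"), bed)
  ann <- read_gene_annotation(bed, "bed12")
  expect_equal(ann[ann$gene_id == "GP", ]$tss, 1000L)
  expect_equal(ann[ann$gene_id == "GM", ]$tss, 1999L)

  tss_f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\ttss\tstrand", "G1\tchr19\t10000\t+"), tss_f)
  ann2 <- read_gene_annotation(tss_f, "tss_table")
  expect_equal(nrow(ann2), 1)
  expect_equal(ann2$tss, 10000L)

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste0('chr3\tsrc\ttranscript\t1001\t2000\t.\t-\t.\t',
                    'gene_id "GX"; transcript_id "GX.t1";'), gtf)
  ann3 <- read_gene_annotation(gtf, "gtf_lite")
  expect_equal(ann3$start, 1000L)  # GTF 1-based closed -> 0-based half-open
  expect_equal(ann3$tss, 1999L)

  writeLines("chr2\t1000\t2000\tGQ\t0\t.", bed)
  expect_error(read_gene_annotation(bed, "bed12"), "strand")
})

test_that("reversing a transcript's strand moves the TSS to the opposite end", {
  set.seed(42)
  for (i in 1:25) {
    st <- sample.int(1e6, 1)
    en <- st + sample.int(1e4, 1)
    plus <- gene_annotation(data.table(gene_id = "g", transcript_id = "t",
                                       chrom = "c", start = st, end = en,
                                       strand = "+"))
    minus <- gene_annotation(data.table(gene_id = "g", transcript_id = "t",
                                        chrom = "c", start = st, end = en,
                                        strand = "-"))
    expect_equal(plus$tss, st)
    expect_equal(minus$tss, en - 1L)
    expect_equal(plus$tss + minus$tss, st + en - 1L)
  }
})

test_that("candidate table round-trips with stable columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.table()
  write_candidate_table(empty, f)
  expect_equal(nrow(read_candidate_table(f)), 0)

  cand <- data.table(gene_id = "G1", chrom = "chr1", tss = 1000L,
                     tier = "1_stringent", has_promoter_dmr = TRUE,
                     dmr_direction = "paternal", dmr_delta_pp = 62.5,
                     dmr_q = 0.003, has_imprinted_expression = TRUE,
                     expression_class = "MEG_like", expr_log2fc = 2.1,
                     expr_q = 0.001, concordant = TRUE,
                     ase_support = "monoallelic", isoform_specific = FALSE,
                     near_gdmr = TRUE)
  write_candidate_table(cand, f)
  back <- read_candidate_table(f)
  expect_equal(back$tier, "1_stringent")
  expect_equal(back$dmr_delta_pp, 62.5)
  expect_true(all(uniprint:::CANDIDATE_COLS %in% names(back)))
})

test_that("methylome coverage writer round-trips through the reader", {
  s <- make_meth_sample("s1", "androgenetic",
                        data.table(chrom = "chr1", pos = c(100L, 500L),
                                   meth = c(3L, 0L), unmeth = c(7L, 9L)))
  f <- withr::local_tempfile(fileext = ".cov")
  write_cytosine_coverage(s, f)
  back <- read_cytosine_report(f, "coverage", sample_id = "s1",
                               origin = "androgenetic", merge_strands = FALSE)
  expect_equal(back$calls, s$calls)
})

test_that("sample manifest validates vocabulary and uniqueness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\torigin\tstage", "a\tandrogenetic\tESC",
               "b\tparthenogenetic\tNPC"), f)
  m <- read_sample_manifest(f)
  expect_equal(nrow(m), 2)
  writeLines(c("sample_id\torigin\tstage", "a\tandrogenetic\tESC",
               "a\tbiparental\tESC"), f)
  expect_error(read_sample_manifest(f), "duplicate")
  writeLines(c("sample_id\torigin\tstage", "a\tmartian\tESC"), f)
  expect_error(read_sample_manifest(f), "origin")
})
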