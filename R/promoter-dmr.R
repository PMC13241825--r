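#' Promoter window around a transcript's TSS
#'
#' The promoter is the window TSS - flank to TSS + flank (0-based half-open,
#' clipped at zero), the canonical minus-500/plus-500 region when
#' `flank_bp = 500`.
#'
#' @param annotation A `gene_annotation`.
#' @param transcript_id Transcript to centre on.
#' @param flank_bp Half-width in bp.
#' @return A `genomic_interval`.
#' @export
promoter_window <- function(annotation, transcript_id, flank_bp = 500L) {
  wanted_tx <- transcript_id
  ann_df <- as.data.frame(annotation)
  row <- ann_df[ann_df$transcript_id == wanted_tx, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown transcript: ", transcript_id)
  tss <- row$tss[1]
  genomic_interval(row$chrom[1], max(0L, tss - flank_bp), tss + flank_bp,
                   row$strand[1])
}

#' Promoter windows for every transcript
#'
#' @param annotation A `gene_annotation`.
#' @param flank_bp Half-width in bp.
#' @return data.table: gene_id, transcript_id, chrom, win_start, win_end.
#' @export
promoter_windows <- function(annotation, flank_bp = 500L) {
  ann <- as.data.table(annotation)
  out <- ann[, .(gene_id, transcript_id, chrom,
                 win_start = pmax(0L, tss - as.integer(flank_bp)),
                 win_end = tss + as.integer(flank_bp))]
  out[]
}

# Long table of per-CpG methylation levels inside each window for one sample.
# Only CpGs with coverage >= min_cov are informative.  Windows are matched to
# CpGs with a data.table non-equi join per chromosome.
window_cpg_levels <- function(sample, windows, min_cov) {
  calls <- copy(sample$calls)
  calls <- calls[meth + unmeth >= min_cov]
  if (nrow(calls) == 0) return(data.table())
  w <- as.data.table(windows)[, .(gene_id, transcript_id, chrom,
                                  win_start, win_end)]
  calls[, `:=`(p1 = pos, p2 = pos)]
  setkey(w, chrom, win_start, win_end)
  hits <- foverlaps(calls[, .(chrom, p1, p2, pos, meth, unmeth)],
                    w, by.x = c("chrom", "p1", "p2"), nomatch = NULL)
  if (nrow(hits) == 0) return(data.table())
  hits[, .(sample_id = sample$sample_id, gene_id, transcript_id, chrom, pos,
           meth, unmeth, level = meth / (meth + unmeth))]
}

#' Summarise promoter methylation for one sample
#'
#' Pooled-count mean over informative CpGs inside the window, plus the CpG
#' and read tallies; the mean is NA when fewer than `min_cpgs_per_region`
#' CpGs are informative.
#'
#' @param sample A `methylome_sample`.
#' @param windows Output of [promoter_windows()] (or a one-row subset).
#' @param config A [pipeline_config()].
#' @return data.table: gene_id, transcript_id, sample_id, mean_meth_percent,
#'   n_cpgs, total_reads.
#' @export
summarize_promoter <- function(sample, windows, config = pipeline_config()) {
  lv <- window_cpg_levels(sample, windows, config$min_cov_per_cpg)
  w <- as.data.table(windows)
  if (nrow(lv) == 0) {
    return(w[, .(gene_id, transcript_id, sample_id = sample$sample_id,
                 mean_meth_percent = NA_real_, n_cpgs = 0L, total_reads = 0L)])
  }
  agg <- lv[, .(mean_meth_percent = 100 * sum(meth) / sum(meth + unmeth),
                n_cpgs = .N, total_reads = sum(meth + unmeth)),
            by = .(gene_id, transcript_id)]
  out <- merge(w[, .(gene_id, transcript_id)], agg,
               by = c("gene_id", "transcript_id"), all.x = TRUE)
  out[is.na(n_cpgs), `:=`(n_cpgs = 0L, total_reads = 0L)]
  out[n_cpgs < config$min_cpgs_per_region, mean_meth_percent := NA_real_]
  out[, sample_id := sample$sample_id]
  out[]
}

#' Rank test for one promoter between androgenetic and parthenogenetic groups
#'
#' Two units of test are supported.  `sample_mean`: exact two-sided Wilcoxon
#' rank-sum on per-sample pooled promoter means (one value per sample).
#' `cpg_level` (default): two-sided Mann-Whitney on the pooled per-sample
#' per-CpG methylation levels in the window, androgenetic pool versus
#' parthenogenetic pool; ties are handled by midranks with the
#' continuity-corrected normal approximation (the behaviour of
#' [stats::wilcox.test()]).  The effect size `delta_pp` is always the
#' difference of group means of per-sample promoter means, androgenetic
#' minus parthenogenetic, in percentage points.
#'
#' @param ag_means,pg_means Per-sample pooled promoter means (percent).
#' @param ag_levels,pg_levels Per-sample per-CpG levels (fractions), needed
#'   for `cpg_level` mode.
#' @param mode "cpg_level" or "sample_mean".
#' @return List with `p_value`, `delta_pp`, `mode`, or NULL when fewer than
#'   two informative samples exist in either group.
#' @export
test_promoter <- function(ag_means, pg_means, ag_levels = NULL,
                          pg_levels = NULL, mode = c("cpg_level", "sample_mean")) {
  mode <- match.arg(mode)
  ag_means <- ag_means[!is.na(ag_means)]
  pg_means <- pg_means[!is.na(pg_means)]
  if (length(ag_means) < 2 || length(pg_means) < 2) return(NULL)
  delta <- mean(ag_means) - mean(pg_means)
  if (mode == "sample_mean") {
    p <- suppressWarnings(
      wilcox.test(ag_means, pg_means, alternative = "two.sided")$p.value)
  } else {
    if (is.null(ag_levels) || is.null(pg_levels) ||
        length(ag_levels) == 0 || length(pg_levels) == 0) return(NULL)
    p <- suppressWarnings(
      wilcox.test(ag_levels, pg_levels, alternative = "two.sided")$p.value)
  }
  list(p_value = min(1, p), delta_pp = delta, mode = mode)
}

#' Call parent-of-origin promoter DMRs
#'
#' Runs the configured rank test on every expressed gene's promoter
#' (androgenetic versus parthenogenetic samples only; biparental samples are
#' deliberately excluded from the test), applies Benjamini-Hochberg FDR over
#' all tested promoters, and reports calls with q at most `dmr_alpha` and an
#' absolute group difference of at least `dmr_min_delta_pp` percentage
#' points.  Positive deltas (androgenetic hypermethylated) are paternal
#' DMRs; negative, maternal.
#'
#' @param samples List of `methylome_sample`s (androgenetic and
#'   parthenogenetic members are used).
#' @param annotation A `gene_annotation`.
#' @param expressed_genes Character vector defining the FDR universe
#'   (expressed genes); NULL tests every annotated gene.
#' @param config A [pipeline_config()].
#' @return List with `tests` (every tested promoter: gene_id, delta_pp,
#'   p_value, q_value, called) and `calls` (the DMR calls with direction).
#' @export
call_promoter_dmrs <- function(samples, annotation, expressed_genes = NULL,
                               config = pipeline_config()) {
  origins <- vapply(samples, `[[`, "", "origin")
  ag <- samples[origins == "androgenetic"]
  pg <- samples[origins == "parthenogenetic"]
  if (length(ag) < 2 || length(pg) < 2) {
    stop("need >= 2 androgenetic and >= 2 parthenogenetic samples")
  }
  ann <- as.data.table(annotation)
  if (!is.null(expressed_genes)) ann <- ann[gene_id %in% expressed_genes]
  # one window per gene: the first transcript's TSS (canonical-most row)
  ann_gene <- ann[, .SD[1], by = gene_id]
  windows <- promoter_windows(gene_annotation(ann_gene), config$promoter_flank_bp)

  grp_samples <- c(ag, pg)
  lv <- rbindlist(lapply(grp_samples, window_cpg_levels, windows = windows,
                         min_cov = config$min_cov_per_cpg))
  if (nrow(lv) == 0) {
    warning("no informative promoter CpGs; empty DMR output")
    empty <- data.table(gene_id = character(), chrom = character(),
                        win_start = integer(), win_end = integer(),
                        direction = character(), delta_pp = numeric(),
                        p_value = numeric(), q_value = numeric())
    return(list(tests = empty, calls = empty, test_mode = config$test_mode))
  }
  sample_origin <- setNames(vapply(grp_samples, `[[`, "", "origin"),
                            vapply(grp_samples, `[[`, "", "sample_id"))
  lv[, origin := sample_origin[sample_id]]

  per_sample <- lv[, .(n_cpgs = .N,
                       mean_pct = 100 * sum(meth) / sum(meth + unmeth)),
                   by = .(gene_id, sample_id, origin)]
  per_sample[n_cpgs < config$min_cpgs_per_region, mean_pct := NA_real_]

  ps_split <- split(per_sample, by = "gene_id", keep.by = TRUE)
  lv_split <- split(lv, by = "gene_id", keep.by = TRUE)
  test_one <- function(g) {
    ps <- ps_split[[g]]
    agm <- ps[origin == "androgenetic" & !is.na(mean_pct), mean_pct]
    pgm <- ps[origin == "parthenogenetic" & !is.na(mean_pct), mean_pct]
    ok_ag <- ps[origin == "androgenetic" & !is.na(mean_pct), sample_id]
    ok_pg <- ps[origin == "parthenogenetic" & !is.na(mean_pct), sample_id]
    sub <- lv_split[[g]]
    res <- test_promoter(agm, pgm,
                         ag_levels = sub[sample_id %in% ok_ag, level],
                         pg_levels = sub[sample_id %in% ok_pg, level],
                         mode = config$test_mode)
    if (is.null(res)) return(NULL)
    data.table(gene_id = g, delta_pp = res$delta_pp, p_value = res$p_value)
  }
  genes <- unique(per_sample$gene_id)
  tests <- rbindlist(Filter(Negate(is.null), lapply(genes, test_one)))
  if (nrow(tests) == 0) {
    warning("no testable promoters; empty DMR output")
    return(list(tests = tests, calls = tests, test_mode = config$test_mode))
  }
  tests[, q_value := p.adjust(p_value, method = "BH")]
  tests <- merge(tests, windows[, .(gene_id, chrom, win_start, win_end)],
                 by = "gene_id")
  tests[, called := q_value <= config$dmr_alpha &
          abs(delta_pp) >= config$dmr_min_delta_pp]
  calls <- tests[called == TRUE]
  calls[, direction := ifelse(delta_pp > 0, "paternal", "maternal")]
  setorder(calls, chrom, win_start)
  list(tests = tests[], calls = calls[], test_mode = config$test_mode)
}
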