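#' Pipeline configuration
#'
#' Bundles every tunable threshold of the imprinting screen in one validated
#' object.  Defaults follow the published workflow the package implements:
#' promoter windows of TSS +/- 500 bp, a "normal" methylation band of 30--70
#' percent for known-DMR QC, a QC pass rule of at least half of assessable
#' known DMRs normal, FDR 0.05 for DMR and expression calls, allelic-ratio
#' cut-offs of 0.15 (monoallelic) and 0.3 (partially monoallelic), a minimum
#' of more than 5 reads per SNP (20 in stringent mode), 1-kb germline-DMR
#' scan windows with 200-kb region flanks, and a 500-kb cluster radius
#' (a 1-Mb window around a stringent hit's TSS).
#'
#' @param promoter_flank_bp Promoter half-width around the TSS, bp.
#' @param qc_normal_range Inclusive percent band considered normal methylation
#'   at a known imprinted DMR.
#' @param qc_min_fraction Minimum fraction of assessable known DMRs that must
#'   be normal for a sample to pass QC.
#' @param dmr_alpha BH FDR threshold for DMR calls (promoter and germline).
#' @param dmr_min_delta_pp Minimum absolute group methylation difference, in
#'   percentage points, for a reported DMR call.
#' @param min_cpgs_per_region Minimum informative CpGs for a regional mean.
#' @param min_cov_per_cpg Minimum reads at a CpG for it to be informative.
#' @param expressed_tpm A gene is expressed at a stage if TPM strictly exceeds
#'   this value in at least two samples of the stage.
#' @param ase_min_reads Minimum SNP read total for ASE classification
#'   (default 6, i.e. more than 5 reads).
#' @param ase_stringent_reads SNP read total required in stringent ASE mode.
#' @param ase_mono Allelic ratio strictly below this is monoallelic.
#' @param ase_partial Allelic ratio in [ase_mono, ase_partial] is partially
#'   monoallelic; above it, biallelic.
#' @param gdmr_window_bp Width of germline-DMR scan tiles, bp.
#' @param gdmr_flank_bp Flank added around anchor genes for the scan region.
#' @param gdmr_persistence_alpha Permutation p-value threshold for calling a
#'   germline window persistent in uniparental cells.
#' @param cluster_radius_bp Radius of the TSS neighbourhood searched around
#'   tier-1 candidates (500 kb = a 1-Mb window).
#' @param expr_alpha BH FDR threshold for imprinted-like expression calls.
#' @param test_mode Promoter test unit: "cpg_level" pools per-sample per-CpG
#'   levels (default); "sample_mean" ranks per-sample promoter means.
#' @param merge_strands Merge opposite-strand CpG calls at a dyad by summing
#'   counts on ingest.
#' @param perm_max_exact Enumerate all label assignments when their number is
#'   at most this; otherwise Monte-Carlo.
#' @param perm_n_mc Monte-Carlo permutation draws.
#' @param rng_seed Seed recorded in run manifests and used by stochastic steps.
#'
#' @return A validated list of class `uniprint_config`.
#' @export
pipeline_config <- function(promoter_flank_bp = 500L,
                            qc_normal_range = c(30, 70),
                            qc_min_fraction = 0.5,
                            dmr_alpha = 0.05,
                            dmr_min_delta_pp = 25,
                            min_cpgs_per_region = 3L,
                            min_cov_per_cpg = 5L,
                            expressed_tpm = 1,
                            ase_min_reads = 6L,
                            ase_stringent_reads = 20L,
                            ase_mono = 0.15,
                            ase_partial = 0.3,
                            gdmr_window_bp = 1000L,
                            gdmr_flank_bp = 200000L,
                            gdmr_persistence_alpha = 0.05,
                            cluster_radius_bp = 500000L,
                            expr_alpha = 0.05,
                            test_mode = c("cpg_level", "sample_mean"),
                            merge_strands = TRUE,
                            perm_max_exact = 20000L,
                            perm_n_mc = 10000L,
                            rng_seed = 1L) {
  test_mode <- match.arg(test_mode)
  cfg <- list(
    promoter_flank_bp = as.integer(promoter_flank_bp),
    qc_normal_range = as.numeric(qc_normal_range),
    qc_min_fraction = qc_min_fraction,
    dmr_alpha = dmr_alpha,
    dmr_min_delta_pp = dmr_min_delta_pp,
    min_cpgs_per_region = as.integer(min_cpgs_per_region),
    min_cov_per_cpg = as.integer(min_cov_per_cpg),
    expressed_tpm = expressed_tpm,
    ase_min_reads = as.integer(ase_min_reads),
    ase_stringent_reads = as.integer(ase_stringent_reads),
    ase_mono = ase_mono,
    ase_partial = ase_partial,
    gdmr_window_bp = as.integer(gdmr_window_bp),
    gdmr_flank_bp = as.integer(gdmr_flank_bp),
    gdmr_persistence_alpha = gdmr_persistence_alpha,
    cluster_radius_bp = as.integer(cluster_radius_bp),
    expr_alpha = expr_alpha,
    test_mode = test_mode,
    merge_strands = isTRUE(merge_strands),
    perm_max_exact = as.integer(perm_max_exact),
    perm_n_mc = as.integer(perm_n_mc),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  class(cfg) <- "uniprint_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$promoter_flank_bp > 0,
    length(cfg$qc_normal_range) == 2,
    cfg$qc_normal_range[1] >= 0, cfg$qc_normal_range[2] <= 100,
    cfg$qc_normal_range[1] < cfg$qc_normal_range[2],
    cfg$qc_min_fraction > 0, cfg$qc_min_fraction <= 1,
    cfg$dmr_alpha > 0, cfg$dmr_alpha <= 1,
    cfg$dmr_min_delta_pp >= 0, cfg$dmr_min_delta_pp <= 100,
    cfg$min_cpgs_per_region >= 1,
    cfg$min_cov_per_cpg >= 1,
    cfg$expressed_tpm >= 0,
    cfg$ase_min_reads >= 1,
    cfg$ase_stringent_reads >= cfg$ase_min_reads,
    cfg$ase_mono > 0, cfg$ase_mono < cfg$ase_partial, cfg$ase_partial <= 0.5,
    cfg$gdmr_window_bp > 0,
    cfg$gdmr_flank_bp >= 0,
    cfg$gdmr_persistence_alpha > 0, cfg$gdmr_persistence_alpha <= 1,
    cfg$cluster_radius_bp > 0,
    cfg$expr_alpha > 0, cfg$expr_alpha <= 1,
    cfg$perm_max_exact >= 1,
    cfg$perm_n_mc >= 100
  )
  invisible(cfg)
}

#' @export
print.uniprint_config <- function(x, ...) {
  cat("uniprint pipeline configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
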