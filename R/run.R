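#' Run the complete imprinting screen
#'
#' Executes the stages in dependency order on one bundle of inputs:
#' registry QC (biparental samples only, by default; uniparental samples
#' legitimately show extreme methylation at imprinted DMRs), expression
#' normalisation and imprinted-like classification per stage, promoter DMR
#' calling over the expressed universe, ASE summaries and isoform flags,
#' the germline-DMR scan with persistence and origin classification, and
#' candidate integration.  Every threshold used is recorded in the returned
#' run manifest; with a fixed configuration and seed the output is
#' reproducible byte for byte.
#'
#' @param data List with elements: `methylomes` (list of
#'   `methylome_sample`), `counts` (genes x samples), `col_data`
#'   (sample_id, origin, stage for the count columns), `lengths` (per-gene
#'   transcript lengths, for TPM), `annotation` (a `gene_annotation`), and
#'   optionally `ase` (ASE table), `germ` (gamete methylomes), `windows`
#'   (scan tiles) or `scan_anchors` (gene ids; tiles are then built with
#'   [make_scan_region()]), and `registry` (known-DMR table for QC).
#'   [simulate_study()] emits this shape directly.
#' @param config A [pipeline_config()].
#' @param qc_origins Origins the registry QC gate applies to.
#' @param gdmr_use_nominal Use the nominal (unadjusted p) putative germline
#'   window set for annotation; appropriate for small gamete panels where
#'   the minimum attainable permutation p cannot survive BH.
#' @return List: candidates, dmr_only, promoter (tests + calls), expression
#'   (per stage), expressed universe, ase_summary, isoform_flags,
#'   gdmr_scan, gdmr_calls, dmr_origin, qc, manifest.
#' @export
run_all <- function(data, config = pipeline_config(),
                    qc_origins = "biparental", gdmr_use_nominal = TRUE) {
  t0 <- Sys.time()
  for (req in c("methylomes", "counts", "col_data", "annotation")) {
    if (is.null(data[[req]])) stop("missing pipeline input: ", req)
  }
  annotation <- data$annotation
  methylomes <- data$methylomes

  ## stage 1: registry QC
  qc <- NULL
  if (!is.null(data$registry)) {
    gated <- Filter(function(s) s$origin %in% qc_origins, methylomes)
    qc <- rbindlist(lapply(gated, function(s) {
      res <- tryCatch(qc_pass(s, data$registry, config), error = function(e) NULL)
      if (is.null(res)) {
        # no assessable registry DMR: unassessable, excluded like a failure
        data.table(sample_id = s$sample_id, pass = NA,
                   n_normal = NA_integer_, n_assessable = 0L)
      } else {
        data.table(sample_id = s$sample_id, pass = res$pass,
                   n_normal = res$n_normal, n_assessable = res$n_assessable)
      }
    }))
    failed <- qc[is.na(pass) | pass == FALSE, sample_id]
    if (length(failed)) {
      message("QC-excluded sample(s): ", paste(failed, collapse = ", "))
      methylomes <- Filter(function(s) !s$sample_id %in% failed, methylomes)
    }
  }

  ## stage 2: expression
  counts <- data$counts
  col_data <- as.data.table(data$col_data)
  lens <- data$lengths[rownames(counts)]
  tpm_mat <- tpm(counts, lens)
  stages <- intersect(c("ESC", "NPC"), unique(col_data$stage))
  expressed <- lapply(setNames(stages, stages), function(st) {
    expressed_filter(tpm_mat, col_data$stage[match(colnames(counts),
                                                   col_data$sample_id)],
                     st, config)
  })
  expression_calls <- rbindlist(lapply(stages, function(st) {
    cols <- col_data[stage == st]
    cts <- counts[, cols$sample_id, drop = FALSE]
    tests <- nb_exact_test(cts, cols$origin)
    classify_imprinted_expression(tests, expressed[[st]], stage = st, config)
  }))

  ## stage 3: promoter DMRs over the expressed universe
  universe <- unique(unlist(expressed))
  dmr <- call_promoter_dmrs(methylomes, annotation, universe, config)

  ## stage 4: ASE
  ase_summary <- NULL
  iso_flags <- NULL
  if (!is.null(data$ase) && nrow(as.data.table(data$ase))) {
    ase_summary <- gene_ase_summary(data$ase, config)
    iso_flags <- isoform_specific_flag(data$ase, config)
  }

  ## stage 5: germline-DMR scan
  gdmr_scan_tab <- NULL
  gdmr_calls <- NULL
  dmr_origin <- NULL
  if (!is.null(data$germ) && length(data$germ)) {
    windows <- data$windows
    if (is.null(windows)) {
      anchors <- data$scan_anchors
      if (is.null(anchors)) {
        # default anchors: tier-relevant genes are unknown yet, so use the
        # promoter-DMR genes on the most-hit chromosome
        calls <- dmr$calls
        if (nrow(calls) >= 2) {
          top_chrom <- calls[, .N, by = chrom][order(-N)][1, chrom]
          anchors <- calls[chrom == top_chrom, gene_id]
        }
      }
      if (!is.null(anchors) && length(anchors) >= 1) {
        region <- make_scan_region(anchors, annotation, config$gdmr_flank_bp)
        windows <- make_windows(region, config$gdmr_window_bp)
      }
    }
    if (!is.null(windows)) {
      gdmr_scan_tab <- scan_gdmrs(data$germ, windows, config)
      if (nrow(gdmr_scan_tab)) {
        putative <- call_gdmrs(gdmr_scan_tab, config,
                               use_nominal = gdmr_use_nominal)
        gdmr_calls <- persistence_check(putative, methylomes, windows, config)
        dmr_origin <- classify_dmr_origin(dmr$calls, gdmr_calls)
      }
    }
  }

  ## stage 6: integration
  assembled <- assemble_candidates(
    dmr$calls, expression_calls, ase_summary, iso_flags,
    if (!is.null(gdmr_calls)) gdmr_calls[persistent == TRUE] else NULL,
    annotation, config)

  manifest <- run_manifest(config, data)
  list(candidates = assembled$candidates, dmr_only = assembled$dmr_only,
       promoter = dmr, expression = expression_calls, expressed = expressed,
       ase_summary = ase_summary, isoform_flags = iso_flags,
       gdmr_scan = gdmr_scan_tab, gdmr_calls = gdmr_calls,
       dmr_origin = dmr_origin, qc = qc,
       manifest = c(manifest, list(elapsed_s = as.numeric(
         difftime(Sys.time(), t0, units = "secs")))))
}

#' Machine-readable run manifest
#'
#' Snapshot of the configuration, input dimensions and package version;
#' emitted with every [run_all()] result and serialisable to JSON.
#'
#' @param config A [pipeline_config()].
#' @param data The input bundle.
#' @return List.
#' @export
run_manifest <- function(config, data) {
  list(
    package = "uniprint",
    version = as.character(utils::packageVersion("uniprint")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$rng_seed,
    config = unclass(config),
    inputs = list(
      n_methylomes = length(data$methylomes),
      n_germ = length(data$germ),
      counts_dim = dim(data$counts),
      n_ase_records = if (is.null(data$ase)) 0L else nrow(as.data.table(data$ase)),
      n_transcripts = nrow(as.data.table(data$annotation))
    )
  )
}

#' Write a run manifest as JSON
#' @param manifest From [run_manifest()] or a [run_all()] result's
#'   `manifest` element.
#' @param path Output path.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
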