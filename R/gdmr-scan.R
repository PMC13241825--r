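#' Scan region spanning anchor genes plus flanks
#'
#' The region runs from the smallest anchor transcript start minus the flank
#' to the largest anchor end plus the flank, clipped at zero.  All anchors
#' must lie on one chromosome.
#'
#' @param anchor_genes Character vector of gene ids.
#' @param annotation A `gene_annotation`.
#' @param flank_bp Flank in bp (default 200 kb).
#' @return A `genomic_interval`.
#' @export
make_scan_region <- function(anchor_genes, annotation, flank_bp = 200000L) {
  ann <- as.data.table(annotation)[gene_id %in% anchor_genes]
  if (nrow(ann) == 0) stop("no anchor gene found in annotation")
  missing <- setdiff(anchor_genes, ann$gene_id)
  if (length(missing)) stop("anchors absent from annotation: ",
                            paste(missing, collapse = ", "))
  if (length(unique(ann$chrom)) != 1) {
    stop("anchor genes lie on different chromosomes: ",
         paste(unique(ann$chrom), collapse = ", "))
  }
  genomic_interval(ann$chrom[1], max(0L, min(ann$start) - flank_bp),
                   max(ann$end) + flank_bp)
}

#' Tile a region into fixed-width scan windows
#'
#' Consecutive non-overlapping tiles aligned to multiples of the window
#' width, intersected with the region; the first and last tiles may be
#' short.  Tiles reassemble the region exactly.
#'
#' @param region A `genomic_interval` (or list with chrom/start/end).
#' @param window_bp Tile width in bp.
#' @return data.table: window_id, chrom, start, end.
#' @export
make_windows <- function(region, window_bp = 1000L) {
  w <- as.integer(window_bp)
  first <- floor(region$start / w) * w
  starts <- seq(first, region$end - 1, by = w)
  dt <- data.table(chrom = region$chrom,
                   start = pmax(as.numeric(region$start), starts),
                   end = pmin(as.numeric(region$end), starts + w))
  dt <- dt[end > start]
  dt[, window_id := sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))]
  setcolorder(dt, c("window_id", "chrom", "start", "end"))
  dt[]
}

#' Exact / Monte-Carlo permutation test for a group mean difference
#'
#' The statistic is the absolute difference of group means.  When the number
#' of distinct label assignments choose(nA+nB, nA) is at most `max_exact`,
#' all assignments are enumerated and the p-value is the fraction with a
#' statistic at least the observed one (the observed assignment is always
#' included, so p >= 1/N).  Otherwise `n_mc` Monte-Carlo draws are taken
#' with an add-one correction, p = (b + 1) / (n_mc + 1).
#'
#' @param a,b Numeric vectors (per-sample window methylation, one group each).
#' @param max_exact Enumeration cap on the number of assignments.
#' @param n_mc Monte-Carlo draws when enumeration is too large.
#' @return List: p_value, stat (observed |mean(a) - mean(b)|), exact,
#'   n_assignments.
#' @export
permutation_test <- function(a, b, max_exact = 20000L, n_mc = 10000L) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  n_assign <- choose(n, na)
  tol <- 1e-12
  if (n_assign <= max_exact) {
    idx <- combn(n, na)
    total <- sum(pool)
    stats <- apply(idx, 2, function(i) {
      sa <- sum(pool[i])
      abs(sa / na - (total - sa) / (n - na))
    })
    p <- sum(stats >= obs - tol) / n_assign
    list(p_value = p, stat = obs, exact = TRUE, n_assignments = n_assign)
  } else {
    hits <- 0L
    for (k in seq_len(n_mc)) {
      i <- sample.int(n, na)
      sa <- sum(pool[i])
      if (abs(sa / na - (sum(pool) - sa) / (n - na)) >= obs - tol) hits <- hits + 1L
    }
    list(p_value = (hits + 1) / (n_mc + 1), stat = obs, exact = FALSE,
         n_assignments = n_assign)
  }
}

# Per-sample pooled methylation fraction of each window for a list of
# methylome samples.  Windows tile one chromosome, so assignment is integer
# division on position.
window_sample_meth <- function(samples, windows, min_cov, min_cpgs) {
  win <- as.data.table(windows)
  res <- rbindlist(lapply(samples, function(s) {
    calls <- s$calls[chrom == win$chrom[1]]
    calls <- calls[meth + unmeth >= min_cov]
    if (nrow(calls) == 0) return(data.table())
    calls[, `:=`(p1 = pos, p2 = pos)]
    w2 <- copy(win)
    setkey(w2, chrom, start, end)
    hits <- foverlaps(calls[, .(chrom, p1, p2, meth, unmeth)], w2,
                      by.x = c("chrom", "p1", "p2"), nomatch = NULL)
    if (nrow(hits) == 0) return(data.table())
    hits[, .(sample_id = s$sample_id, origin = s$origin,
             n_cpgs = .N, frac = sum(meth) / sum(meth + unmeth)),
         by = .(window_id)]
  }))
  if (nrow(res) == 0) return(res)
  res[n_cpgs < min_cpgs, frac := NA_real_]
  res[]
}

#' Scan windows for sperm-versus-oocyte germline DMRs
#'
#' For every tile with at least `min_cpgs_per_region` covered CpGs in at
#' least two samples of each gamete, the absolute difference of gamete group
#' means is tested by exact (or Monte-Carlo) permutation; BH FDR is applied
#' over the tested windows, and windows are additionally marked "nominal"
#' at unadjusted p <= 0.05 with the delta gate.  With small gamete panels
#' (four sperm versus three oocytes gives a minimum attainable p of 1/35)
#' the BH-significant set is empty over any realistic universe; the nominal
#' set is the putative-gDMR readout in that regime.
#'
#' @param germ_samples List of `methylome_sample`s with origins sperm/oocyte.
#' @param windows Tiles from [make_windows()].
#' @param config A [pipeline_config()].
#' @return data.table per tested window: window_id, chrom, start, end,
#'   sperm_mean, oocyte_mean, delta_pp, stat, p_value, q_value,
#'   germ_direction, called (BH + delta), nominal (p + delta), n_tested.
#' @export
scan_gdmrs <- function(germ_samples, windows, config = pipeline_config()) {
  origins <- vapply(germ_samples, `[[`, "", "origin")
  if (sum(origins == "sperm") < 2 || sum(origins == "oocyte") < 2) {
    stop("need >= 2 sperm and >= 2 oocyte samples")
  }
  wm <- window_sample_meth(germ_samples, windows,
                           config$min_cov_per_cpg, config$min_cpgs_per_region)
  if (nrow(wm) == 0) return(data.table())
  wm <- wm[!is.na(frac)]
  counts <- wm[, .(n_sperm = sum(origin == "sperm"),
                   n_oocyte = sum(origin == "oocyte")), by = window_id]
  testable <- counts[n_sperm >= 2 & n_oocyte >= 2, window_id]
  wm <- wm[window_id %in% testable]
  if (nrow(wm) == 0) return(data.table())
  res <- wm[, {
    sp <- frac[origin == "sperm"]
    oo <- frac[origin == "oocyte"]
    pt <- permutation_test(sp, oo, config$perm_max_exact, config$perm_n_mc)
    .(sperm_mean = 100 * mean(sp), oocyte_mean = 100 * mean(oo),
      delta_pp = 100 * (mean(sp) - mean(oo)), stat = 100 * pt$stat,
      p_value = pt$p_value)
  }, by = window_id]
  res[, q_value := p.adjust(p_value, method = "BH")]
  res[, germ_direction := ifelse(delta_pp > 0, "sperm_methylated",
                                 "oocyte_methylated")]
  res[, called := q_value <= config$dmr_alpha &
        abs(delta_pp) >= config$dmr_min_delta_pp]
  res[, nominal := p_value <= 0.05 & abs(delta_pp) >= config$dmr_min_delta_pp]
  res[, n_tested := .N]
  out <- merge(as.data.table(windows), res, by = "window_id")
  setorder(out, chrom, start)
  out[]
}

#' Call germ-significant windows
#'
#' Filters a scan table to its BH-significant rows (q <= dmr_alpha and the
#' delta gate); set `use_nominal = TRUE` to fall back to the nominal
#' (unadjusted p <= 0.05) putative set appropriate for small gamete panels.
#'
#' @param scan Output of [scan_gdmrs()].
#' @param config A [pipeline_config()].
#' @param use_nominal Return nominal putative windows instead of BH calls.
#' @return data.table of called windows.
#' @export
call_gdmrs <- function(scan, config = pipeline_config(), use_nominal = FALSE) {
  if (nrow(scan) == 0) {
    warning("empty gDMR scan input")
    return(scan)
  }
  if (use_nominal) scan[nominal == TRUE] else scan[called == TRUE]
}

#' Persistence of a germline DMR in uniparental cells
#'
#' Re-tests called germ windows on androgenetic-versus-parthenogenetic
#' per-sample window methylation with the same permutation machinery.  A
#' window is persistent when the uniparental p-value is at most
#' `gdmr_persistence_alpha` and the direction is concordant with the gamete
#' direction (oocyte-methylated windows must be parthenogenetic-
#' hypermethylated; sperm-methylated, androgenetic-hypermethylated).
#'
#' @param gdmr_calls Called windows from [call_gdmrs()].
#' @param samples List of `methylome_sample`s (androgenetic/parthenogenetic
#'   members used).
#' @param windows The tile table used for the scan.
#' @param config A [pipeline_config()].
#' @return `gdmr_calls` with ag_mean, pg_mean, uniparental_p, persistent.
#' @export
persistence_check <- function(gdmr_calls, samples, windows,
                              config = pipeline_config()) {
  if (nrow(gdmr_calls) == 0) {
    return(cbind(gdmr_calls, data.table(ag_mean = numeric(),
                                        pg_mean = numeric(),
                                        uniparental_p = numeric(),
                                        persistent = logical())))
  }
  origins <- vapply(samples, `[[`, "", "origin")
  uni <- samples[origins %in% c("androgenetic", "parthenogenetic")]
  wm <- window_sample_meth(uni, windows, config$min_cov_per_cpg,
                           config$min_cpgs_per_region)
  res <- lapply(seq_len(nrow(gdmr_calls)), function(i) {
    wid <- gdmr_calls$window_id[i]
    sub <- wm[window_id == wid & !is.na(frac)]
    agv <- sub[origin == "androgenetic", frac]
    pgv <- sub[origin == "parthenogenetic", frac]
    if (length(agv) < 2 || length(pgv) < 2) {
      return(data.table(ag_mean = NA_real_, pg_mean = NA_real_,
                        uniparental_p = NA_real_, persistent = FALSE))
    }
    pt <- permutation_test(agv, pgv, config$perm_max_exact, config$perm_n_mc)
    dir_concordant <- if (gdmr_calls$germ_direction[i] == "oocyte_methylated") {
      mean(pgv) > mean(agv)
    } else {
      mean(agv) > mean(pgv)
    }
    data.table(ag_mean = 100 * mean(agv), pg_mean = 100 * mean(pgv),
               uniparental_p = pt$p_value,
               persistent = pt$p_value <= config$gdmr_persistence_alpha &&
                 dir_concordant)
  })
  out <- cbind(gdmr_calls, rbindlist(res))
  out[, origin_class := ifelse(persistent, "germline_candidate",
                               "germline_non_persistent")]
  out[]
}

#' Classify promoter DMRs as germline-derived or secondary
#'
#' A uniparental promoter DMR overlapping a concordant germ-significant
#' window is germline-derived (oocyte-methylated germ window with a
#' maternal-direction promoter DMR, or sperm-methylated with paternal);
#' one overlapping no germ-significant window is secondary.  Germ windows
#' without any overlapping uniparental DMR are germline_non_persistent.
#'
#' @param promoter_calls DMR calls from [call_promoter_dmrs()].
#' @param gdmr_calls Germ-significant windows (ideally after
#'   [persistence_check()]).
#' @return List: `dmr_origin` (per promoter DMR: gene_id, origin_class,
#'   gdmr_window) and `orphan_gdmrs` (germ windows with no uniparental DMR).
#' @export
classify_dmr_origin <- function(promoter_calls, gdmr_calls) {
  promoter_calls <- as.data.table(promoter_calls)
  gdmr_calls <- as.data.table(gdmr_calls)
  if (nrow(promoter_calls) == 0) {
    return(list(dmr_origin = data.table(gene_id = character(),
                                        origin_class = character(),
                                        gdmr_window = character()),
                orphan_gdmrs = gdmr_calls))
  }
  matched_windows <- character()
  origin <- vapply(seq_len(nrow(promoter_calls)), function(i) {
    pc <- promoter_calls[i]
    if (nrow(gdmr_calls) == 0) return("secondary")
    ov <- gdmr_calls[chrom == pc$chrom & start < pc$win_end & end > pc$win_start]
    if (nrow(ov) == 0) return("secondary")
    concord <- (pc$direction == "maternal" &
                  ov$germ_direction == "oocyte_methylated") |
      (pc$direction == "paternal" & ov$germ_direction == "sperm_methylated")
    if (any(concord)) {
      matched_windows <<- c(matched_windows, ov$window_id[concord])
      "germline_derived"
    } else "secondary"
  }, character(1))
  window_hit <- vapply(seq_len(nrow(promoter_calls)), function(i) {
    pc <- promoter_calls[i]
    if (nrow(gdmr_calls) == 0) return(NA_character_)
    ov <- gdmr_calls[chrom == pc$chrom & start < pc$win_end & end > pc$win_start]
    if (nrow(ov) == 0) NA_character_ else ov$window_id[1]
  }, character(1))
  orphans <- if (nrow(gdmr_calls)) {
    gdmr_calls[!window_id %in% matched_windows]
  } else gdmr_calls
  list(dmr_origin = data.table(gene_id = promoter_calls$gene_id,
                               origin_class = origin,
                               gdmr_window = window_hit),
       orphan_gdmrs = orphans)
}
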