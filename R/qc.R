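#' Pooled mean methylation of a region
#'
#' The regional mean is the pooled-count ratio sum(meth) / sum(meth + unmeth)
#' over CpGs inside the region whose per-CpG coverage reaches `min_cov`,
#' expressed in percent.  Regions with fewer informative CpGs than
#' `min_cpgs` yield NA ("no data") — a value, not an error, so sparse RRBS
#' coverage degrades gracefully.
#'
#' @param sample A `methylome_sample`.
#' @param chrom,start,end Region in 0-based half-open coordinates.
#' @param min_cov Minimum reads per CpG to count it as informative.
#' @param min_cpgs Minimum informative CpGs for a defined mean.
#' @return List with `mean_percent` (NA if no data) and `n_cpgs`.
#' @export
mean_meth_in_region <- function(sample, chrom, start, end,
                                min_cov = 5L, min_cpgs = 3L) {
  region_chrom <- chrom; region_start <- start; region_end <- end
  calls <- sample$calls
  sub <- calls[chrom == region_chrom & pos >= region_start & pos < region_end]
  sub <- sub[meth + unmeth >= min_cov]
  if (nrow(sub) < min_cpgs) {
    return(list(mean_percent = NA_real_, n_cpgs = nrow(sub)))
  }
  list(mean_percent = 100 * sum(sub$meth) / sum(sub$meth + sub$unmeth),
       n_cpgs = nrow(sub))
}

#' Classify a known-DMR methylation level
#'
#' Normal iff the mean lies inside the configured band (inclusive; default
#' 30--70 percent); above it hypermethylated, below it hypomethylated.
#'
#' @param mean_percent Regional mean methylation in percent.
#' @param config A [pipeline_config()].
#' @return "normal", "hyper" or "hypo" (vectorised; NA in, NA out).
#' @export
classify_dmr_status <- function(mean_percent, config = pipeline_config()) {
  lo <- config$qc_normal_range[1]
  hi <- config$qc_normal_range[2]
  ifelse(is.na(mean_percent), NA_character_,
         ifelse(mean_percent < lo, "hypo",
                ifelse(mean_percent > hi, "hyper", "normal")))
}

#' Read a known-imprinted-DMR registry (BED6+2)
#'
#' Columns: chrom, start, end, name, score, strand, germline origin
#' (paternal/maternal), notes.  Comment lines starting with `#` are skipped.
#'
#' @param path BED path.
#' @return data.table with chrom, start, end, name, origin, notes.
#' @export
read_dmr_registry <- function(path) {
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   comment.char = "#")
  if (ncol(df) < 7) stop("registry BED needs at least 7 columns (BED6 + origin)")
  reg <- data.table(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), name = as.character(df[[4]]),
                    origin = as.character(df[[7]]),
                    notes = if (ncol(df) >= 8) as.character(df[[8]]) else "")
  if (!all(reg$origin %in% c("paternal", "maternal"))) {
    stop("registry origin column must be 'paternal' or 'maternal'")
  }
  if (any(reg$start < 0 | reg$end <= reg$start)) stop("invalid registry interval")
  reg[]
}

#' Default registry of well-known imprinted DMRs
#'
#' Approximate hg38 coordinates of widely studied imprinted DMRs
#' (H19/IGF2 ICR, KCNQ1OT1, MEG3, SNRPN, MKRN3, PEG3, PLAGL1, MEST, GRB10,
#' NNAT, PEG10, RB1).  Intended as a replaceable starting point for
#' registry-based QC, not as an authoritative coordinate set.
#'
#' @return data.table as from [read_dmr_registry()].
#' @export
default_dmr_registry <- function() {
  read_dmr_registry(system.file("extdata", "known_imprinted_dmrs.bed",
                                package = "uniprint"))
}

#' Score one sample against a known-DMR registry
#'
#' @param sample A `methylome_sample`.
#' @param registry Registry table from [read_dmr_registry()].
#' @param config A [pipeline_config()].
#' @return data.table: one row per registry DMR with mean_meth_percent,
#'   n_cpgs and status ("normal"/"hyper"/"hypo"/"no_data").
#' @export
dmr_status_report <- function(sample, registry, config = pipeline_config()) {
  res <- lapply(seq_len(nrow(registry)), function(i) {
    m <- mean_meth_in_region(sample, registry$chrom[i], registry$start[i],
                             registry$end[i], min_cov = config$min_cov_per_cpg,
                             min_cpgs = config$min_cpgs_per_region)
    data.table(sample_id = sample$sample_id, dmr = registry$name[i],
               mean_meth_percent = m$mean_percent, n_cpgs = m$n_cpgs,
               status = if (is.na(m$mean_percent)) "no_data"
                        else classify_dmr_status(m$mean_percent, config))
  })
  rbindlist(res)
}

#' Known-DMR inclusion filter
#'
#' A sample passes QC iff at least `qc_min_fraction` (default one half) of
#' the registry DMRs with data have normal methylation.  DMRs without data
#' are excluded from the denominator; a sample with no assessable DMR at all
#' is unassessable, which is an error.
#'
#' @param sample A `methylome_sample`.
#' @param registry Registry table.
#' @param config A [pipeline_config()].
#' @return List with `pass` (logical), `n_normal`, `n_assessable` and the
#'   per-DMR `report`.
#' @export
qc_pass <- function(sample, registry, config = pipeline_config()) {
  if (nrow(registry) == 0) stop("empty registry")
  rep <- dmr_status_report(sample, registry, config)
  assessable <- rep[status != "no_data"]
  if (nrow(assessable) == 0) {
    stop("sample ", sample$sample_id,
         " unassessable: no registry DMR has sufficient coverage")
  }
  n_normal <- sum(assessable$status == "normal")
  list(pass = (n_normal / nrow(assessable)) >= config$qc_min_fraction,
       n_normal = n_normal, n_assessable = nrow(assessable), report = rep)
}

#' Group known DMRs by their aberration pattern across origins
#'
#' Known imprinted DMRs in cultured uniparental and biparental cells show
#' three behaviours: (i) "normal-behaviour" -- the expected parent-of-origin
#' pattern (the methylated-parent group hyper, the other hypo; e.g. a
#' paternal-germline DMR near 100 percent in androgenetic and near 0 in
#' parthenogenetic cells); (ii) "retained-difference" -- the expected pattern
#' is lost but an androgenetic-versus-parthenogenetic difference of at least
#' `dmr_min_delta_pp` survives (partial loss of imprinting); (iii)
#' "uniform-hyper" -- the difference is erased as well, typically through
#' culture-driven hypermethylation of both alleles.
#'
#' @param samples List of `methylome_sample`s; needs at least two
#'   androgenetic and two parthenogenetic samples.
#' @param registry Registry table.
#' @param config A [pipeline_config()].
#' @return data.table: dmr, per-origin mean methylation, ag_pg_delta_pp, label.
#' @export
aberration_report <- function(samples, registry, config = pipeline_config()) {
  origins <- vapply(samples, `[[`, "", "origin")
  if (sum(origins == "androgenetic") < 2 || sum(origins == "parthenogenetic") < 2) {
    stop("aberration_report needs >= 2 androgenetic and >= 2 parthenogenetic samples")
  }
  hi <- config$qc_normal_range[2]
  lo <- config$qc_normal_range[1]
  res <- lapply(seq_len(nrow(registry)), function(i) {
    means <- vapply(samples, function(s) {
      mean_meth_in_region(s, registry$chrom[i], registry$start[i],
                          registry$end[i], min_cov = config$min_cov_per_cpg,
                          min_cpgs = config$min_cpgs_per_region)$mean_percent
    }, numeric(1))
    by_origin <- tapply(means, origins, mean, na.rm = TRUE)
    ag <- by_origin[["androgenetic"]]
    pg <- by_origin[["parthenogenetic"]]
    bi <- if ("biparental" %in% names(by_origin)) by_origin[["biparental"]] else NA_real_
    # expected uniparental pattern: the methylated-parent group hyper, the
    # other hypo (paternal DMR: AG high / PG low; maternal: mirrored)
    meth_parent <- if (registry$origin[i] == "paternal") ag else pg
    unmeth_parent <- if (registry$origin[i] == "paternal") pg else ag
    expected <- !is.na(meth_parent) && !is.na(unmeth_parent) &&
      meth_parent > hi && unmeth_parent < lo
    label <- if (expected) {
      "normal-behaviour"
    } else if (!is.na(ag) && !is.na(pg) &&
               abs(ag - pg) >= config$dmr_min_delta_pp) {
      "retained-difference"
    } else {
      "uniform-hyper"
    }
    data.table(dmr = registry$name[i], germline_origin = registry$origin[i],
               ag_mean = ag, pg_mean = pg, bi_mean = bi,
               ag_pg_delta_pp = ag - pg, label = label)
  })
  rbindlist(res)
}
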