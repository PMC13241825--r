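#' Allelic ratio at a heterozygous SNP
#'
#' The proportion of reads carrying the less-expressed allele relative to all
#' reads at the site: min(ref, alt) / (ref + alt), symmetric in its
#' arguments and bounded in [0, 0.5].
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @return Numeric ratio(s).
#' @export
allelic_ratio <- function(ref_count, alt_count) {
  total <- ref_count + alt_count
  if (any(total == 0)) stop("allelic ratio undefined at zero total reads")
  pmin(ref_count, alt_count) / total
}

#' Classify allele-specific expression at one SNP record
#'
#' Records below the read-depth floor (more than 5 reads by default; at
#' least 20 in stringent mode) are insufficient_reads.  Otherwise the
#' allelic ratio r classifies the record: r < 0.15 monoallelic;
#' 0.15 <= r <= 0.3 partially monoallelic; r > 0.3 biallelic.
#'
#' @param ref_count,alt_count Read counts (vectorised).
#' @param config A [pipeline_config()].
#' @param stringent Use the stringent read-depth floor.
#' @return Character vector of classes.
#' @export
classify_ase <- function(ref_count, alt_count, config = pipeline_config(),
                         stringent = FALSE) {
  total <- ref_count + alt_count
  floor_reads <- if (stringent) config$ase_stringent_reads else config$ase_min_reads
  ratio <- ifelse(total > 0, pmin(ref_count, alt_count) / total, NA_real_)
  ifelse(total < floor_reads, "insufficient_reads",
         ifelse(ratio < config$ase_mono, "monoallelic",
                ifelse(ratio <= config$ase_partial, "partially_monoallelic",
                       "biallelic")))
}

ASE_CLASS_ORDER <- c("monoallelic", "partially_monoallelic", "biallelic")

#' Per-gene ASE support summary
#'
#' Aggregates SNP-level calls per gene: the support level is the strongest
#' class among qualifying records (monoallelic > partially monoallelic >
#' biallelic), with a discordance flag when qualifying records disagree, and
#' per-class counts (their sum equals the number of qualifying records).
#'
#' @param ase ASE table as from [read_ase_table()].
#' @param config A [pipeline_config()].
#' @param stringent Use the stringent read-depth floor.
#' @return data.table: gene_id, support, discordant, n_mono, n_partial,
#'   n_biallelic, n_insufficient, n_records, cell_types.
#' @export
gene_ase_summary <- function(ase, config = pipeline_config(), stringent = FALSE) {
  ase <- as.data.table(ase)
  if (nrow(ase) == 0) {
    return(data.table(gene_id = character(), support = character(),
                      discordant = logical(), n_mono = integer(),
                      n_partial = integer(), n_biallelic = integer(),
                      n_insufficient = integer(), n_records = integer(),
                      cell_types = character()))
  }
  if (!"cell_type" %in% names(ase)) ase[, cell_type := sample_id]
  ase[, class := classify_ase(ref_count, alt_count, config, stringent)]
  ase[, .(
    support = {
      q <- class[class != "insufficient_reads"]
      if (length(q) == 0) "none" else ASE_CLASS_ORDER[min(match(q, ASE_CLASS_ORDER))]
    },
    discordant = length(unique(class[class != "insufficient_reads"])) > 1,
    n_mono = sum(class == "monoallelic"),
    n_partial = sum(class == "partially_monoallelic"),
    n_biallelic = sum(class == "biallelic"),
    n_insufficient = sum(class == "insufficient_reads"),
    n_records = .N,
    cell_types = paste(sort(unique(cell_type[class %in% ASE_CLASS_ORDER[1:2]])),
                       collapse = ",")
  ), by = gene_id][]
}

#' Isoform-specific imprinting flag
#'
#' A gene is flagged when, within a single cell type, at least one of its
#' transcripts is classified monoallelic or partially monoallelic while
#' another is biallelic.  Requiring the contrast within one cell type keeps
#' tissue-specific imprinting from masquerading as isoform-specific
#' imprinting.
#'
#' @param ase ASE table with transcript_id populated.
#' @param config A [pipeline_config()].
#' @param stringent Use the stringent read-depth floor.
#' @return data.table: gene_id, isoform_specific.
#' @export
isoform_specific_flag <- function(ase, config = pipeline_config(),
                                  stringent = FALSE) {
  ase <- as.data.table(ase)
  ase <- ase[!is.na(transcript_id)]
  if (nrow(ase) == 0) {
    return(data.table(gene_id = character(), isoform_specific = logical()))
  }
  if (!"cell_type" %in% names(ase)) ase[, cell_type := sample_id]
  ase[, class := classify_ase(ref_count, alt_count, config, stringent)]
  # transcript-level call per (gene, cell type): strongest class among records
  tx <- ase[class != "insufficient_reads",
            .(tx_class = ASE_CLASS_ORDER[min(match(class, ASE_CLASS_ORDER))]),
            by = .(gene_id, cell_type, transcript_id)]
  flags <- tx[, .(
    isoform_specific = any(tx_class %in% c("monoallelic", "partially_monoallelic")) &&
      any(tx_class == "biallelic") &&
      uniqueN(transcript_id) >= 2
  ), by = .(gene_id, cell_type)]
  flags[, .(isoform_specific = any(isoform_specific)), by = gene_id][]
}
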