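#' Concordance between a promoter DMR and an expression class
#'
#' A paternal promoter DMR (androgenetic-hypermethylated) silences the
#' paternal allele, so the maternal allele carries expression: concordant
#' with MEG-like.  A maternal DMR is concordant with PEG-like.  Any other
#' combination (including not_imprinted_like, the pattern of a gene whose
#' DMR does not translate into a parent-of-origin expression bias) is
#' discordant.
#'
#' @param dmr_direction "paternal" or "maternal" (vectorised).
#' @param expression_class One of MEG_like, PEG_like, not_imprinted_like,
#'   not_expressed.
#' @return Logical vector.
#' @export
concordance <- function(dmr_direction, expression_class) {
  (dmr_direction == "paternal" & expression_class == "MEG_like") |
    (dmr_direction == "maternal" & expression_class == "PEG_like")
}

#' Genes whose TSS lies within a radius of an anchor's TSS
#'
#' @param anchor_gene Anchor gene id.
#' @param annotation A `gene_annotation`.
#' @param radius_bp Neighbourhood radius (default 500 kb, i.e. a 1-Mb
#'   window centred on the anchor TSS).
#' @return Character vector of gene ids (anchor excluded), ordered by TSS.
#' @export
neighborhood_genes <- function(anchor_gene, annotation, radius_bp = 500000L) {
  ann <- as.data.table(annotation)
  anchor <- ann[gene_id == anchor_gene]
  if (nrow(anchor) == 0) stop("anchor gene not in annotation: ", anchor_gene)
  a_tss <- anchor$tss[1]
  a_chrom <- anchor$chrom[1]
  hits <- ann[chrom == a_chrom & abs(tss - a_tss) <= radius_bp &
                gene_id != anchor_gene]
  unique(hits[order(tss), gene_id])
}

#' Assemble the tiered candidate table
#'
#' Tier 1 (stringent): genes with a promoter DMR call, an imprinted-like
#' expression call in at least one stage, and concordance between DMR
#' direction and expression class.  Tier 2 (cluster): genes within
#' `cluster_radius_bp` of a tier-1 anchor TSS carrying either a promoter
#' DMR or imprinted-like expression.  ASE support, isoform-specific flags
#' and germline-window proximity are annotated but never gate membership.
#' Genes with a DMR but flat expression are reported separately as
#' DMR-only genes (possible isoform-specific imprinting).
#'
#' @param dmr_calls `calls` table from [call_promoter_dmrs()].
#' @param expression_calls Rows from [classify_imprinted_expression()]
#'   (multiple stages may be stacked).
#' @param ase_summaries Output of [gene_ase_summary()]; optional.
#' @param isoform_flags Output of [isoform_specific_flag()]; optional.
#' @param gdmr_calls Germ-significant windows; optional.
#' @param annotation A `gene_annotation`.
#' @param config A [pipeline_config()].
#' @return List: `candidates` (tiered table ordered by chrom, TSS) and
#'   `dmr_only` (DMR without concordant expression).
#' @export
assemble_candidates <- function(dmr_calls, expression_calls,
                                ase_summaries = NULL, isoform_flags = NULL,
                                gdmr_calls = NULL, annotation,
                                config = pipeline_config()) {
  ann <- as.data.table(annotation)[, .SD[1], by = gene_id]
  dmr <- as.data.table(dmr_calls)
  expr <- as.data.table(expression_calls)
  unknown <- setdiff(unique(c(dmr$gene_id, expr$gene_id)), ann$gene_id)
  if (length(unknown)) {
    stop("gene universes inconsistent; not in annotation: ",
         paste(head(unknown, 5), collapse = ", "))
  }

  imp <- expr[class %in% c("MEG_like", "PEG_like")]
  # best (smallest q) imprinted-like call per gene across stages
  imp_best <- if (nrow(imp)) {
    imp[order(q_value), .SD[1], by = gene_id]
  } else {
    imp
  }

  ev <- merge(dmr[, .(gene_id, dmr_direction = direction,
                      dmr_delta_pp = delta_pp, dmr_q = q_value)],
              imp_best[, .(gene_id, expression_class = class,
                           expr_log2fc = log2fc_pg_over_ag,
                           expr_q = q_value, expr_stage = stage)],
              by = "gene_id", all = TRUE)
  ev[, has_promoter_dmr := !is.na(dmr_direction)]
  ev[, has_imprinted_expression := !is.na(expression_class)]
  ev[, concordant := has_promoter_dmr & has_imprinted_expression &
       concordance(dmr_direction, expression_class)]

  tier1 <- ev[concordant == TRUE, gene_id]
  dmr_only <- ev[has_promoter_dmr & !concordant]

  # tier-2 search: relaxed criteria in the neighbourhoods of tier-1 anchors
  tier2 <- data.table(gene_id = character(), anchor_gene = character(),
                      distance_to_anchor = numeric())
  if (length(tier1)) {
    tss_of <- setNames(ann$tss, ann$gene_id)
    for (anchor in sort(tier1)) {
      nb <- neighborhood_genes(anchor, annotation, config$cluster_radius_bp)
      nb <- setdiff(nb, tier1)
      hit <- ev[gene_id %in% nb & (has_promoter_dmr | has_imprinted_expression),
                gene_id]
      if (length(hit)) {
        tier2 <- rbind(tier2, data.table(
          gene_id = hit, anchor_gene = anchor,
          distance_to_anchor = abs(tss_of[hit] - tss_of[anchor])))
      }
    }
    # a gene near several anchors keeps its nearest one
    tier2 <- tier2[order(distance_to_anchor), .SD[1], by = gene_id]
  }

  cand <- rbind(
    data.table(gene_id = tier1, tier = "1_stringent",
               anchor_gene = NA_character_, distance_to_anchor = NA_real_),
    tier2[, .(gene_id, tier = "2_cluster", anchor_gene, distance_to_anchor)]
  )
  if (nrow(cand) == 0) {
    empty <- data.table()
    return(list(candidates = empty, dmr_only = dmr_only))
  }
  cand <- merge(cand, ev, by = "gene_id", all.x = TRUE)
  cand <- merge(cand, ann[, .(gene_id, chrom, tss)], by = "gene_id")

  if (!is.null(ase_summaries) && nrow(as.data.table(ase_summaries))) {
    cand <- merge(cand, as.data.table(ase_summaries)[, .(gene_id,
                                                         ase_support = support)],
                  by = "gene_id", all.x = TRUE)
  } else {
    cand[, ase_support := NA_character_]
  }
  if (!is.null(isoform_flags) && nrow(as.data.table(isoform_flags))) {
    cand <- merge(cand, as.data.table(isoform_flags), by = "gene_id",
                  all.x = TRUE)
    cand[is.na(isoform_specific), isoform_specific := FALSE]
  } else {
    cand[, isoform_specific := FALSE]
  }
  if (!is.null(gdmr_calls) && nrow(as.data.table(gdmr_calls))) {
    gw <- as.data.table(gdmr_calls)
    cand[, near_gdmr := vapply(seq_len(.N), function(i) {
      any(gw$chrom == chrom[i] &
            pmin(gw$end, tss[i] + config$cluster_radius_bp) >
            pmax(gw$start, tss[i] - config$cluster_radius_bp))
    }, logical(1))]
  } else {
    cand[, near_gdmr := FALSE]
  }
  setorder(cand, chrom, tss)
  list(candidates = cand[], dmr_only = dmr_only[])
}
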