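#' Simulation scenario
#'
#' Defines the seeded synthetic study the generator produces: a gene panel
#' with promoter CpGs, androgenetic/parthenogenetic/biparental methylomes
#' with beta-binomial RRBS-like coverage, negative-binomial expression
#' counts, binomial SNP allele counts, and sperm/oocyte methylomes over a
#' sparsely covered scan region.  Defaults mirror the study design the
#' package analyses: 2000 genes, 4 androgenetic versus 4 parthenogenetic
#' samples (plus 2 biparental), 20 planted paternal promoter DMRs at 60
#' percentage points, 20 MEGs and 20 PEGs at 4-fold change with base mean
#' 100 and NB dispersion 0.1, a chromosome-1 cluster of 5 stringent genes
#' (DMR and expression) with 3 expression-only neighbours, 30x methylation
#' depth, 4 sperm versus 3 oocyte gamete samples, and 3 planted germline
#' DMR windows of which 2 persist in uniparental cells.
#'
#' @param seed Integer RNG seed; every generator is a pure function of the
#'   scenario including this seed.
#' @param n_genes Total genes.
#' @param n_chroms Chromosomes the panel is spread over.
#' @param gene_spacing_bp TSS-to-TSS spacing within a chromosome.
#' @param cpgs_per_promoter CpGs simulated per promoter window.
#' @param n_ag,n_pg,n_bi ESC sample counts per origin.
#' @param n_npc NPC samples per uniparental origin (share imprint truth).
#' @param depth_mean,depth_size Negative-binomial CpG depth parameters.
#' @param bg_low_mean,bg_high_mean,bg_low_weight Background methylation
#'   mixture (two beta modes and the weight of the low mode).
#' @param cpg_conc,sample_conc Beta concentrations for CpG-level and
#'   sample-level variation around the locus mean.
#' @param n_dmr_paternal,n_dmr_maternal Planted promoter DMR counts.
#' @param dmr_delta_pp Planted DMR group difference in percentage points.
#' @param n_meg,n_peg Planted imprinted-expression gene counts.
#' @param expr_fold Planted expression fold change.
#' @param planted_base_mean Base mean count of planted expression genes.
#' @param nb_dispersion NB dispersion of counts.
#' @param silent_fraction Fraction of background genes essentially silent.
#' @param n_stringent,n_neighbors Cluster geometry on chromosome 1:
#'   stringent genes carry both a paternal DMR and MEG-like expression;
#'   neighbours carry expression only.
#' @param n_sperm,n_oocyte Gamete methylome sample counts.
#' @param n_covered_windows Scan windows with gamete/ESC coverage (RRBS
#'   sparsity); planted germline windows are always covered.
#' @param n_gdmr,n_gdmr_persistent Planted (oocyte-methylated) germline
#'   windows and how many persist in uniparental cells.
#' @param gdmr_high,gdmr_low Gamete methylation levels at planted windows.
#' @param ase_depth_mean ASE SNP depth mean.
#' @param ase_leakage Minor-allele probability at monoallelic loci.
#' @param n_ase_biallelic Background genes given biallelic ASE records.
#' @param n_isoform_specific Genes planted with one monoallelic and one
#'   biallelic transcript.
#' @param n_snps_per_gene SNPs per gene per cell type in the ASE table.
#' @return List of class `simulation_scenario`.
#' @export
simulation_scenario <- function(seed = 1L,
                                n_genes = 2000L, n_chroms = 4L,
                                gene_spacing_bp = 100000L,
                                cpgs_per_promoter = 12L,
                                n_ag = 4L, n_pg = 4L, n_bi = 2L, n_npc = 0L,
                                depth_mean = 30, depth_size = 4,
                                bg_low_mean = 0.15, bg_high_mean = 0.85,
                                bg_low_weight = 0.6,
                                cpg_conc = 30, sample_conc = 50,
                                n_dmr_paternal = 20L, n_dmr_maternal = 0L,
                                dmr_delta_pp = 60,
                                n_meg = 20L, n_peg = 20L, expr_fold = 4,
                                planted_base_mean = 100,
                                nb_dispersion = 0.1,
                                silent_fraction = 0.15,
                                n_stringent = 5L, n_neighbors = 3L,
                                n_sperm = 4L, n_oocyte = 3L,
                                n_covered_windows = 30L,
                                n_gdmr = 3L, n_gdmr_persistent = 2L,
                                gdmr_high = 0.9, gdmr_low = 0.1,
                                ase_depth_mean = 30,
                                ase_leakage = 0.05,
                                n_ase_biallelic = 20L,
                                n_isoform_specific = 2L,
                                n_snps_per_gene = 2L) {
  sc <- as.list(environment())
  stopifnot(sc$n_genes >= 100, sc$dmr_delta_pp > 0, sc$dmr_delta_pp <= 100,
            sc$expr_fold > 0, sc$ase_leakage >= 0, sc$ase_leakage <= 1,
            sc$bg_low_weight >= 0, sc$bg_low_weight <= 1,
            sc$n_gdmr_persistent <= sc$n_gdmr,
            sc$n_stringent >= 0, sc$n_neighbors <= 3)
  class(sc) <- "simulation_scenario"
  sc
}

# Deterministic layout shared by every generator: annotation, planted-gene
# assignments and window truth.  Consumes RNG from set.seed(seed), so every
# generator recomputes it identically before reseeding for its own noise.
scenario_layout <- function(sc) {
  set.seed(sc$seed)
  n <- sc$n_genes
  per_chrom <- ceiling(n / sc$n_chroms)
  idx <- seq_len(n)
  chrom_i <- (idx - 1) %/% per_chrom + 1
  within <- (idx - 1) %% per_chrom + 1
  tss <- 100000L + (within - 1L) * sc$gene_spacing_bp
  gene_id <- sprintf("G%04d", idx)
  strand <- sample(c("+", "-"), n, replace = TRUE, prob = c(0.7, 0.3))
  tx_len <- sample(1000:4000, n, replace = TRUE)
  ann <- data.table(
    gene_id = gene_id, gene_name = gene_id,
    transcript_id = paste0(gene_id, ".t1"),
    chrom = paste0("chr", chrom_i),
    start = ifelse(strand == "+", tss, tss - tx_len + 1L),
    end = ifelse(strand == "+", tss + tx_len, tss + 1L),
    strand = strand
  )

  # cluster on chr1: stringent anchors at odd within-chrom slots 21..29,
  # expression-only neighbours interleaved at 22, 24, 26
  stringent_slots <- seq(21L, by = 2L, length.out = sc$n_stringent)
  neighbor_slots <- seq(22L, by = 2L, length.out = sc$n_neighbors)
  on_chr1 <- which(chrom_i == 1)
  stringent <- gene_id[on_chr1[stringent_slots]]
  neighbors <- gene_id[on_chr1[neighbor_slots]]
  # keep random planting away from the cluster neighbourhoods
  exclusion <- gene_id[on_chr1[within[on_chr1] >= 10 & within[on_chr1] <= 40]]
  pool <- setdiff(gene_id, c(stringent, neighbors, exclusion))

  dmr_pat <- sample(pool, sc$n_dmr_paternal)
  pool <- setdiff(pool, dmr_pat)
  dmr_mat <- if (sc$n_dmr_maternal > 0) sample(pool, sc$n_dmr_maternal) else character()
  pool <- setdiff(pool, dmr_mat)
  megs <- sample(pool, sc$n_meg)
  pool <- setdiff(pool, megs)
  pegs <- sample(pool, sc$n_peg)
  pool <- setdiff(pool, pegs)
  ase_bi <- sample(pool, sc$n_ase_biallelic)
  pool <- setdiff(pool, ase_bi)
  iso <- if (sc$n_isoform_specific > 0) sample(pool, sc$n_isoform_specific) else character()
  pool <- setdiff(pool, iso)
  planted <- c(stringent, neighbors, dmr_pat, dmr_mat, megs, pegs, ase_bi, iso)
  silent <- sample(pool, round(sc$silent_fraction * n))

  base_mean <- exp(rnorm(n, log(50), 1))
  names(base_mean) <- gene_id
  base_mean[planted] <- sc$planted_base_mean
  base_mean[silent] <- 0.05

  # second transcript for isoform-specific genes (shared TSS, longer body)
  if (length(iso)) {
    extra <- ann[gene_id %in% iso]
    extra[, transcript_id := paste0(gene_id, ".t2")]
    extra[, end := ifelse(strand == "+", end + 500L, end)]
    extra[, start := ifelse(strand == "-", start - 500L, start)]
    ann <- rbind(ann, extra)
  }

  genes <- data.table(
    gene_id = gene_id, chrom = paste0("chr", chrom_i), tss = tss,
    base_mean = base_mean[gene_id],
    is_dmr_paternal = gene_id %in% c(dmr_pat, stringent),
    is_dmr_maternal = gene_id %in% dmr_mat,
    is_meg = gene_id %in% c(megs, stringent, neighbors),
    is_peg = gene_id %in% pegs,
    is_stringent = gene_id %in% stringent,
    is_neighbor = gene_id %in% neighbors,
    is_mono_ase = gene_id %in% c(stringent, neighbors),
    is_ase_biallelic = gene_id %in% ase_bi,
    is_isoform_specific = gene_id %in% iso,
    is_silent = gene_id %in% silent
  )

  # scan region and planted germline windows (offset from the promoter grid)
  annotation <- gene_annotation(ann)
  region_anchors <- if (length(stringent)) stringent else gene_id[on_chr1[21:29]]
  region <- make_scan_region(region_anchors, annotation, 200000L)
  windows <- make_windows(region, 1000L)
  gdmr_starts <- c(2150000, 2151000, 2450000)[seq_len(sc$n_gdmr)]
  gdmr_ids <- windows[start %in% gdmr_starts, window_id]
  persistent_ids <- head(gdmr_ids, sc$n_gdmr_persistent)
  other <- setdiff(windows$window_id, gdmr_ids)
  covered <- c(gdmr_ids,
               sample(other, max(0, sc$n_covered_windows - length(gdmr_ids))))
  win_truth <- data.table(window_id = covered,
                          is_gdmr = covered %in% gdmr_ids,
                          persistent = covered %in% persistent_ids)

  list(annotation = annotation, genes = genes, region = region,
       windows = windows, win_truth = win_truth,
       stringent = stringent, neighbors = neighbors)
}

# Per-origin mean methylation level of each gene's promoter locus.
locus_means <- function(sc, genes) {
  n <- nrow(genes)
  low <- runif(n) < sc$bg_low_weight
  base <- ifelse(low,
                 rbeta(n, sc$cpg_conc * sc$bg_low_mean,
                       sc$cpg_conc * (1 - sc$bg_low_mean)),
                 rbeta(n, sc$cpg_conc * sc$bg_high_mean,
                       sc$cpg_conc * (1 - sc$bg_high_mean)))
  hi <- 0.5 + sc$dmr_delta_pp / 200
  lo <- 0.5 - sc$dmr_delta_pp / 200
  ag <- ifelse(genes$is_dmr_paternal, hi, ifelse(genes$is_dmr_maternal, lo, base))
  pg <- ifelse(genes$is_dmr_paternal, lo, ifelse(genes$is_dmr_maternal, hi, base))
  bi <- ifelse(genes$is_dmr_paternal | genes$is_dmr_maternal, 0.5, base)
  list(androgenetic = ag, parthenogenetic = pg, biparental = bi)
}

clamp01 <- function(x, eps = 1e-4) pmin(1 - eps, pmax(eps, x))

# Draw beta-binomial calls for a CpG table with per-CpG true levels.
draw_calls <- function(b, sc) {
  level <- rbeta(length(b), sc$sample_conc * clamp01(b),
                 sc$sample_conc * (1 - clamp01(b)))
  depth <- rnbinom(length(b), mu = sc$depth_mean, size = sc$depth_size)
  meth <- rbinom(length(b), depth, level)
  list(depth = depth, meth = meth)
}

#' Simulate uniparental and biparental methylomes
#'
#' Promoter CpGs share a per-CpG baseline across origins (so null promoter
#' deltas reflect coverage noise only); planted DMR promoters draw
#' origin-specific levels around 0.5 +/- delta/2.  Scan-region windows with
#' simulated RRBS coverage are included so germline-DMR persistence can be
#' evaluated on the same samples.  NPC samples, when configured, share the
#' imprint truth of their origin.
#'
#' @param sc A [simulation_scenario()].
#' @return List: `samples` (list of `methylome_sample`), `truth` (per-gene
#'   table), `layout` (annotation, scan region, windows, window truth).
#' @export
simulate_methylomes <- function(sc) {
  layout <- scenario_layout(sc)
  set.seed(sc$seed + 1L)
  genes <- layout$genes
  ann1 <- as.data.table(layout$annotation)[, .SD[1], by = gene_id]
  tss <- setNames(ann1$tss, ann1$gene_id)[genes$gene_id]

  offs <- round(seq(-450, 450, length.out = sc$cpgs_per_promoter))
  cpg <- data.table(gene_id = rep(genes$gene_id, each = sc$cpgs_per_promoter),
                    chrom = rep(genes$chrom, each = sc$cpgs_per_promoter),
                    pos = rep(tss, each = sc$cpgs_per_promoter) +
                      rep(offs, nrow(genes)))
  lm <- locus_means(sc, genes)
  # per-CpG baseline around the locus mean, shared across origins when the
  # locus is unplanted
  b_bg <- rbeta(nrow(cpg), sc$cpg_conc * clamp01(rep(lm$biparental,
                                                     each = sc$cpgs_per_promoter)),
                sc$cpg_conc * (1 - clamp01(rep(lm$biparental,
                                               each = sc$cpgs_per_promoter))))
  planted <- rep(genes$is_dmr_paternal | genes$is_dmr_maternal,
                 each = sc$cpgs_per_promoter)
  b_origin <- function(origin) {
    mu <- rep(lm[[origin]], each = sc$cpgs_per_promoter)
    b <- b_bg
    if (any(planted)) {
      b[planted] <- rbeta(sum(planted), sc$cpg_conc * clamp01(mu[planted]),
                          sc$cpg_conc * (1 - clamp01(mu[planted])))
    }
    b
  }
  b_by_origin <- list(androgenetic = b_origin("androgenetic"),
                      parthenogenetic = b_origin("parthenogenetic"),
                      biparental = b_origin("biparental"))

  # scan-region window CpGs (6 per covered window), shared baseline across
  # origins except at planted germline windows
  win <- merge(layout$win_truth,
               as.data.table(layout$windows), by = "window_id")
  wcpg <- data.table(window_id = rep(win$window_id, each = 6L),
                     chrom = rep(win$chrom, each = 6L),
                     pos = as.integer(rep(win$start, each = 6L) +
                                        rep(round(seq(80, 920, length.out = 6)), nrow(win))))
  w_low <- runif(nrow(win)) < sc$bg_low_weight
  w_base <- ifelse(w_low, sc$bg_low_mean, sc$bg_high_mean)
  wb_bg <- rbeta(nrow(wcpg), sc$cpg_conc * rep(w_base, each = 6L),
                 sc$cpg_conc * (1 - rep(w_base, each = 6L)))
  w_is_gdmr <- rep(win$is_gdmr, each = 6L)
  w_persist <- rep(win$persistent, each = 6L)
  # planted windows are oocyte-methylated; persistent ones keep the
  # difference in uniparental cells, non-persistent ones are reprogrammed low
  wb_for <- function(origin) {
    b <- wb_bg
    if (origin == "parthenogenetic") {
      b[w_is_gdmr & w_persist] <- sc$gdmr_high
      b[w_is_gdmr & !w_persist] <- 0.2
    } else if (origin == "androgenetic") {
      b[w_is_gdmr & w_persist] <- sc$gdmr_low
      b[w_is_gdmr & !w_persist] <- 0.2
    } else {
      b[w_is_gdmr & w_persist] <- 0.5
      b[w_is_gdmr & !w_persist] <- 0.2
    }
    b
  }

  make_samples <- function(origin, n, stage) {
    if (n == 0) return(list())
    b_prom <- b_by_origin[[origin]]
    b_win <- wb_for(origin)
    lapply(seq_len(n), function(i) {
      d1 <- draw_calls(b_prom, sc)
      d2 <- draw_calls(b_win, sc)
      calls <- rbind(
        data.table(chrom = cpg$chrom, pos = cpg$pos,
                   meth = d1$meth, unmeth = d1$depth - d1$meth),
        data.table(chrom = wcpg$chrom, pos = wcpg$pos,
                   meth = d2$meth, unmeth = d2$depth - d2$meth)
      )
      calls <- calls[, .(meth = sum(meth), unmeth = sum(unmeth)),
                     by = .(chrom, pos)]
      methylome_sample(sprintf("%s_%s_%d", toupper(substr(origin, 1, 2)),
                               stage, i),
                       origin, stage, calls)
    })
  }
  samples <- c(make_samples("androgenetic", sc$n_ag, "ESC"),
               make_samples("parthenogenetic", sc$n_pg, "ESC"),
               make_samples("biparental", sc$n_bi, "ESC"),
               make_samples("androgenetic", sc$n_npc, "NPC"),
               make_samples("parthenogenetic", sc$n_npc, "NPC"))
  list(samples = samples, truth = genes, layout = layout)
}

#' Simulate gamete (sperm and oocyte) methylomes
#'
#' Gametes are simulated over the covered scan windows only (RRBS sparsity):
#' background windows share one baseline between gametes; planted germline
#' windows are oocyte-high, sperm-low.
#'
#' @param sc A [simulation_scenario()].
#' @return List: `samples` (sperm then oocyte `methylome_sample`s),
#'   `win_truth`, `windows`, `region`.
#' @export
simulate_germ <- function(sc) {
  layout <- scenario_layout(sc)
  set.seed(sc$seed + 2L)
  win <- merge(layout$win_truth, as.data.table(layout$windows),
               by = "window_id")
  wcpg <- data.table(window_id = rep(win$window_id, each = 6L),
                     chrom = rep(win$chrom, each = 6L),
                     pos = as.integer(rep(win$start, each = 6L) +
                                        rep(round(seq(80, 920, length.out = 6)), nrow(win))))
  w_low <- runif(nrow(win)) < sc$bg_low_weight
  w_base <- ifelse(w_low, sc$bg_low_mean, sc$bg_high_mean)
  wb_bg <- rbeta(nrow(wcpg), sc$cpg_conc * rep(w_base, each = 6L),
                 sc$cpg_conc * (1 - rep(w_base, each = 6L)))
  is_gdmr <- rep(win$is_gdmr, each = 6L)
  make_gamete <- function(origin, n) {
    b <- wb_bg
    b[is_gdmr] <- if (origin == "oocyte") sc$gdmr_high else sc$gdmr_low
    lapply(seq_len(n), function(i) {
      d <- draw_calls(b, sc)
      methylome_sample(sprintf("%s_%d", origin, i), origin, "germ",
                       data.table(chrom = wcpg$chrom, pos = wcpg$pos,
                                  meth = d$meth, unmeth = d$depth - d$meth))
    })
  }
  list(samples = c(make_gamete("sperm", sc$n_sperm),
                   make_gamete("oocyte", sc$n_oocyte)),
       win_truth = layout$win_truth, windows = layout$windows,
       region = layout$region)
}

#' Simulate the expression count matrix
#'
#' Counts are negative-binomial around origin-specific means: MEG-like
#' genes have parthenogenetic mean fold times the androgenetic mean
#' (PEG-like mirrored); biparental means are the parental average.  Library
#' depths vary uniformly by +/- 30 percent.
#'
#' @param sc A [simulation_scenario()].
#' @return List: `counts` (genes x samples), `col_data` (sample_id, origin,
#'   stage), `lengths` (per-gene transcript length), `truth`.
#' @export
simulate_counts <- function(sc) {
  layout <- scenario_layout(sc)
  set.seed(sc$seed + 3L)
  genes <- layout$genes
  ann1 <- as.data.table(layout$annotation)[, .SD[1], by = gene_id]
  lens <- setNames(ann1$end - ann1$start, ann1$gene_id)[genes$gene_id]

  mu_ag <- genes$base_mean
  mu_pg <- genes$base_mean
  mu_pg[genes$is_meg] <- genes$base_mean[genes$is_meg] * sc$expr_fold
  mu_ag[genes$is_peg] <- genes$base_mean[genes$is_peg] * sc$expr_fold
  mu_bi <- (mu_ag + mu_pg) / 2

  cols <- data.table(
    sample_id = c(sprintf("AN_ESC_%d", seq_len(sc$n_ag)),
                  sprintf("PA_ESC_%d", seq_len(sc$n_pg)),
                  sprintf("BI_ESC_%d", seq_len(sc$n_bi)),
                  if (sc$n_npc > 0) sprintf("AN_NPC_%d", seq_len(sc$n_npc)),
                  if (sc$n_npc > 0) sprintf("PA_NPC_%d", seq_len(sc$n_npc))),
    origin = c(rep("androgenetic", sc$n_ag), rep("parthenogenetic", sc$n_pg),
               rep("biparental", sc$n_bi),
               rep("androgenetic", sc$n_npc), rep("parthenogenetic", sc$n_npc)),
    stage = c(rep("ESC", sc$n_ag + sc$n_pg + sc$n_bi),
              rep("NPC", 2 * sc$n_npc))
  )
  mu_of <- list(androgenetic = mu_ag, parthenogenetic = mu_pg,
                biparental = mu_bi)
  counts <- vapply(seq_len(nrow(cols)), function(j) {
    libf <- runif(1, 0.7, 1.3)
    rnbinom(nrow(genes), mu = mu_of[[cols$origin[j]]] * libf,
            size = 1 / sc$nb_dispersion)
  }, numeric(nrow(genes)))
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(genes$gene_id, cols$sample_id)
  list(counts = counts, col_data = cols, lengths = lens, truth = genes)
}

#' Simulate the allele-specific expression table
#'
#' Monoallelic genes (the cluster genes) draw minor-allele counts with the
#' leakage probability; biallelic control genes draw at one half.
#' Isoform-specific genes receive two transcripts, one monoallelic and one
#' biallelic, within every cell type.
#'
#' @param sc A [simulation_scenario()].
#' @return List: `ase` (table as from [read_ase_table()]), `truth`.
#' @export
simulate_ase <- function(sc) {
  layout <- scenario_layout(sc)
  set.seed(sc$seed + 4L)
  genes <- layout$genes
  cell_types <- c("pluripotent", "neural", "mesenchymal", "osteoblast")
  tss <- setNames(genes$tss, genes$gene_id)
  chrom <- setNames(genes$chrom, genes$gene_id)

  rows <- list()
  emit <- function(gene, transcript, p_minor) {
    for (ct in cell_types) {
      for (s in seq_len(sc$n_snps_per_gene)) {
        total <- rnbinom(1, mu = sc$ase_depth_mean, size = 10) + 2L
        minor <- rbinom(1, total, p_minor)
        swap <- runif(1) < 0.5
        rows[[length(rows) + 1L]] <<- data.table(
          sample_id = paste0(ct, "_s1"), gene_id = gene,
          transcript_id = transcript, cell_type = ct,
          chrom = chrom[[gene]], pos = tss[[gene]] + 100L + 10L * s,
          ref_count = if (swap) minor else total - minor,
          alt_count = if (swap) total - minor else minor)
      }
    }
  }
  for (g in genes[is_mono_ase == TRUE, gene_id]) {
    emit(g, paste0(g, ".t1"), sc$ase_leakage)
  }
  for (g in genes[is_ase_biallelic == TRUE, gene_id]) {
    emit(g, paste0(g, ".t1"), 0.5)
  }
  for (g in genes[is_isoform_specific == TRUE, gene_id]) {
    emit(g, paste0(g, ".t1"), sc$ase_leakage)
    emit(g, paste0(g, ".t2"), 0.5)
  }
  ase <- rbindlist(rows)
  ase[, total := ref_count + alt_count]
  ase[, allelic_ratio := pmin(ref_count, alt_count) / total]
  list(ase = ase[], truth = genes)
}

#' Simulate the complete study
#'
#' Runs every generator under the scenario seed and bundles the inputs the
#' pipeline consumes, plus the ground-truth ledger.
#'
#' @param sc A [simulation_scenario()].
#' @return List: annotation, methylomes, germ, counts, col_data, lengths,
#'   ase, truth (genes + windows), region, windows, scan_anchors.
#' @export
simulate_study <- function(sc = simulation_scenario()) {
  meth <- simulate_methylomes(sc)
  germ <- simulate_germ(sc)
  expr <- simulate_counts(sc)
  ase <- simulate_ase(sc)
  list(annotation = meth$layout$annotation,
       methylomes = meth$samples,
       germ = germ$samples,
       counts = expr$counts,
       col_data = expr$col_data,
       lengths = expr$lengths,
       ase = ase$ase,
       truth = list(genes = meth$truth, windows = germ$win_truth),
       region = germ$region,
       windows = germ$windows,
       scan_anchors = meth$layout$stringent)
}
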