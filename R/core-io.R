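#' @import data.table
#' @importFrom stats p.adjust wilcox.test rbeta rbinom rnbinom rpois runif
#'   rnorm setNames complete.cases dnbinom dbinom median quantile sd var
#' @importFrom utils read.table write.table head tail combn
NULL

# Closed vocabularies for sample labels.
ORIGINS <- c("androgenetic", "parthenogenetic", "biparental", "sperm", "oocyte")
STAGES  <- c("ESC", "NPC", "germ", "other")

## ---- coordinate conventions -------------------------------------------------
## Internal coordinates are 0-based half-open.  Bismark report/coverage files
## are 1-based; positions are converted on ingest and back on output.

pos_to_internal <- function(pos_1based) as.integer(pos_1based) - 1L
pos_to_report   <- function(pos_0based) as.integer(pos_0based) + 1L

#' Construct a genomic interval
#'
#' Intervals are 0-based half-open, the package-wide convention for promoter
#' windows, DMRs, scan tiles and neighbourhoods.
#'
#' @param chrom Chromosome name (non-empty).
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must exceed `start`.
#' @param strand One of "+", "-", ".".
#' @return A list of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand = ".") {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1)
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end)) {
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  }
  if (!strand %in% c("+", "-", ".")) stop("strand must be one of '+', '-', '.'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

#' Construct a methylome sample
#'
#' @param sample_id Sample identifier.
#' @param origin One of androgenetic, parthenogenetic, biparental, sperm, oocyte.
#' @param stage One of ESC, NPC, germ, other.
#' @param calls data.frame with columns chrom, pos (0-based), meth, unmeth.
#' @param merge_strands Merge CpG dyad calls at consecutive positions by
#'   summing counts (CpG methylation is symmetric; merging raises coverage).
#' @return A list of class `methylome_sample`.
#' @export
methylome_sample <- function(sample_id, origin, stage, calls, merge_strands = FALSE) {
  origin <- match.arg(origin, ORIGINS)
  stage <- match.arg(stage, STAGES)
  calls <- as.data.table(calls)
  req <- c("chrom", "pos", "meth", "unmeth")
  if (!all(req %in% names(calls))) {
    stop("calls must have columns ", paste(req, collapse = ", "))
  }
  calls <- calls[, req, with = FALSE]
  calls[, `:=`(pos = as.integer(pos), meth = as.integer(meth),
               unmeth = as.integer(unmeth))]
  if (any(calls$meth < 0 | calls$unmeth < 0)) stop("negative methylation counts")
  setkey(calls, chrom, pos)
  if (merge_strands) calls <- merge_dyads(calls)
  if (anyDuplicated(calls, by = c("chrom", "pos"))) {
    stop("duplicate (chrom, pos) in methylome sample ", sample_id)
  }
  structure(list(sample_id = sample_id, origin = origin, stage = stage,
                 calls = calls, strands_merged = merge_strands),
            class = "methylome_sample")
}

# A forward-strand CpG at p implies G at p+1, so a call at p+1 following one
# at p can only be the reverse-strand dyad partner.  Runs of adjacent calls
# (e.g. CGCG contexts) are paired greedily from the left, which matches the
# dyad structure: (C+, C-), (C+, C-), ...
merge_dyads <- function(calls) {
  calls <- calls[order(chrom, pos)]
  n <- nrow(calls)
  if (n < 2) return(calls)
  adj <- c(diff(calls$pos) == 1L & calls$chrom[-n] == calls$chrom[-1], FALSE)
  grp <- integer(n)
  g <- 0L
  i <- 1L
  while (i <= n) {
    g <- g + 1L
    grp[i] <- g
    if (adj[i]) {
      grp[i + 1L] <- g
      i <- i + 2L
    } else {
      i <- i + 1L
    }
  }
  calls[, .dyad_grp := grp]
  out <- calls[, .(chrom = chrom[1], pos = pos[1],
                   meth = sum(meth), unmeth = sum(unmeth)), by = .dyad_grp]
  out[, .dyad_grp := NULL]
  setkey(out, chrom, pos)
  out[]
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf("methylome_sample %s (%s, %s): %d CpG calls on %d chromosome(s)\n",
              x$sample_id, x$origin, x$stage, nrow(x$calls),
              length(unique(x$calls$chrom))))
  invisible(x)
}

#' Read a Bismark-style per-cytosine methylation file
#'
#' Supports the cytosine-report dialect (chrom, 1-based pos, strand,
#' meth count, unmeth count, context, trinucleotide) and the coverage dialect
#' (chrom, 1-based start, end, percent methylation, meth count, unmeth count).
#' Only CpG-context records are retained in report files; counts are preserved
#' exactly.  Positions are converted to the package's 0-based convention.
#'
#' @param path File path (plain text, tab- or space-delimited).
#' @param dialect "cytosine_report" or "coverage".
#' @param sample_id,origin,stage Sample labels for the returned object.
#' @param merge_strands Merge opposite-strand dyad calls by count summing.
#' @return A `methylome_sample`.
#' @export
read_cytosine_report <- function(path, dialect = c("cytosine_report", "coverage"),
                                 sample_id = basename(path),
                                 origin = "biparental", stage = "ESC",
                                 merge_strands = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(methylome_sample(sample_id, origin, stage,
                            data.table(chrom = character(), pos = integer(),
                                       meth = integer(), unmeth = integer())))
  }
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (dialect == "cytosine_report") {
    bad <- which(nf < 5)
    if (length(bad)) stop("malformed cytosine-report line ", bad[1], " in ", path)
    m <- do.call(rbind, lapply(fields, function(f) f[1:7]))
    ctx <- m[, 6]
    keep <- is.na(ctx) | ctx %in% c("CpG", "CG")
    m <- m[keep, , drop = FALSE]
    pos1 <- suppressWarnings(as.integer(m[, 2]))
    meth <- suppressWarnings(as.integer(m[, 4]))
    unmeth <- suppressWarnings(as.integer(m[, 5]))
    bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth))
    if (length(bad)) stop("malformed cytosine-report line ", which(keep)[bad[1]],
                          " in ", path)
    strand <- m[, 3]
    pos0 <- pos_to_internal(pos1)
    if (merge_strands) {
      # a reverse-strand cytosine reports the G position of the dyad; map it
      # to the forward C so dyad merging is a plain positional aggregation
      pos0 <- ifelse(!is.na(strand) & strand == "-", pos0 - 1L, pos0)
    }
    calls <- data.table(chrom = m[, 1], pos = pos0, meth = meth, unmeth = unmeth)
    if (merge_strands) {
      calls <- calls[, .(meth = sum(meth), unmeth = sum(unmeth)),
                     by = .(chrom, pos)]
    }
    methylome_sample(sample_id, origin, stage, calls, merge_strands = FALSE)
  } else {
    bad <- which(nf < 6)
    if (length(bad)) stop("malformed coverage line ", bad[1], " in ", path)
    m <- do.call(rbind, lapply(fields, function(f) f[1:6]))
    pos1 <- suppressWarnings(as.integer(m[, 2]))
    meth <- suppressWarnings(as.integer(m[, 5]))
    unmeth <- suppressWarnings(as.integer(m[, 6]))
    bad <- which(is.na(pos1) | is.na(meth) | is.na(unmeth))
    if (length(bad)) stop("malformed coverage line ", bad[1], " in ", path)
    calls <- data.table(chrom = m[, 1], pos = pos_to_internal(pos1),
                        meth = meth, unmeth = unmeth)
    methylome_sample(sample_id, origin, stage, calls,
                     merge_strands = merge_strands)
  }
}

#' Write a methylome sample in Bismark coverage dialect
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @export
write_cytosine_coverage <- function(sample, path) {
  calls <- sample$calls
  total <- calls$meth + calls$unmeth
  pct <- ifelse(total > 0, 100 * calls$meth / total, 0)
  out <- data.table(chrom = calls$chrom, start = pos_to_report(calls$pos),
                    end = pos_to_report(calls$pos), pct = pct,
                    meth = calls$meth, unmeth = calls$unmeth)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---- counts -----------------------------------------------------------------

#' Read a gene-by-sample raw count matrix
#'
#' Delimited text with a `gene_id` first column and sample identifiers in the
#' header.  Counts must be non-negative integers with no missing cells.
#'
#' @param path File path.
#' @param manifest Optional sample manifest; every header sample must appear.
#' @return Integer matrix, genes in rows.
#' @export
read_counts_matrix <- function(path, manifest = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("counts matrix needs a gene_id column plus samples")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicated gene_id in counts matrix: ", dup[1])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(mat))) stop("missing cells in counts matrix")
  if (any(mat < 0)) stop("negative counts in counts matrix")
  if (any(mat != round(mat))) stop("non-integer counts in counts matrix")
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  if (!is.null(manifest)) {
    missing <- setdiff(colnames(mat), manifest$sample_id)
    if (length(missing)) {
      stop("samples in counts header absent from manifest: ",
           paste(missing, collapse = ", "))
    }
  }
  mat
}

#' Write a count matrix as TSV
#' @param mat Gene-by-sample matrix with rownames.
#' @param path Output path.
#' @export
write_counts_matrix <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- ASE --------------------------------------------------------------------

#' Read an allele-specific expression (ASE) table
#'
#' Tab-delimited with columns sample_id, gene_id, chrom, pos, ref_count,
#' alt_count, and optionally transcript_id and cell_type.  When cell_type is
#' absent it defaults to the sample_id (each sample its own cell type).
#'
#' @param path File path.
#' @return data.table with derived `total` and `allelic_ratio` columns.
#' @export
read_ase_table <- function(path) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0) {
    warning("empty ASE table: ", path)
    return(data.table(sample_id = character(), gene_id = character(),
                      transcript_id = character(), cell_type = character(),
                      chrom = character(), pos = integer(),
                      ref_count = integer(), alt_count = integer(),
                      total = integer(), allelic_ratio = numeric()))
  }
  req <- c("sample_id", "gene_id", "chrom", "pos", "ref_count", "alt_count")
  if (!all(req %in% names(df))) {
    stop("ASE table must have columns ", paste(req, collapse = ", "))
  }
  for (col in c("ref_count", "alt_count")) {
    v <- df[[col]]
    if (any(is.na(v)) || any(v != round(v)) || any(v < 0)) {
      stop("non-integer or negative values in ASE column ", col)
    }
  }
  dt <- as.data.table(df)
  if (!"transcript_id" %in% names(dt)) dt[, transcript_id := NA_character_]
  if (!"cell_type" %in% names(dt)) dt[, cell_type := sample_id]
  dt[, `:=`(ref_count = as.integer(ref_count), alt_count = as.integer(alt_count))]
  dt[, total := ref_count + alt_count]
  dt[, allelic_ratio := ifelse(total > 0, pmin(ref_count, alt_count) / total,
                               NA_real_)]
  dt[]
}

#' Write an ASE table as TSV
#' @param ase ASE data.table/data.frame.
#' @param path Output path.
#' @export
write_ase_table <- function(ase, path) {
  cols <- intersect(c("sample_id", "gene_id", "transcript_id", "cell_type",
                      "chrom", "pos", "ref_count", "alt_count"), names(ase))
  write.table(as.data.frame(ase)[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- annotation -------------------------------------------------------------

#' Read a gene/transcript annotation
#'
#' Three dialects are accepted: BED12 (name parsed as `gene|transcript`, or
#' used for both when it has no pipe), a minimal GTF with gene_id /
#' transcript_id attributes, and a 4-column TSS table (gene_id, chrom,
#' 0-based TSS, strand) from which one synthetic transcript per gene is built.
#' The transcription start site is computed strand-aware: for a `+` transcript
#' it is the 0-based start; for a `-` transcript, end - 1.
#'
#' @param path File path.
#' @param dialect "bed12", "gtf_lite" or "tss_table".
#' @return data.table of class `gene_annotation` with one row per transcript:
#'   gene_id, gene_name, transcript_id, chrom, start, end, strand, tss.
#' @export
read_gene_annotation <- function(path, dialect = c("bed12", "gtf_lite", "tss_table")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed12") {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED12 requires at least 6 columns")
    name <- as.character(df[[4]])
    has_pipe <- grepl("|", name, fixed = TRUE)
    gene <- ifelse(has_pipe, sub("\\|.*$", "", name), name)
    tx <- ifelse(has_pipe, sub("^[^|]*\\|", "", name), name)
    ann <- data.table(gene_id = gene, gene_name = gene, transcript_id = tx,
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                      strand = as.character(df[[6]]))
  } else if (dialect == "gtf_lite") {
    df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                     comment.char = "#", quote = "")
    df <- df[df[[3]] %in% c("transcript", "mRNA"), , drop = FALSE]
    attr_get <- function(attrs, key) {
      m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]+"'), attrs))
      ifelse(lengths(regmatches(attrs, gregexpr(paste0(key, ' "'), attrs))) > 0,
             sub('"$', "", sub(paste0(key, ' "'), "", m)), NA_character_)
    }
    ann <- data.table(gene_id = attr_get(df[[9]], "gene_id"),
                      gene_name = attr_get(df[[9]], "gene_id"),
                      transcript_id = attr_get(df[[9]], "transcript_id"),
                      chrom = as.character(df[[1]]),
                      start = as.integer(df[[4]]) - 1L,  # GTF is 1-based closed
                      end = as.integer(df[[5]]),
                      strand = as.character(df[[7]]))
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "tss", "strand")
    if (!all(req %in% names(df))) {
      stop("tss_table requires columns ", paste(req, collapse = ", "))
    }
    tss <- as.integer(df$tss)
    ann <- data.table(gene_id = df$gene_id, gene_name = df$gene_id,
                      transcript_id = paste0(df$gene_id, ".t1"),
                      chrom = as.character(df$chrom),
                      start = tss, end = tss + 1L,
                      strand = as.character(df$strand))
  }
  gene_annotation(ann)
}

#' Build a gene annotation object from a transcript table
#'
#' @param ann data.frame with gene_id, transcript_id, chrom, start, end, strand
#'   (0-based half-open).
#' @return data.table of class `gene_annotation` with a strand-aware `tss`.
#' @export
gene_annotation <- function(ann) {
  ann <- as.data.table(ann)
  if (!"gene_name" %in% names(ann)) ann[, gene_name := gene_id]
  bad <- !ann$strand %in% c("+", "-")
  if (any(bad)) {
    stop("transcript strand must be '+' or '-': ",
         paste(head(ann$transcript_id[bad], 3), collapse = ", "))
  }
  if (any(ann$start < 0 | ann$end <= ann$start)) stop("invalid transcript interval")
  ann[, tss := ifelse(strand == "+", start, end - 1L)]
  setkey(ann, chrom, tss)
  class(ann) <- c("gene_annotation", class(ann))
  ann[]
}

## ---- manifest ---------------------------------------------------------------

#' Read a sample manifest (TSV or YAML)
#'
#' A manifest maps sample_id to origin, stage, and the file paths and dialects
#' of its inputs.  TSV columns: sample_id, origin, stage, plus optional
#' methylome, methylome_dialect, ase.  A YAML manifest holds a list of sample
#' records with the same fields.
#'
#' @param path Manifest path (.tsv/.txt or .yml/.yaml).
#' @return data.table with one row per sample.
#' @export
read_sample_manifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    y <- yaml::read_yaml(path)
    df <- rbindlist(lapply(y$samples, as.data.table), fill = TRUE)
  } else {
    df <- as.data.table(read.table(path, header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in manifest")
  if (!all(df$origin %in% ORIGINS)) {
    stop("manifest origin must be one of ", paste(ORIGINS, collapse = ", "))
  }
  if (!all(df$stage %in% STAGES)) {
    stop("manifest stage must be one of ", paste(STAGES, collapse = ", "))
  }
  if ("methylome" %in% names(df) && !"methylome_dialect" %in% names(df)) {
    stop("manifest with methylome paths must declare methylome_dialect")
  }
  df[]
}

## ---- candidate table --------------------------------------------------------

CANDIDATE_COLS <- c("gene_id", "chrom", "tss", "tier", "anchor_gene",
                    "distance_to_anchor", "has_promoter_dmr", "dmr_direction",
                    "dmr_delta_pp", "dmr_q", "has_imprinted_expression",
                    "expression_class", "expr_log2fc", "expr_q", "concordant",
                    "ase_support", "isoform_specific", "near_gdmr")

#' Write the integrated candidate table
#'
#' One row per candidate gene with all evidence columns in a stable order,
#' suitable for round-tripping with [read_candidate_table()].
#'
#' @param candidates Candidate data.frame from [assemble_candidates()].
#' @param path Output TSV path.
#' @export
write_candidate_table <- function(candidates, path) {
  df <- as.data.table(candidates)
  if (nrow(df) == 0) {
    writeLines(paste(CANDIDATE_COLS, collapse = "\t"), path)
    return(invisible(path))
  }
  for (col in setdiff(CANDIDATE_COLS, names(df))) df[, (col) := NA]
  df <- df[, CANDIDATE_COLS, with = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a candidate table written by [write_candidate_table()]
#' @param path TSV path.
#' @return data.table of candidates.
#' @export
read_candidate_table <- function(path) {
  dt <- as.data.table(read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE, na.strings = "NA"))
  dt[]
}
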