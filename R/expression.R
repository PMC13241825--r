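#' Counts per million
#'
#' @param counts Gene-by-sample matrix of raw counts.
#' @param lib_sizes Optional library sizes; defaults to column sums.
#' @return CPM matrix; each column sums to 1e6 over the genes present.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  zero <- lib_sizes <= 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  t(t(counts) / lib_sizes) * 1e6
}

#' Transcripts per million
#'
#' Length-normalised counts rescaled so each sample sums to 1e6.
#'
#' @param counts Gene-by-sample matrix of raw counts.
#' @param lengths Per-gene effective lengths (bp), matching rows.
#' @return TPM matrix.
#' @export
tpm <- function(counts, lengths) {
  if (length(lengths) != nrow(counts)) stop("lengths must match rows of counts")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  rate <- counts / lengths
  denom <- colSums(rate)
  if (any(denom <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[denom <= 0], collapse = ", "))
  }
  t(t(rate) / denom) * 1e6
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Composition-bias normalisation: for each sample versus a reference, the
#' scaling factor is two to the power of the weighted mean of gene-wise
#' log-ratios (M-values), after trimming the 30 percent most extreme
#' M-values and the 5 percent most extreme average log-expressions, with
#' inverse delta-method variances as weights.  Factors are rescaled to
#' geometric mean one.
#'
#' @param counts Gene-by-sample matrix of raw counts.
#' @param ref_sample Reference column (index or name); by default the sample
#'   whose upper quartile of scaled counts is closest to the mean upper
#'   quartile.
#' @param logratio_trim,sum_trim Trim fractions for M and A values.
#' @return Named vector of scaling factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, sum_trim = 0.05) {
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, function(x) quantile(x[x > 0], 0.75)) / lib
    ref_sample <- which.min(abs(uq - mean(uq)))
  }
  ref <- counts[, ref_sample]
  nref <- lib[ref_sample]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_sample) return(1)
    obs <- counts[, j]
    nobs <- lib[j]
    keep <- obs > 0 & ref > 0
    if (sum(keep) < 2) return(1)
    o <- obs[keep]; r <- ref[keep]
    M <- log2((o / nobs) / (r / nref))
    A <- 0.5 * log2((o / nobs) * (r / nref))
    w <- (nobs - o) / (nobs * o) + (nref - r) / (nref * r)
    finite <- is.finite(M) & is.finite(A)
    M <- M[finite]; A <- A[finite]; w <- w[finite]
    if (length(M) < 2) return(1)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * sum_trim) + 1
    hiA <- n + 1 - loA
    keep2 <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  if (nrow(counts) == 1) warning("single gene: TMM degenerate, factors near 1")
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Expressed-gene universe for a stage
#'
#' A gene counts as expressed at a stage when its TPM strictly exceeds the
#' configured threshold in at least two samples of that stage, regardless of
#' origin.
#'
#' @param tpm_mat TPM matrix (genes x samples).
#' @param sample_stages Character vector of stages matching columns.
#' @param stage Stage to evaluate ("ESC" or "NPC").
#' @param config A [pipeline_config()].
#' @return Character vector of expressed gene ids.
#' @export
expressed_filter <- function(tpm_mat, sample_stages, stage,
                             config = pipeline_config()) {
  cols <- sample_stages == stage
  if (!any(cols)) return(character())
  n_pass <- rowSums(tpm_mat[, cols, drop = FALSE] > config$expressed_tpm)
  rownames(tpm_mat)[n_pass >= 2]
}

# Conditional two-sided exact NB test on group sums.  Under a common
# per-sample dispersion phi, the sum of n iid NB(mu, phi) counts is
# NB(n mu, phi / n); conditioning on the total, the p-value is the summed
# probability of all splits at most as likely as the observed one.  At
# phi = 0 this reduces to the binomial (conditional Poisson) test.
exact_nb_p <- function(s_a, s_b, n_a, n_b, phi) {
  s <- s_a + s_b
  if (s == 0) return(1)
  m <- s / (n_a + n_b)
  a <- 0:s
  if (phi < 1e-8) {
    logp <- dbinom(a, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    logp <- dnbinom(a, size = n_a / phi, mu = n_a * m, log = TRUE) +
      dnbinom(s - a, size = n_b / phi, mu = n_b * m, log = TRUE)
  }
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  pobs <- p[s_a + 1]
  min(1, sum(p[p <= pobs * (1 + 1e-8)]))
}

# Method-of-moments dispersion per gene from depth-equalised counts:
# pooled within-group variance s2 and mean m give phi = (s2 - m) / m^2.
mom_dispersion <- function(pseudo, group) {
  ga <- pseudo[, group == levels(factor(group))[1], drop = FALSE]
  gb <- pseudo[, group == levels(factor(group))[2], drop = FALSE]
  va <- apply(ga, 1, var); vb <- apply(gb, 1, var)
  na <- ncol(ga); nb <- ncol(gb)
  s2 <- (va * (na - 1) + vb * (nb - 1)) / (na + nb - 2)
  m <- (rowMeans(ga) * na + rowMeans(gb) * nb) / (na + nb)
  phi <- (s2 - m) / m^2
  phi[!is.finite(phi) | phi < 0] <- 0
  phi
}

#' Negative-binomial exact test between two groups
#'
#' Counts are depth-equalised to the geometric-mean effective library size
#' (library size times TMM factor), summed within groups, and compared with
#' a conditional NB exact test.  The per-gene dispersion is the larger of a
#' common (trimmed-mean) estimate and a method-of-moments tagwise estimate
#' shrunk halfway toward the common value; this is deliberately conservative
#' for small sample counts.  Log2 fold changes are parthenogenetic over
#' androgenetic group means with a prior count of 0.5.
#'
#' @param counts Gene-by-sample raw counts.
#' @param group Factor/character vector over columns with values
#'   "androgenetic" and "parthenogenetic".
#' @param norm_factors Optional TMM factors (default computed).
#' @return data.table: gene_id, log2fc_pg_over_ag, p_value, dispersion.
#' @export
nb_exact_test <- function(counts, group, norm_factors = NULL) {
  group <- as.character(group)
  keep <- group %in% c("androgenetic", "parthenogenetic")
  counts <- counts[, keep, drop = FALSE]
  group <- group[keep]
  n_a <- sum(group == "androgenetic")
  n_b <- sum(group == "parthenogenetic")
  if (n_a < 2 || n_b < 2) stop("need >= 2 samples per group")
  if (is.null(norm_factors)) norm_factors <- tmm_factors(counts)
  eff <- colSums(counts) * norm_factors
  target <- exp(mean(log(eff)))
  pseudo <- t(t(counts) * (target / eff))

  phi_tag <- mom_dispersion(pseudo, group)
  m <- rowMeans(pseudo)
  informative <- m >= 1
  phi_common <- if (any(informative)) {
    mean(phi_tag[informative], trim = 0.25)
  } else 0
  phi <- pmax(phi_common, 0.5 * phi_tag + 0.5 * phi_common)

  ia <- group == "androgenetic"
  ib <- group == "parthenogenetic"
  sa <- round(rowSums(pseudo[, ia, drop = FALSE]))
  sb <- round(rowSums(pseudo[, ib, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(g) {
    exact_nb_p(sa[g], sb[g], n_a, n_b, phi[g])
  }, numeric(1))
  mu_a <- rowMeans(pseudo[, ia, drop = FALSE])
  mu_b <- rowMeans(pseudo[, ib, drop = FALSE])
  lfc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  all_zero <- sa + sb == 0
  p[all_zero] <- 1
  lfc[all_zero] <- 0
  data.table(gene_id = rownames(counts), log2fc_pg_over_ag = lfc,
             p_value = p, dispersion = phi)
}

#' Classify imprinted-like expression
#'
#' BH FDR is applied within the expressed universe of the stage; a gene is
#' MEG-like (maternally-expressed-like) when significant with higher
#' parthenogenetic expression, PEG-like when significant with higher
#' androgenetic expression.  Genes outside the universe are not_expressed.
#'
#' @param tests Output of [nb_exact_test()] (or an external DE table with
#'   columns gene_id, log2fc_pg_over_ag, p_value).
#' @param expressed_genes Character vector: the stage's expressed universe.
#' @param stage Stage label recorded on the calls.
#' @param config A [pipeline_config()].
#' @return data.table: gene_id, stage, log2fc_pg_over_ag, p_value, q_value,
#'   class.
#' @export
classify_imprinted_expression <- function(tests, expressed_genes, stage = "ESC",
                                          config = pipeline_config()) {
  tests <- as.data.table(tests)
  inside <- tests[gene_id %in% expressed_genes]
  outside <- tests[!gene_id %in% expressed_genes]
  inside[, q_value := p.adjust(p_value, method = "BH")]
  inside[, class := ifelse(q_value <= config$expr_alpha & log2fc_pg_over_ag > 0,
                           "MEG_like",
                    ifelse(q_value <= config$expr_alpha & log2fc_pg_over_ag < 0,
                           "PEG_like", "not_imprinted_like"))]
  outside[, `:=`(q_value = NA_real_, class = "not_expressed")]
  out <- rbind(inside, outside, fill = TRUE)
  out[, stage := stage]
  setcolorder(out, c("gene_id", "stage"))
  out[]
}
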