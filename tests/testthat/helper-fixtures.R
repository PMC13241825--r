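library(data.table)

# Methylome sample whose CpGs are laid out explicitly.
make_meth_sample <- function(id, origin, calls, stage = "ESC") {
  methylome_sample(id, origin, stage, as.data.table(calls))
}

# Sample with 3 CpGs of coverage 10 per registry region, at the requested
# mean percent levels; NA level leaves the region without CpGs (no_data).
sample_with_region_levels <- function(id, origin, registry, levels_pct) {
  stopifnot(nrow(registry) == length(levels_pct))
  rows <- list()
  for (i in seq_len(nrow(registry))) {
    if (is.na(levels_pct[i])) next
    meth <- round(levels_pct[i] / 10)  # out of coverage 10
    pos <- registry$start[i] + c(10L, 20L, 30L)
    rows[[length(rows) + 1L]] <- data.table(
      chrom = registry$chrom[i], pos = pos,
      meth = as.integer(meth), unmeth = as.integer(10 - meth))
  }
  calls <- if (length(rows)) rbindlist(rows) else
    data.table(chrom = character(), pos = integer(),
               meth = integer(), unmeth = integer())
  make_meth_sample(id, origin, calls)
}

# Synthetic registry of n one-kb regions on one chromosome.
toy_registry <- function(n, origin = "maternal") {
  data.table(chrom = "chrT", start = seq(0L, by = 10000L, length.out = n),
             end = seq(0L, by = 10000L, length.out = n) + 1000L,
             name = sprintf("DMR%02d", seq_len(n)),
             origin = rep(origin, n), notes = "")
}

# Independent brute-force permutation oracle: enumerates subsets via bitmask,
# a different enumeration path than the implementation's combn().
brute_force_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  total <- 0L
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[1:n]
    if (sum(bits) != na) next
    total <- total + 1L
    sa <- sum(pool[bits == 1])
    stat <- abs(sa / na - (sum(pool) - sa) / (n - na))
    if (stat >= obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

# Independent exact two-sided rank-sum oracle over all label partitions.
rank_sum_exact_p <- function(x, y) {
  pooled <- rank(c(x, y))
  nx <- length(x)
  obs <- sum(pooled[seq_len(nx)])
  parts <- combn(length(pooled), nx)
  stats <- apply(parts, 2, function(i) sum(pooled[i]))
  lo <- mean(stats <= obs + 1e-9)
  hi <- mean(stats >= obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
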