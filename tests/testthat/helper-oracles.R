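# Brute-force oracles used across tests. These are deliberately naive,
# independent re-implementations: they loop, enumerate, and never share
# code with the package internals they check.

# sum of per-base coverage over [start, end) by explicit position loop
oracle_window_sum <- function(intervals, start, end) {
  # intervals: data.frame(start, end, value), 0-based half-open
  total <- 0
  for (p in start:(end - 1L)) {
    for (i in seq_len(nrow(intervals))) {
      if (p >= intervals$start[i] && p < intervals$end[i]) {
        total <- total + intervals$value[i]
      }
    }
  }
  total
}

# single-linkage clustering of integer positions with gap <= merge_gap
oracle_clusters <- function(pos, merge_gap) {
  pos <- sort(pos)
  id <- integer(length(pos))
  cur <- 1L
  id[1L] <- cur
  for (i in seq_along(pos)[-1L]) {
    if (pos[i] - pos[i - 1L] > merge_gap) cur <- cur + 1L
    id[i] <- cur
  }
  split(pos, id)
}

# Pearson chi-squared statistic by the textbook formula
oracle_pearson <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}

# two-sample KS statistic as the maximum ECDF gap on the pooled support
oracle_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  fa <- vapply(grid, function(x) mean(a <= x), 0)
  fb <- vapply(grid, function(x) mean(b <= x), 0)
  max(abs(fa - fb))
}

# 99% binomial confidence interval (normal approximation) for a proportion
binom_ci99 <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}

# rank-based AUC of `pos` values scoring above `neg` values
oracle_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

make_units <- function(starts, lengths, strands, chrom = "chr1",
                       ids = NULL) {
  n <- length(starts)
  data.frame(
    id = ids %||% sprintf("u%02d", seq_len(n)),
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(starts + lengths),
    strand = rep_len(strands, n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
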