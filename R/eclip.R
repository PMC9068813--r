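# eCLIP crosslink-site analysis: site extraction from read records,
# assignment to transcript units with 1-based 5'-end distances, distance-
# window distributions, expression-normalised meta-profiles, and
# chi-squared comparison of window distributions.
#
# Distances are 1-based inclusive to match the conventional window labels
# ("1-200"); genomic coordinates remain 0-based half-open.

#' Extract crosslink sites from read records
#'
#' The crosslink site of an eCLIP read pair is the first nucleotide of the
#' R2 read (the reverse-transcription truncation position). Read records
#' carry that genomic position directly; this accumulates them into a site
#' table with per-position counts.
#'
#' @param reads Data frame with columns `chrom`, `pos` (0-based genomic
#'   position of the R2 first nucleotide), `strand`.
#' @param dedup Collapse identical records to a single read before
#'   counting (a conservative stand-in for upstream PCR-duplicate
#'   removal). Default `FALSE`.
#' @return Site-table data frame (`chrom`, `pos`, `strand`, `count`).
#' @export
extract_crosslink_sites <- function(reads, dedup = FALSE) {
  if (nrow(reads) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = numeric()))
  }
  if (dedup) reads <- unique(reads[c("chrom", "pos", "strand")])
  tab <- stats::aggregate(
    count ~ chrom + pos + strand,
    data = data.frame(reads[c("chrom", "pos", "strand")], count = 1),
    FUN = sum
  )
  tab <- tab[order(tab$chrom, tab$strand, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Assign crosslink sites to transcript units
#'
#' A site is assigned to every unit that contains it on the same strand
#' (sites inside overlapping units are assigned to all, flagged
#' `multi_unit`). The distance is 1-based from the unit's 5' end in
#' transcript orientation: a site exactly at the 5' end has distance 1.
#' Sites contained in no unit are dropped; their count is reported in the
#' `n_unassigned` attribute.
#'
#' @param sites Site-table data frame (`chrom`, `pos`, `strand`, `count`).
#' @param units Transcript-unit data frame (`id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @return Data frame: `chrom`, `pos`, `strand`, `count`, `unit`,
#'   `distance` (1-based nt), `multi_unit`; attribute `n_unassigned`.
#' @export
assign_to_units <- function(sites, units) {
  site_gr <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = sites$strand
  )
  unit_gr <- GenomicRanges::GRanges(
    units$chrom, IRanges::IRanges(start = units$start + 1L, end = units$end),
    strand = units$strand
  )
  hits <- GenomicRanges::findOverlaps(site_gr, unit_gr, ignore.strand = FALSE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  unit5p <- .unit_5prime(units)
  dist1 <- .signed_distance(sites$pos[qi], unit5p[si], units$strand[si]) + 1L
  n_hits <- tabulate(qi, nbins = nrow(sites))
  out <- data.frame(
    chrom = sites$chrom[qi], pos = sites$pos[qi], strand = sites$strand[qi],
    count = sites$count[qi], unit = units$id[si], distance = dist1,
    multi_unit = n_hits[qi] > 1L
  )
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- sum(sites$count[n_hits == 0L])
  out
}

#' Distance-window distribution of crosslink sites
#'
#' Counts assigned crosslink sites per distance window. Windows are
#' half-open on the left in 1-based distance, `(prev_edge, edge]`, so the
#' default edges 200/400/600 give the windows labelled 1-200, 201-400 and
#' 401-600. Distances beyond the last edge are dropped and counted in the
#' `n_beyond` attribute.
#'
#' @param assignments Assignment data frame from [assign_to_units()].
#' @param edges Increasing window edges in nt (default
#'   `c(200, 400, 600, 800, 1000, 2000)`).
#' @return Data frame: `window` (label), `count`, `proportion`
#'   (`NA` and flagged via attribute `empty` when no site is retained);
#'   attribute `n_beyond`.
#' @export
window_distribution <- function(assignments,
                                edges = c(200L, 400L, 600L, 800L, 1000L, 2000L)) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0))
    stop("edges must be strictly increasing positive integers")
  lower <- c(0L, edges[-length(edges)])
  labels <- paste(lower + 1L, edges, sep = "-")
  counts <- numeric(length(edges))
  beyond <- 0
  if (nrow(assignments) > 0L) {
    idx <- findInterval(assignments$distance, c(lower, max(edges)) + 0.5)
    # idx in 1..k for windows, k+1 beyond the last edge
    inside <- idx <= length(edges)
    counts <- vapply(seq_along(edges), function(w)
      sum(assignments$count[inside & idx == w]), 0)
    beyond <- sum(assignments$count[!inside])
  }
  total <- sum(counts)
  out <- data.frame(
    window = labels, count = counts,
    proportion = if (total > 0) counts / total else rep(NA_real_, length(counts))
  )
  attr(out, "n_beyond") <- beyond
  attr(out, "empty") <- total == 0
  out
}

#' Expression-normalised crosslink meta-profile
#'
#' Per unit, per-position crosslink counts within `span` nt of the 5' end
#' are divided by the unit's expression density (reads per bp), removing
#' the trivial abundance component; the normalised per-position values are
#' then averaged across all units carrying at least one crosslink and
#' binned. Units with zero expression are excluded and counted.
#'
#' @param assignments Assignment data frame from [assign_to_units()].
#' @param units Transcript-unit data frame.
#' @param expression Named numeric vector of per-unit expression densities
#'   (reads/bp; names = unit ids).
#' @param span Profile span from the 5' end, nt (default 600).
#' @param binsize Bin width, nt (default 10).
#' @param per_window Normalise by density but computed per window rather
#'   than per unit; kept for parity with length-normalised displays
#'   (default `FALSE` = per-unit density).
#' @return Data frame `bin_start`, `bin_end` (1-based inclusive),
#'   `normalized_coverage`; attributes `n_units_used`,
#'   `n_excluded_zero_expression`.
#' @export
normalized_profile <- function(assignments, units, expression, span = 600L,
                               binsize = 10L, per_window = FALSE) {
  if (span %% binsize != 0L) stop("span must be a multiple of binsize")
  used <- 0L; excluded <- 0L
  acc <- numeric(span)
  for (uid in unique(assignments$unit)) {
    sub <- assignments[assignments$unit == uid & assignments$distance <= span, ,
                       drop = FALSE]
    if (nrow(sub) == 0L) next
    dens <- expression[[uid]]
    if (is.null(dens) || is.na(dens) || dens == 0) {
      excluded <- excluded + 1L
      next
    }
    prof <- numeric(span)
    prof[sub$distance] <- sub$count
    acc <- acc + prof / dens
    used <- used + 1L
  }
  if (used > 0L) acc <- acc / used
  bins <- matrix(acc, nrow = binsize)
  out <- data.frame(
    bin_start = seq(1L, span, by = binsize),
    bin_end = seq(binsize, span, by = binsize),
    normalized_coverage = colMeans(bins)
  )
  attr(out, "n_units_used") <- used
  attr(out, "n_excluded_zero_expression") <- excluded
  out
}

#' Chi-squared comparison of two window distributions
#'
#' Pearson chi-squared (no continuity correction) on the 2 x k contingency
#' table of window counts — counts, not proportions — with k - 1 degrees
#' of freedom.
#'
#' @param dist_a,dist_b Window-distribution data frames from
#'   [window_distribution()] (or plain count vectors of equal length).
#' @return List: `statistic`, `df`, `p_value`, `table`.
#' @export
compare_window_distributions <- function(dist_a, dist_b) {
  counts <- function(d) if (is.data.frame(d)) d$count else as.numeric(d)
  a <- counts(dist_a); b <- counts(dist_b)
  if (length(a) != length(b)) stop("window distributions differ in length")
  tab <- rbind(a = a, b = b)
  if (all(tab == 0)) stop("both distributions are empty")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1 & expected > 0))
    warning("expected cell count < 1: chi-squared approximation is poor")
  if (identical(a, b)) {
    # zero-signal case chisq.test refuses; the statistic is exactly 0
    return(list(statistic = 0, df = length(a) - 1L, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, table = tab)
}
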