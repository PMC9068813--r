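# SHAPE-MaP reactivity computation from two-channel mutation counts
# (1M7-modified vs untreated control), box-plot/percentile normalisation,
# median-reactivity structure classification, and the positional G-content
# enrichment analysis.

#' Compute raw and normalised SHAPE reactivities from mutation counts
#'
#' Per position, the mutation rate of each channel is `count / depth`; the
#' raw reactivity is `rate_modified - rate_untreated` (negative values are
#' retained by default). Positions with depth below `min_depth` in either
#' channel are masked and excluded from every summary. Normalisation
#' divides by a scale computed by the box-plot/percentile rule: values
#' above `Q3 + 1.5 IQR` of the unmasked raw reactivities are excluded as
#' outliers (capped at 10% of the data), and the scale is the mean of the
#' remaining values ranked between their 90th and 98th percentiles, so a
#' profile of identical raw values normalises to 1 (see
#' [shape_norm_scale()]).
#'
#' @param counts Data frame with columns `position`, `mod_count`,
#'   `mod_depth`, `unt_count`, `unt_depth` (e.g. from
#'   [simulate_mutation_counts()] or a mutation-count TSV).
#' @param min_depth Minimum per-channel depth (default 1000).
#' @param clamp_negative Set negative raw reactivities to 0 before
#'   normalisation (default `FALSE`).
#' @return An object of class `shape_profile`: the input plus columns
#'   `mask`, `raw_reactivity`, `normalized_reactivity`, and attribute
#'   `scale`.
#' @export
shape_reactivity <- function(counts, min_depth = 1000, clamp_negative = FALSE) {
  req <- c("position", "mod_count", "mod_depth", "unt_count", "unt_depth")
  if (!all(req %in% names(counts))) {
    stop("counts must have columns: ", paste(req, collapse = ", "))
  }
  if (any(counts$mod_count > counts$mod_depth) ||
      any(counts$unt_count > counts$unt_depth))
    stop("mutation counts exceed depths")
  out <- counts
  out$mask <- counts$mod_depth < min_depth | counts$unt_depth < min_depth
  if (all(out$mask)) stop("insufficient depth: all positions masked")
  rate_mod <- ifelse(out$mask, NA_real_, counts$mod_count / counts$mod_depth)
  rate_unt <- ifelse(out$mask, NA_real_, counts$unt_count / counts$unt_depth)
  raw <- rate_mod - rate_unt
  if (clamp_negative) raw <- pmax(raw, 0)
  scale <- shape_norm_scale(raw[!out$mask])
  out$raw_reactivity <- raw
  out$normalized_reactivity <- raw / scale
  attr(out, "scale") <- scale
  class(out) <- c("shape_profile", class(out))
  out
}

#' Box-plot/percentile normalisation scale for SHAPE reactivities
#'
#' Values more than `1.5 IQR` above the third quartile are excluded as
#' outliers, but never more than 10% of the data (the box-plot rule's cap,
#' which keeps genuinely reactive positions from being discarded wholesale
#' on bimodal profiles). The scale is then the mean of the remaining
#' values ranked between their 90th and 98th percentiles — i.e. the top
#' 2% are dropped and the next 8% averaged.
#'
#' @param raw Unmasked raw reactivities.
#' @return The normalisation scale (a nonzero number).
#' @export
shape_norm_scale <- function(raw) {
  raw <- raw[!is.na(raw)]
  if (length(raw) == 0L) stop("no values to normalise")
  q <- stats::quantile(raw, c(0.25, 0.75), names = FALSE, type = 7)
  cutoff <- q[2L] + 1.5 * (q[2L] - q[1L])
  srt <- sort(raw)  # ascending
  n_out <- min(sum(srt > cutoff), floor(0.1 * length(srt)))
  kept <- if (n_out > 0L) srt[seq_len(length(srt) - n_out)] else srt
  m <- length(kept)
  lo <- floor(0.90 * m) + 1L
  hi <- ceiling(0.98 * m)
  band <- kept[lo:min(hi, m)]
  scale <- mean(band)
  if (!is.finite(scale) || scale == 0)
    stop("degenerate normalisation scale (flat zero profile band)")
  scale
}

#' Classify an RNA by its median SHAPE reactivity
#'
#' Median over unmasked positions of the normalised (default) or raw
#' reactivity; RNAs below `structured_cutoff` are highly structured, those
#' below `intermediate_cutoff` intermediate, the rest flexible. Cutoffs
#' are strict (`<`), so a median exactly at 0.1 is intermediate.
#'
#' @param profile A `shape_profile` from [shape_reactivity()].
#' @param structured_cutoff,intermediate_cutoff Class boundaries (defaults
#'   0.1 and 0.15).
#' @param use Which reactivity to summarise (`"normalized"` or `"raw"`).
#' @return List: `median`, `class` (one of `structured`, `intermediate`,
#'   `flexible`).
#' @export
median_reactivity_class <- function(profile, structured_cutoff = 0.1,
                                    intermediate_cutoff = 0.15,
                                    use = c("normalized", "raw")) {
  use <- match.arg(use)
  col <- if (use == "normalized") "normalized_reactivity" else "raw_reactivity"
  vals <- profile[[col]][!profile$mask]
  med <- stats::median(vals)
  cls <- if (med < structured_cutoff) "structured"
         else if (med < intermediate_cutoff) "intermediate"
         else "flexible"
  list(median = med, class = cls)
}

#' Positional base frequencies in fixed bins
#'
#' Splits each sequence (5' to 3') into consecutive bins of `binsize` nt
#' and tabulates A/C/G/U frequencies per bin per sequence. Sequences
#' contribute only their complete bins. When TSS positions are supplied,
#' alternative TSSs closer than `dedup_distance` are collapsed to a single
#' representative (the first), preventing near-duplicate sequences from
#' inflating the test.
#'
#' @param sequences Named character vector of RNA (or DNA; T is read as U)
#'   sequences, starting at the TSS.
#' @param binsize Bin width, nt (default 200).
#' @param n_bins Number of bins (default 5, i.e. 1 kb total).
#' @param tss_positions Optional numeric vector (same names) of TSS
#'   coordinates used for deduplication.
#' @param dedup_distance Collapse TSSs closer than this (strict `<`,
#'   default 40 nt).
#' @return Data frame: `rna`, `bin` (1-based index), `bin_label`,
#'   `A`, `C`, `G`, `U` (frequencies summing to 1 per row).
#' @export
g_content_bins <- function(sequences, binsize = 200L, n_bins = 5L,
                           tss_positions = NULL, dedup_distance = 40L) {
  if (is.null(names(sequences)) && length(sequences) > 0L)
    names(sequences) <- paste0("rna_", seq_along(sequences))
  if (!is.null(tss_positions)) {
    keep <- rep(TRUE, length(sequences))
    pos <- tss_positions[names(sequences)]
    for (i in seq_along(sequences)) {
      if (!keep[i]) next
      later <- which(seq_along(sequences) > i & keep)
      dup <- later[abs(pos[later] - pos[i]) < dedup_distance]
      keep[dup] <- FALSE
    }
    sequences <- sequences[keep]
  }
  rows <- list()
  for (id in names(sequences)) {
    chars <- toupper(strsplit(sequences[[id]], "")[[1L]])
    chars[chars == "T"] <- "U"
    for (b in seq_len(n_bins)) {
      lo <- (b - 1L) * binsize + 1L
      hi <- b * binsize
      if (hi > length(chars)) break  # incomplete bins are skipped
      counts <- table(factor(chars[lo:hi], levels = c("A", "C", "G", "U")))
      total <- sum(counts)
      if (total == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        rna = id, bin = b,
        bin_label = paste(lo, hi, sep = "-"),
        A = counts[["A"]] / total, C = counts[["C"]] / total,
        G = counts[["G"]] / total, U = counts[["U"]] / total
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise t-tests for G enrichment per bin
#'
#' For each bin, paired two-sided t-tests across RNAs of the G frequency
#' against each other base's frequency (A/G, C/G, U/G). Raw p-values are
#' reported alongside Benjamini-Hochberg-adjusted values (adjustment over
#' all bin x comparison tests).
#'
#' @param bins Bin-frequency data frame from [g_content_bins()].
#' @return Data frame: `bin`, `bin_label`, `comparison`, `t`, `df`,
#'   `p_value`, `p_adjusted`.
#' @export
g_enrichment_test <- function(bins) {
  rows <- list()
  for (b in sort(unique(bins$bin))) {
    sub <- bins[bins$bin == b, , drop = FALSE]
    for (other in c("A", "C", "U")) {
      diff <- sub$G - sub[[other]]
      if (length(diff) < 2L) next
      tt <- if (stats::sd(diff) == 0) {
        # degenerate paired test: identical columns give t = 0, p = 1; a
        # constant nonzero difference is infinitely significant
        if (mean(diff) == 0) {
          list(statistic = 0, parameter = length(diff) - 1L, p.value = 1)
        } else {
          list(statistic = sign(mean(diff)) * Inf,
               parameter = length(diff) - 1L, p.value = 0)
        }
      } else {
        stats::t.test(sub$G, sub[[other]], paired = TRUE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, bin_label = sub$bin_label[1L],
        comparison = paste0(other, "/G"),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
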