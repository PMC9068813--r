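# Pausing-index computation from strand-specific nascent coverage, NELF
# occupancy grouping, and comparison of PI distributions across conditions.

#' Promoter-proximal pausing index of one transcript unit
#'
#' Ratio of nascent-read density in the promoter-proximal window (100 bp
#' upstream to 200 bp downstream of the TSS) to density in the gene-body
#' window (400 to 800 bp downstream of the TSS). Windows are oriented by
#' the unit's strand: upstream/downstream flip on the minus strand. The PI
#' is undefined (`NA`, not infinite) when the body density is zero.
#'
#' @param track A `coverage_track` of nascent (GRO-seq-like) signal.
#' @param unit One-row transcript-unit data frame (`chrom`, `start`, `end`,
#'   `strand`, optionally `id`).
#' @param promoter_window,body_window Window edges in transcript
#'   coordinates relative to the TSS (0 = TSS, negative upstream),
#'   half-open.
#' @return One-row data frame: `unit`, `promoter_density`, `body_density`,
#'   `pi` (`NA` when undefined).
#' @export
pausing_index <- function(track, unit,
                          promoter_window = c(-100L, 200L),
                          body_window = c(400L, 800L)) {
  strand <- unit$strand
  tss <- if (strand == "+") unit$start else unit$end - 1L
  # transcript offsets [a, b) map to genomic [tss + a, tss + b) on plus and
  # [tss - b + 1, tss - a + 1) on minus
  win <- function(w) {
    if (strand == "+") c(tss + w[1L], tss + w[2L])
    else c(tss - w[2L] + 1L, tss - w[1L] + 1L)
  }
  pw <- win(promoter_window)
  bw <- win(body_window)
  size <- track$chrom_sizes[[unit$chrom]]
  if (is.null(size)) stop("unknown chromosome: ", unit$chrom)
  if (pw[1L] < 0L || bw[1L] < 0L || pw[2L] > size || bw[2L] > size) {
    warning("pausing-index windows out of bounds for unit ",
            unit$id %||% "?", ": skipped")
    return(data.frame(unit = unit$id %||% NA_character_,
                      promoter_density = NA_real_, body_density = NA_real_,
                      pi = NA_real_))
  }
  pd <- window_density(track, unit$chrom, pw[1L], pw[2L], strand)
  bd <- window_density(track, unit$chrom, bw[1L], bw[2L], strand)
  data.frame(unit = unit$id %||% NA_character_,
             promoter_density = pd, body_density = bd,
             pi = if (bd == 0) NA_real_ else pd / bd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pausing indices for a table of transcript units
#'
#' Vectorised wrapper around [pausing_index()]. Units whose windows fall
#' outside chromosome bounds are skipped with a warning; units with zero
#' body density get `NA` and are counted in the `excluded` attribute.
#'
#' @inheritParams pausing_index
#' @param units Transcript-unit data frame.
#' @return Data frame with one row per unit and attribute
#'   `excluded_undefined` (count of zero-body-density units).
#' @export
pausing_index_table <- function(track, units,
                                promoter_window = c(-100L, 200L),
                                body_window = c(400L, 800L)) {
  rows <- lapply(seq_len(nrow(units)), function(i)
    pausing_index(track, units[i, ], promoter_window, body_window))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded_undefined") <-
    sum(is.na(out$pi) & !is.na(out$promoter_density))
  out
}

#' Group transcript units by NELF occupancy
#'
#' A unit is NELF-bound when its promoter ChIP score reaches
#' `bound_threshold` (or, if `peaks` is given, when its promoter overlaps a
#' called NELF peak). Bound units are split at configurable score
#' quantiles (tertiles by default) into `low`/`mid`/`high` tiers; unbound
#' units get tier `unbound`.
#'
#' @param chip_scores Named numeric vector of promoter NELF ChIP scores
#'   (names = unit ids).
#' @param bound_threshold Minimum score for "bound" (default: any positive
#'   score). Ignored when `peak_overlap` is given.
#' @param tier_quantiles Interior quantile cut points among bound units
#'   (default tertiles `c(1/3, 2/3)`).
#' @param peak_overlap Optional named logical vector: does the unit's
#'   promoter overlap a NELF peak?
#' @return Data frame: `unit`, `score`, `bound`, `tier` (factor
#'   `unbound < low < mid < high`).
#' @export
nelf_tiers <- function(chip_scores, bound_threshold = NULL,
                       tier_quantiles = c(1 / 3, 2 / 3),
                       peak_overlap = NULL) {
  ids <- names(chip_scores)
  if (is.null(ids)) stop("chip_scores must be named by unit id")
  bound <- if (!is.null(peak_overlap)) {
    as.logical(peak_overlap[ids])
  } else if (!is.null(bound_threshold)) {
    chip_scores >= bound_threshold
  } else {
    chip_scores > 0
  }
  tier <- rep("unbound", length(ids))
  if (any(bound)) {
    cuts <- stats::quantile(chip_scores[bound], probs = tier_quantiles,
                            names = FALSE, type = 7)
    labs <- c("low", "mid", "high")
    tier[bound] <- labs[findInterval(chip_scores[bound], cuts,
                                     left.open = TRUE) + 1L]
  }
  data.frame(
    unit = ids, score = unname(chip_scores), bound = unname(bound),
    tier = factor(tier, levels = c("unbound", "low", "mid", "high"),
                  ordered = TRUE)
  )
}

#' Compare two pausing-index distributions (two-sample KS test)
#'
#' Undefined (`NA`) PI values are dropped before testing. Returns the KS
#' statistic, p-value, and the empirical cumulative curves for plotting.
#'
#' @param pis_a,pis_b Numeric PI vectors (may contain `NA`).
#' @return List: `statistic` (D), `p_value`, `n_a`, `n_b`, `ecdf_a`,
#'   `ecdf_b` (data frames of sorted values and cumulative probability).
#' @export
compare_pi_distributions <- function(pis_a, pis_b) {
  a <- pis_a[!is.na(pis_a)]
  b <- pis_b[!is.na(pis_b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("need at least one defined PI value per sample")
  kt <- suppressWarnings(stats::ks.test(a, b))
  ecdf_tab <- function(x) {
    xs <- sort(x)
    data.frame(pi = xs, cumulative = seq_along(xs) / length(xs))
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b),
       ecdf_a = ecdf_tab(a), ecdf_b = ecdf_tab(b))
}
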