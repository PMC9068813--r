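# Crosslinking-MS post-search processing: quality filtering of search
# result tables, per-residue aggregation of redundant spectral counts
# (nseen), and subunit/domain crosslink proportions.

#' Filter crosslink-search records by quality thresholds
#'
#' Keeps records meeting all three post-search thresholds (`>=` semantics,
#' so a record exactly at a threshold is kept): matched-ion count
#' (`minions`), total-ion-current subscore (`tic`), and search identification
#' score (`id_score`). Decoy records are subjected to the same thresholds
#' and retained, flagged, so a decoy-based FDR can be estimated among the
#' survivors.
#'
#' @param records Data frame with columns `subunit`, `residue`, `nseen`,
#'   `minions`, `tic`, `id_score` and optionally `decoy` (logical,
#'   defaults to all `FALSE`).
#' @param min_minions,min_tic,min_score Thresholds (defaults 7, 0.15, 20).
#' @return The surviving records, with attribute `fdr_estimate`
#'   (decoy/target ratio among survivors; `NA` when no targets survive).
#' @export
filter_xl <- function(records, min_minions = 7, min_tic = 0.15,
                      min_score = 20) {
  if (any(records$nseen < 1)) stop("nseen must be >= 1")
  if (any(records$tic < 0 | records$tic > 1)) stop("tic must lie in [0, 1]")
  if (is.null(records$decoy)) records$decoy <- FALSE
  keep <- records$minions >= min_minions & records$tic >= min_tic &
    records$id_score >= min_score
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  n_target <- sum(!out$decoy)
  attr(out, "fdr_estimate") <-
    if (n_target > 0) sum(out$decoy) / n_target else NA_real_
  out
}

#' Aggregate redundant spectral counts per residue
#'
#' Sums `nseen` over all records at the same (subunit, residue) position.
#' Decoy records are excluded from aggregation. Listed exclusions — e.g. an
#' overrepresented N-terminal methionine treated as an outlier — are
#' omitted from the output and reported in the `excluded` attribute.
#'
#' @param records Filtered crosslink records (see [filter_xl()]).
#' @param exclusions Character vector of `"subunit:residue"` pairs to omit
#'   (e.g. `"NELF-E:1"`), or a two-column data frame
#'   (`subunit`, `residue`).
#' @return Data frame `subunit`, `residue`, `nseen_total`, sorted; with
#'   attribute `excluded` (the omitted rows, aggregated).
#' @export
aggregate_per_residue <- function(records, exclusions = character(0)) {
  if (is.null(records$decoy)) records$decoy <- FALSE
  tgt <- records[!records$decoy, , drop = FALSE]
  if (is.data.frame(exclusions)) {
    excl_keys <- paste(exclusions$subunit, exclusions$residue, sep = ":")
  } else {
    excl_keys <- as.character(exclusions)
  }
  if (nrow(tgt) == 0L) {
    out <- data.frame(subunit = character(), residue = integer(),
                      nseen_total = numeric())
    attr(out, "excluded") <- out
    return(out)
  }
  agg <- stats::aggregate(nseen ~ subunit + residue, data = tgt, FUN = sum)
  names(agg)[names(agg) == "nseen"] <- "nseen_total"
  agg <- agg[order(agg$subunit, agg$residue), , drop = FALSE]
  rownames(agg) <- NULL
  keys <- paste(agg$subunit, agg$residue, sep = ":")
  is_excluded <- keys %in% excl_keys
  out <- agg[!is_excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- agg[is_excluded, , drop = FALSE]
  out
}

#' Default NELF domain spans (residue intervals per subunit)
#'
#' The spans used to split crosslink totals within a subunit: the NELF-E
#' N-terminal region (1-138) vs the NELF-E tentacle (138-380, which
#' includes the RRM domain), and the NELF-AC lobe (NELF-A 1-187) vs the
#' NELF-A tentacle (188-528).
#'
#' @return Data frame `subunit`, `domain`, `from`, `to` (1-based inclusive).
#' @export
nelf_domain_spans <- function() {
  data.frame(
    subunit = c("NELF-E", "NELF-E", "NELF-A", "NELF-A"),
    domain  = c("N-terminal", "tentacle", "AC-lobe", "tentacle"),
    from    = c(1L, 138L, 1L, 188L),
    to      = c(137L, 380L, 187L, 528L)
  )
}

#' Crosslink proportions per subunit and per domain span
#'
#' Subunit proportions are each subunit's share of the grand total of
#' aggregated spectral counts (summing to 1). Within a subunit, counts are
#' additionally split over the supplied residue spans; the per-domain
#' shares of a subunit sum to that subunit's overall share (residues
#' outside every span are reported as domain `other`).
#'
#' @param per_residue Per-residue totals from [aggregate_per_residue()].
#' @param domain_spans Data frame `subunit`, `domain`, `from`, `to`
#'   (1-based inclusive residue spans); default [nelf_domain_spans()].
#' @return List: `subunits` (data frame `subunit`, `nseen_total`,
#'   `proportion`) and `domains` (data frame `subunit`, `domain`,
#'   `nseen_total`, `proportion_of_total`, `proportion_of_subunit`).
#' @export
subunit_proportions <- function(per_residue, domain_spans = nelf_domain_spans()) {
  grand <- sum(per_residue$nseen_total)
  if (grand == 0) stop("no crosslink counts to summarise")
  sub_tot <- stats::aggregate(nseen_total ~ subunit, data = per_residue,
                              FUN = sum)
  sub_tot$proportion <- sub_tot$nseen_total / grand

  dom_rows <- list()
  for (s in unique(per_residue$subunit)) {
    pr <- per_residue[per_residue$subunit == s, , drop = FALSE]
    spans <- domain_spans[domain_spans$subunit == s, , drop = FALSE]
    covered <- rep(FALSE, nrow(pr))
    for (j in seq_len(nrow(spans))) {
      inside <- pr$residue >= spans$from[j] & pr$residue <= spans$to[j]
      covered <- covered | inside
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        subunit = s, domain = spans$domain[j],
        nseen_total = sum(pr$nseen_total[inside])
      )
    }
    if (any(!covered)) {
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        subunit = s, domain = "other",
        nseen_total = sum(pr$nseen_total[!covered])
      )
    }
  }
  domains <- do.call(rbind, dom_rows)
  rownames(domains) <- NULL
  domains$proportion_of_total <- domains$nseen_total / grand
  sub_lookup <- stats::setNames(sub_tot$nseen_total, sub_tot$subunit)
  domains$proportion_of_subunit <-
    domains$nseen_total / sub_lookup[domains$subunit]

  list(subunits = sub_tot, domains = domains)
}
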