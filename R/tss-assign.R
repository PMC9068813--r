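# TSS calling from 5'-end read pileups, extragenic filtering, assignment of
# one high-confidence TSS per enhancer transcript unit, and activity-
# induction classification.

#' Call TSSs from a 5'-end site table
#'
#' Strand-wise single-linkage clustering of read positions: positions on
#' the same chromosome and strand whose gap is at most `merge_gap` join one
#' cluster. Clusters whose total read count falls below `min_cluster_reads`
#' are dropped. The called TSS is the position of maximum count within the
#' cluster; ties break toward the most upstream position in transcript
#' orientation (smallest coordinate on `+`, largest on `-`). A call is
#' flagged `well_defined` when its read count exceeds
#' `well_defined_reads` — a two-tier usage where the flag marks
#' high-confidence 5' ends without filtering the call set. By default the
#' flag is computed on the called position; set `well_defined_on = "cluster"`
#' to count the whole cluster instead.
#'
#' @param sites Site-table data frame (`chrom`, `pos`, `strand`, `count`).
#' @param min_cluster_reads Minimum total reads per cluster (default 5).
#' @param merge_gap Maximum gap (nt) joining positions into one cluster
#'   (default 25).
#' @param well_defined_reads Read-count threshold for the `well_defined`
#'   flag (strict `>`, default 20).
#' @param well_defined_on Count the called position (`"position"`, default)
#'   or the whole cluster (`"cluster"`) against `well_defined_reads`.
#' @return Data frame of calls: `chrom`, `pos`, `strand`, `read_count`
#'   (at the called position), `cluster_start`, `cluster_end` (0-based
#'   half-open span), `cluster_count`, `well_defined`.
#' @export
call_tss <- function(sites, min_cluster_reads = 5, merge_gap = 25,
                     well_defined_reads = 20,
                     well_defined_on = c("position", "cluster")) {
  well_defined_on <- match.arg(well_defined_on)
  if (merge_gap < 0) stop("merge_gap must be >= 0")
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), read_count = numeric(),
                      cluster_start = integer(), cluster_end = integer(),
                      cluster_count = numeric(), well_defined = logical())
  if (nrow(sites) == 0L) return(empty)
  if (any(sites$count < 1)) stop("site counts must be >= 1")

  out <- list()
  for (key in split(seq_len(nrow(sites)),
                    paste(sites$chrom, sites$strand, sep = "\r"))) {
    sub <- sites[key, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    # single-linkage: new cluster where the gap to the previous position
    # exceeds merge_gap
    gap <- c(Inf, diff(sub$pos))
    cluster_id <- cumsum(gap > merge_gap)
    for (cl in split(seq_len(nrow(sub)), cluster_id)) {
      cc <- sub[cl, , drop = FALSE]
      total <- sum(cc$count)
      if (total < min_cluster_reads) next
      top <- which(cc$count == max(cc$count))
      # tie toward the 5'-most position in transcript orientation
      peak <- if (cc$strand[1L] == "-") max(top) else min(top)
      read_count <- cc$count[peak]
      wd_count <- if (well_defined_on == "cluster") total else read_count
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc$chrom[1L], pos = cc$pos[peak], strand = cc$strand[1L],
        read_count = read_count,
        cluster_start = min(cc$pos), cluster_end = max(cc$pos) + 1L,
        cluster_count = total,
        well_defined = wd_count > well_defined_reads
      )
    }
  }
  if (length(out) == 0L) return(empty)
  calls <- do.call(rbind, out)
  calls <- calls[order(calls$chrom, calls$strand, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Remove TSS calls inside genes extended by a flank
#'
#' Keeps only extragenic calls: a call is removed, strand-agnostically,
#' when its position falls within any gene interval extended by `flank` bp
#' on both sides. The extension stays half-open, so a call exactly at
#' `gene_end + flank` is kept.
#'
#' @param calls TSS-call data frame from [call_tss()].
#' @param genes Gene annotation: `GRanges` (from [read_bed()]) or a data
#'   frame with `chrom`, `start`, `end` (0-based half-open).
#' @param flank Flank size in bp (default 2000).
#' @return The retained calls.
#' @export
filter_extragenic <- function(calls, genes, flank = 2000) {
  if (nrow(calls) == 0L) return(calls)
  if (inherits(genes, "GRanges")) {
    genes <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(genes)),
      start = GenomicRanges::start(genes) - 1L,
      end   = GenomicRanges::end(genes)
    )
  }
  call_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(start = calls$pos + 1L, width = 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(genes$start - flank, 0) + 1L,
                     end = genes$end + flank)
  )
  hits <- GenomicRanges::findOverlaps(call_gr, gene_gr, ignore.strand = TRUE)
  drop <- unique(S4Vectors::queryHits(hits))
  kept <- calls[setdiff(seq_len(nrow(calls)), drop), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

.unit_5prime <- function(units) {
  ifelse(units$strand == "+", units$start, units$end - 1L)
}

#' Signed distance of positions from a unit's 5' end
#'
#' Positive downstream of the 5' end in transcript orientation.
#' @noRd
.signed_distance <- function(pos, unit5p, strand) {
  strand <- rep_len(strand, length(pos))
  unit5p <- rep_len(unit5p, length(pos))
  ifelse(strand == "+", pos - unit5p, unit5p - pos)
}

#' Assign one high-confidence TSS to each enhancer transcript unit
#'
#' Candidate calls for a unit are those on the unit's strand whose position
#' lies within the unit extended by `offset` nt on both sides. Exactly one
#' winner per unit: highest read count first, ties broken by smallest
#' absolute distance to the unit's 5' end, remaining ties by the most
#' upstream position. A call inside two overlapping units may be assigned
#' to both. Optionally, units whose antisense 5'-end signal around the
#' winning TSS exceeds `max_antisense_fraction` of the sense signal are
#' rejected — an explicit surrogate for curating out pervasive/convergent
#' transcription.
#'
#' @param calls TSS-call data frame from [call_tss()].
#' @param units Enhancer transcript-unit data frame (`id`, `chrom`,
#'   `start`, `end`, `strand`).
#' @param offset Extension of the unit on both sides, nt (default 200).
#' @param sites Optional site table for the antisense check.
#' @param max_antisense_fraction Reject a unit when antisense signal within
#'   +/-200 nt of its assigned TSS exceeds this fraction of sense signal
#'   (default 0.5); only applied when `sites` is given.
#' @return Data frame, one row per unit: `unit`, `assigned` (logical),
#'   `pos`, `read_count`, `distance_to_unit_5p` (signed, positive
#'   downstream), `well_defined`, `convergent_rejected`.
#' @export
assign_enhancer_tss <- function(calls, units, offset = 200, sites = NULL,
                                max_antisense_fraction = 0.5) {
  if (offset < 0) stop("offset must be >= 0")
  unit5p <- .unit_5prime(units)
  res <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    cand <- calls[calls$chrom == u$chrom & calls$strand == u$strand &
                    calls$pos >= u$start - offset &
                    calls$pos < u$end + offset, , drop = FALSE]
    base <- data.frame(unit = u$id, assigned = FALSE, pos = NA_integer_,
                       read_count = NA_real_,
                       distance_to_unit_5p = NA_integer_,
                       well_defined = NA, convergent_rejected = FALSE)
    if (nrow(cand) == 0L) return(base)
    dist <- .signed_distance(cand$pos, unit5p[i], u$strand)
    upstream_rank <- if (u$strand == "+") cand$pos else -cand$pos
    ord <- order(-cand$read_count, abs(dist), upstream_rank)
    w <- ord[1L]
    base$assigned <- TRUE
    base$pos <- cand$pos[w]
    base$read_count <- cand$read_count[w]
    base$distance_to_unit_5p <- dist[w]
    base$well_defined <- cand$well_defined[w]
    if (!is.null(sites)) {
      near <- sites$chrom == u$chrom & abs(sites$pos - cand$pos[w]) <= 200
      sense <- sum(sites$count[near & sites$strand == u$strand])
      anti  <- sum(sites$count[near & sites$strand != u$strand])
      if (sense > 0 && anti / sense > max_antisense_fraction) {
        base$assigned <- FALSE
        base$convergent_rejected <- TRUE
      }
    }
    base
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Classify transcript units as activity-induced
#'
#' A unit is induced when the maximum fold change of its expression over
#' the baseline condition across all stimulated conditions strictly exceeds
#' `fold_threshold`. With the default pseudocount of 0, a unit with zero
#' baseline and any nonzero stimulated signal is induced; a unit with zero
#' signal everywhere is not.
#'
#' @param units Transcript-unit data frame carrying an `expression` matrix
#'   column (conditions in columns), or a plain matrix of expression values.
#' @param baseline_condition Column name of the baseline (default: first
#'   column).
#' @param fold_threshold Strict fold-change threshold (default 1.5).
#' @param pseudocount Added to numerator and denominator (default 0).
#' @return Logical vector, `TRUE` for induced units.
#' @export
classify_induction <- function(units, baseline_condition = NULL,
                               fold_threshold = 1.5, pseudocount = 0) {
  expr <- if (is.matrix(units)) units else units$expression
  if (is.null(expr)) stop("units must carry an expression matrix")
  if (any(expr < 0)) stop("expression values must be >= 0")
  if (is.null(baseline_condition)) baseline_condition <- colnames(expr)[1L]
  stim <- setdiff(colnames(expr), baseline_condition)
  if (length(stim) == 0L) stop("no stimulated conditions")
  base <- expr[, baseline_condition] + pseudocount
  fc <- (expr[, stim, drop = FALSE] + pseudocount) / base
  # 0/0 (flat zero unit) is not induced; x/0 with x > 0 is
  fc[is.nan(fc)] <- 0
  apply(fc, 1L, max) > fold_threshold
}
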