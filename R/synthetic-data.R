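# Synthetic-data generators. Every generator emits ground truth alongside
# the data (as attributes or list elements) so that each downstream stage
# can be tested for parameter recovery without any external download.
#
# Reproducibility: one global seed; each generator draws from its own
# substream derived by a fixed offset, so stages stay deterministic when
# run alone or in any order.

.SEED_OFFSETS <- c(nascent = 101L, fiveprime = 202L, crosslink = 303L,
                   binding = 404L, shape = 505L, xlms = 606L)

#' Write a generator's ground truth as a JSON sidecar
#'
#' Companion to the `simulate_*` generators: when a synthetic dataset is
#' written to disk (e.g. via [write_site_table()] or
#' [write_bedgraph_pair()]), its `truth` attribute can be stored alongside
#' so recovery experiments can be replayed from files alone.
#'
#' @param truth The `truth` attribute (or list element) of a generated
#'   dataset.
#' @param path Output path, conventionally `<dataset>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_truth_json requires the jsonlite package")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Simulation configuration
#'
#' Bundles the parameters of all synthetic-data generators. Defaults mirror
#' the experimental conditions the package models: a PEC (receptor) total
#' of 0.1 uM with the eRNA titration series 0.15-1.8 uM, ~70% of NELF
#' crosslink sites within the first 200 nt of a transcript, SHAPE
#' modification rates of 0.05 (unpaired) vs 0.005 (paired) against an
#' untreated error rate of 0.002, and KCl stimulation time points
#' 0/10/30/60 min.
#'
#' @param seed Integer seed; per-generator substreams are derived from it
#'   by fixed offsets.
#' @param n_genes,n_enhancers Number of gene / eRNA transcript units.
#' @param chrom_length Chromosome length (bp) of the synthetic genome.
#' @param gene_length Length of each gene unit (bp, >= 1200 so that both
#'   pausing-index windows fit).
#' @param pausing_index_true Generating pausing index, recycled per gene.
#' @param reads_per_gene Expected nascent reads per gene at baseline.
#' @param conditions Condition labels; the first is the baseline.
#' @param induction_fold Per-condition fold change of unit signal relative
#'   to baseline (recycled over units x conditions).
#' @param tss_mean_reads Mean 5'-end read count at a true TSS.
#' @param tss_jitter_probs Probability mass on read offsets -2..+2 nt
#'   around the true TSS.
#' @param background_rate Uniform 5'-end background, reads per bp per strand.
#' @param crosslink_5prime_fraction Probability mass of a crosslink falling
#'   within the first 200 nt of its transcript.
#' @param n_crosslinks Total simulated crosslink reads.
#' @param kd_true,amplitude_true,receptor_total,noise_sd Quadratic binding
#'   model truth (uM, fraction units) and additive Gaussian noise SD on
#'   release fractions.
#' @param mod_rate_unpaired,mod_rate_paired,untreated_rate Per-read
#'   mutation probabilities for the SHAPE channels.
#' @param shape_depth Read depth per position for SHAPE counts.
#' @param xl_n_rows,xl_decoy_rate,xl_subunits Crosslink-MS table size,
#'   decoy fraction, and subunit names with lengths.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       n_enhancers = 10L,
                       chrom_length = 1000000L,
                       gene_length = 2000L,
                       pausing_index_true = 5,
                       reads_per_gene = 10000,
                       conditions = c("KCl_0", "KCl_10", "KCl_30", "KCl_60"),
                       induction_fold = 1,
                       tss_mean_reads = 50,
                       tss_jitter_probs = c(0.02, 0.08, 0.80, 0.08, 0.02),
                       background_rate = 0.01,
                       crosslink_5prime_fraction = 0.7,
                       n_crosslinks = 10000L,
                       kd_true = 0.14,
                       amplitude_true = 1,
                       receptor_total = 0.1,
                       noise_sd = 0.05,
                       mod_rate_unpaired = 0.05,
                       mod_rate_paired = 0.005,
                       untreated_rate = 0.002,
                       shape_depth = 10000L,
                       xl_n_rows = 500L,
                       xl_decoy_rate = 0.05,
                       xl_subunits = c("NELF-A" = 528L, "NELF-B" = 580L,
                                       "NELF-C" = 590L, "NELF-E" = 380L)) {
  cfg <- as.list(environment())
  rates <- c(cfg$crosslink_5prime_fraction, cfg$noise_sd,
             cfg$mod_rate_unpaired, cfg$mod_rate_paired, cfg$untreated_rate,
             cfg$xl_decoy_rate)
  if (any(rates < 0 | rates > 1)) stop("rates/probabilities must lie in [0, 1]")
  if (cfg$kd_true <= 0) stop("kd_true must be > 0")
  if (any(cfg$pausing_index_true <= 0)) stop("pausing_index_true must be > 0")
  if (cfg$amplitude_true <= 0 || cfg$amplitude_true > 1)
    stop("amplitude_true must lie in (0, 1]")
  if (cfg$gene_length < 1200L)
    stop("gene_length must be >= 1200 bp so both pausing-index windows fit")
  if (abs(sum(cfg$tss_jitter_probs) - 1) > 1e-9)
    stop("tss_jitter_probs must sum to 1")
  structure(cfg, class = "sim_config")
}

.sim_seed <- function(config, stream) {
  set.seed(config$seed + .SEED_OFFSETS[[stream]])
}

.evenly_spaced_tss <- function(n, chrom_length, footprint, margin = 1000L) {
  usable <- chrom_length - 2L * margin
  if (n * footprint > usable) stop("chromosome too short for requested units")
  spacing <- usable %/% n
  as.integer(margin + spacing * (seq_len(n) - 1L))
}

#' Simulate nascent (GRO-seq-like) coverage with a paused promoter peak
#'
#' Each gene gets a promoter-proximal window (TSS-100 to TSS+200 in
#' transcript orientation) whose per-base read weight is
#' `pausing_index_true` times the weight everywhere else in the gene, so
#' the expected promoter/body density ratio equals the generating pausing
#' index. Reads are multinomial over positions. One coverage track per
#' condition; a unit's read total scales with its `induction_fold` for that
#' condition. Genes alternate between the two strands.
#'
#' @param config A [sim_config()].
#' @return A list with `tracks` (named list of `coverage_track`, one per
#'   condition), `units` (transcript-unit data frame with an `expression`
#'   matrix column of measured reads/bp per condition), and `truth`
#'   (per-gene generating pausing index and expected read counts).
#' @export
simulate_nascent_coverage <- function(config) {
  .sim_seed(config, "nascent")
  n <- config$n_genes
  glen <- config$gene_length
  pi_true <- rep_len(config$pausing_index_true, n)
  tss <- .evenly_spaced_tss(n, config$chrom_length, glen + 200L,
                            margin = glen + 200L)
  strand <- rep_len(c("+", "-"), n)
  conditions <- config$conditions
  nc <- length(conditions)
  f <- config$induction_fold
  # scalar: flat; vector of length n_conditions: per-condition fold shared
  # by all units; matrix: per-unit, per-condition
  fold <- if (is.matrix(f)) {
    if (!all(dim(f) == c(n, nc))) stop("induction_fold matrix must be n_genes x n_conditions")
    f
  } else if (length(f) == nc && nc > 1L) {
    matrix(f, nrow = n, ncol = nc, byrow = TRUE)
  } else {
    matrix(rep_len(f, n * nc), nrow = n)
  }
  dimnames(fold) <- list(NULL, conditions)
  fold[, 1L] <- 1  # baseline

  if (any(tss - 100L < 0L) || any(tss + glen > config$chrom_length))
    stop("pausing-index windows overflow past chromosome end")

  tracks <- lapply(conditions, function(cond) coverage_track(
    stats::setNames(config$chrom_length, "chr1")))
  names(tracks) <- conditions
  expression <- matrix(0, nrow = n, ncol = length(conditions),
                       dimnames = list(NULL, conditions))

  # transcript-orientation offsets -100 .. glen-1 relative to TSS
  offsets <- seq(-100L, glen - 1L)

  for (g in seq_len(n)) {
    weights <- ifelse(offsets < 200L, pi_true[g], 1)
    prob <- weights / sum(weights)
    for (ci in seq_along(conditions)) {
      n_reads <- stats::rpois(1L, config$reads_per_gene * fold[g, ci])
      if (n_reads == 0L) next
      counts <- stats::rmultinom(1L, n_reads, prob)[, 1L]
      hit <- counts > 0L
      d <- offsets[hit]
      pos <- if (strand[g] == "+") tss[g] + d else tss[g] - d
      tracks[[ci]] <- add_sites(tracks[[ci]], "chr1", pos, strand[g],
                                counts[hit])
      expression[g, ci] <- n_reads / glen
    }
  }

  units <- data.frame(
    id = sprintf("gene_%03d", seq_len(n)),
    chrom = "chr1",
    start = ifelse(strand == "+", tss, tss - glen + 1L),
    end   = ifelse(strand == "+", tss + glen, tss + 1L),
    strand = strand,
    kind = "gene",
    stringsAsFactors = FALSE
  )
  units$expression <- expression

  list(tracks = tracks, units = units,
       truth = list(pausing_index = pi_true, tss = tss, strand = strand,
                    induction_fold = fold))
}

#' Simulate single-nucleotide 5'-end (Exo-seq-like) read pileups
#'
#' Spikes of reads at known TSS positions with +/-2 nt jitter mass, over a
#' uniform per-base background on both strands.
#'
#' @param config A [sim_config()].
#' @param tss_positions 0-based true TSS positions; defaults to
#'   `n_enhancers` evenly spaced positions.
#' @param tss_strand Strand per TSS (recycled).
#' @return A site-table data frame (`chrom`, `pos`, `strand`, `count`) with
#'   attribute `truth` (the generating TSS table).
#' @export
simulate_5prime_reads <- function(config, tss_positions = NULL,
                                  tss_strand = "+") {
  .sim_seed(config, "fiveprime")
  if (is.null(tss_positions)) {
    tss_positions <- .evenly_spaced_tss(config$n_enhancers,
                                        config$chrom_length, 1000L)
  }
  if (any(tss_positions < 2L) || any(tss_positions >= config$chrom_length - 2L))
    stop("tss_positions (with jitter span) outside chromosome bounds")
  strand <- rep_len(tss_strand, length(tss_positions))

  pos_all <- integer(0); strand_all <- character(0)
  for (i in seq_along(tss_positions)) {
    n_reads <- stats::rpois(1L, config$tss_mean_reads)
    if (n_reads == 0L) next
    jit <- sample(-2:2, n_reads, replace = TRUE, prob = config$tss_jitter_probs)
    pos_all <- c(pos_all, tss_positions[i] + jit)
    strand_all <- c(strand_all, rep(strand[i], n_reads))
  }
  for (s in STRANDS) {
    n_bg <- stats::rpois(1L, config$background_rate * config$chrom_length)
    if (n_bg == 0L) next
    pos_all <- c(pos_all, sample.int(config$chrom_length, n_bg,
                                     replace = TRUE) - 1L)
    strand_all <- c(strand_all, rep(s, n_bg))
  }
  tab <- stats::aggregate(
    count ~ chrom + pos + strand,
    data = data.frame(chrom = "chr1", pos = pos_all, strand = strand_all,
                      count = 1),
    FUN = sum
  )
  tab <- tab[order(tab$strand, tab$pos), c("chrom", "pos", "strand", "count")]
  rownames(tab) <- NULL
  attr(tab, "truth") <- data.frame(tss = tss_positions, strand = strand)
  tab
}

#' Simulate crosslink sites from a 5'-biased mixture over transcripts
#'
#' For each crosslink read, a transcript unit is picked uniformly and the
#' 0-based distance from its 5' end is drawn from a two-component mixture:
#' with probability `crosslink_5prime_fraction` uniform on the first 200
#' nt, otherwise uniform on the remaining transcript length. Units shorter
#' than 200 nt collapse to a uniform draw, with a warning.
#'
#' @param config A [sim_config()].
#' @param units Transcript-unit data frame (`chrom`, `start`, `end`,
#'   `strand`, `id`).
#' @return A site-table data frame with attribute `truth` listing the
#'   generating mixture fraction and the drawn per-read distances.
#' @export
simulate_crosslink_sites <- function(config, units) {
  .sim_seed(config, "crosslink")
  n <- config$n_crosslinks
  lens <- units$end - units$start
  if (any(lens <= 200L)) {
    warning("unit(s) shorter than 200 nt: mixture collapses to uniform")
  }
  pick <- sample.int(nrow(units), n, replace = TRUE)
  in5p <- stats::runif(n) < config$crosslink_5prime_fraction
  dist0 <- integer(n)   # 0-based distance from 5' end
  for (i in seq_len(n)) {
    len <- lens[pick[i]]
    if (len <= 200L) {
      dist0[i] <- sample.int(len, 1L) - 1L
    } else if (in5p[i]) {
      dist0[i] <- sample.int(200L, 1L) - 1L
    } else {
      dist0[i] <- 199L + sample.int(len - 200L, 1L)
    }
  }
  on_plus <- units$strand[pick] == "+"
  pos <- ifelse(on_plus, units$start[pick] + dist0,
                units$end[pick] - 1L - dist0)
  tab <- stats::aggregate(
    count ~ chrom + pos + strand,
    data = data.frame(chrom = units$chrom[pick], pos = pos,
                      strand = units$strand[pick], count = 1),
    FUN = sum
  )
  tab <- tab[order(tab$chrom, tab$strand, tab$pos),
             c("chrom", "pos", "strand", "count")]
  rownames(tab) <- NULL
  attr(tab, "truth") <- list(
    fraction_5prime = config$crosslink_5prime_fraction,
    unit = units$id[pick], distance = dist0 + 1L  # 1-based, as reported
  )
  tab
}

#' Simulate a release (pseudo-binding) curve from the quadratic model
#'
#' Evaluates [quadratic_model()] at the given concentration series with the
#' configured true Kd and amplitude, then adds Gaussian noise of SD
#' `noise_sd` truncated to \[0, 1\].
#'
#' @param config A [sim_config()].
#' @param concentrations Ligand series, uM; defaults to the titration
#'   series 0.15, 0.3, 0.6, 0.9, 1.2, 1.8.
#' @param n_replicates Number of noisy replicate columns.
#' @return A [binding_curve()] with attribute `truth`.
#' @export
simulate_binding_curve <- function(config,
                                   concentrations = c(0.15, 0.3, 0.6, 0.9, 1.2, 1.8),
                                   n_replicates = 1L) {
  .sim_seed(config, "binding")
  f <- quadratic_model(concentrations, config$kd_true, config$amplitude_true,
                       config$receptor_total)
  frac <- matrix(rep(f, n_replicates), ncol = n_replicates)
  if (config$noise_sd > 0) {
    frac <- frac + stats::rnorm(length(frac), 0, config$noise_sd)
    frac <- pmin(pmax(frac, 0), 1)
  }
  curve <- binding_curve(concentrations, frac, config$receptor_total)
  attr(curve, "truth") <- list(kd = config$kd_true,
                               amplitude = config$amplitude_true)
  curve
}

.parse_structure <- function(structure_string) {
  if (is.logical(structure_string)) return(structure_string)
  chars <- strsplit(structure_string, "")[[1L]]
  ok_unpaired <- chars %in% c(".", "u")
  ok_paired <- chars %in% c("(", ")", "p")
  if (!all(ok_unpaired | ok_paired))
    stop("structure string must use '.'/'u' (unpaired) and '('/')'/'p' (paired)")
  ok_paired
}

#' Simulate SHAPE-MaP mutation counts for a known structure
#'
#' Modified-channel counts are Binomial(depth, rate) with the rate chosen
#' by pairing state; the untreated channel uses a single background rate.
#'
#' @param structure_string Dot-bracket string (or string over `u`/`p`, or a
#'   logical vector with `TRUE` = paired) giving the pairing state per
#'   position.
#' @param config A [sim_config()].
#' @param depths Per-position read depth (recycled); defaults to
#'   `config$shape_depth`.
#' @return Data frame with columns `position` (1-based), `paired`,
#'   `mod_count`, `mod_depth`, `unt_count`, `unt_depth`.
#' @export
simulate_mutation_counts <- function(structure_string, config, depths = NULL) {
  .sim_seed(config, "shape")
  paired <- .parse_structure(structure_string)
  n <- length(paired)
  depth <- as.integer(rep_len(if (is.null(depths)) config$shape_depth else depths, n))
  rate <- ifelse(paired, config$mod_rate_paired, config$mod_rate_unpaired)
  data.frame(
    position  = seq_len(n),
    paired    = paired,
    mod_count = stats::rbinom(n, depth, rate),
    mod_depth = depth,
    unt_count = stats::rbinom(n, depth, config$untreated_rate),
    unt_depth = depth
  )
}

#' Simulate a crosslink-search result table with known per-residue truth
#'
#' Rows carry the quality columns the post-search filters act on (`minions`,
#' `tic`, `id_score`) plus redundant spectral counts (`nseen`), a subunit,
#' a residue position and a decoy flag. Quality scores are drawn so that a
#' predictable subset falls below the default thresholds; the ground truth
#' records which rows pass and the per-residue `nseen` totals among passing
#' target rows.
#'
#' @param config A [sim_config()].
#' @return Data frame with attribute `truth` (logical `passes` per row and
#'   the per-residue aggregation of passing, non-decoy rows).
#' @export
simulate_xlms_table <- function(config) {
  .sim_seed(config, "xlms")
  n <- config$xl_n_rows
  subunit <- sample(names(config$xl_subunits), n, replace = TRUE)
  residue <- vapply(subunit, function(s)
    sample.int(config$xl_subunits[[s]], 1L), 1L)
  tab <- data.frame(
    subunit  = subunit,
    residue  = residue,
    nseen    = 1L + stats::rpois(n, 2),
    minions  = sample(3:25, n, replace = TRUE),
    tic      = round(stats::runif(n, 0, 0.6), 4),
    id_score = round(stats::runif(n, 5, 45), 2),
    decoy    = stats::runif(n) < config$xl_decoy_rate,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  passes <- tab$minions >= 7 & tab$tic >= 0.15 & tab$id_score >= 20
  keep <- passes & !tab$decoy
  agg <- stats::aggregate(nseen ~ subunit + residue, data = tab[keep, ],
                          FUN = sum)
  agg <- agg[order(agg$subunit, agg$residue), ]
  rownames(agg) <- NULL
  attr(tab, "truth") <- list(passes = passes, per_residue = agg)
  tab
}
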