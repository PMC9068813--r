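# Core data model: genomic intervals, strand-specific coverage tracks, and
# readers/writers for the flat-file formats (BED6, bedGraph, chrom.sizes,
# site tables) shared by every analysis stage.
#
# Conventions: all internal coordinates are 0-based half-open, matching
# BED/bedGraph. 1-based labels (e.g. the distance window "1-200") appear only
# in report columns, never in stored coordinates.

STRANDS <- c("+", "-")

#' Read a BED file into a GRanges object
#'
#' Reads BED3/BED6 records into a `GRanges`, preserving name, score and
#' strand when present. BED is 0-based half-open; `GRanges` is 1-based
#' closed, so `start` is shifted by one on import (and back on export by
#' [write_bed()]), the single conversion point in the package.
#'
#' @param path Path to a tab-separated BED file with at least 3 columns.
#' @return A `GRanges` with optional metadata columns `name` and `score`.
#'   Records without a strand field get strand `*`.
#' @seealso [write_bed()], [read_site_table()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1L], ": fewer than 3 fields")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed BED line ", bad[1L], ": non-numeric coordinates")
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad) > 0L) {
    stop("invalid interval on BED line ", bad[1L],
         ": need 0 <= start < end, got [", start[bad[1L]], ", ",
         end[bad[1L]], ")")
  }
  name   <- ifelse(nf >= 4L, vapply(fields, function(f) f[4L], ""), NA_character_)
  score  <- ifelse(nf >= 5L,
                   suppressWarnings(as.numeric(vapply(fields, function(f) f[min(5L, length(f))], ""))),
                   NA_real_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% STRANDS] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges   = IRanges::IRanges(start = start + 1L, end = end),
    strand   = strand
  )
  if (any(nf >= 4L)) S4Vectors::mcols(gr)$name <- name
  if (any(nf >= 5L)) S4Vectors::mcols(gr)$score <- score
  gr
}

#' Write a GRanges object to a BED6 file
#'
#' @param gr A `GRanges`; metadata columns `name` and `score` are used when
#'   present, otherwise `.` and `0` are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else rep(".", length(gr))
  name[is.na(name)] <- "."
  score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  score[is.na(score)] <- 0
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- paste(
    as.character(GenomicRanges::seqnames(gr)),
    GenomicRanges::start(gr) - 1L,
    GenomicRanges::end(gr),
    name,
    format(score, trim = TRUE, scientific = FALSE),
    strand,
    sep = "\t"
  )
  writeLines(out, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with columns chromosome name and length (bp).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  if (any(tab$length <= 0L)) stop("non-positive chromosome length in ", path)
  stats::setNames(tab$length, tab$chrom)
}

#' Construct an empty strand-specific coverage track
#'
#' A coverage track stores one run-length-encoded vector of non-negative
#' counts per (chromosome, strand), at single-base resolution. It carries
#' GRO-seq/Exo-seq/ChIP-style signal through the pipeline.
#'
#' @param chrom_sizes Named integer vector of chromosome lengths (bp).
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  empty <- lapply(chrom_sizes, function(n) S4Vectors::Rle(0, n))
  structure(
    list(plus = empty, minus = empty, chrom_sizes = chrom_sizes),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$chrom_sizes), "chromosome(s)\n")
  for (chrom in names(x$chrom_sizes)) {
    cat(sprintf("  %s (%d bp): +%g / -%g total signal\n", chrom,
                x$chrom_sizes[[chrom]],
                sum(x$plus[[chrom]]), sum(x$minus[[chrom]])))
  }
  invisible(x)
}

#' Total signal in a coverage track
#'
#' @param track A `coverage_track`.
#' @return Sum of counts over all chromosomes and both strands.
#' @export
track_total <- function(track) {
  sum(vapply(track$plus, sum, 0)) + sum(vapply(track$minus, sum, 0))
}

.strand_slot <- function(strand) {
  switch(as.character(strand), "+" = "plus", "-" = "minus",
         stop("strand must be '+' or '-', got '", strand, "'"))
}

parse_bedgraph <- function(path, chrom_sizes) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric()))
  }
  # tolerant read: space- or tab-separated accepted
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("malformed bedGraph line ", which(nf < 4L)[1L], " in ", path)
  }
  df <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(vapply(fields, `[`, "", 2L)),
    end   = as.integer(vapply(fields, `[`, "", 3L)),
    value = as.numeric(vapply(fields, `[`, "", 4L))
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
    stop("non-numeric field in bedGraph ", path)
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown) > 0L)
    stop("unknown chromosome in ", path, ": ", paste(unknown, collapse = ", "))
  if (any(df$value < 0)) stop("negative coverage value in ", path)
  if (any(df$start < 0L) || any(df$end > chrom_sizes[df$chrom]))
    stop("interval outside chromosome bounds in ", path)
  if (any(df$start >= df$end)) stop("inverted interval in ", path)
  df
}

.bedgraph_to_rle <- function(df, chrom_sizes) {
  out <- lapply(names(chrom_sizes), function(chrom) {
    sub <- df[df$chrom == chrom, , drop = FALSE]
    if (nrow(sub) == 0L) return(S4Vectors::Rle(0, chrom_sizes[[chrom]]))
    # per-base expansion; overlapping lines sum
    cov <- IRanges::coverage(
      IRanges::IRanges(start = sub$start + 1L, end = sub$end),
      weight = sub$value, width = chrom_sizes[[chrom]]
    )
    cov
  })
  stats::setNames(out, names(chrom_sizes))
}

#' Read a strand-separated bedGraph pair into a coverage track
#'
#' Each bedGraph interval value is expanded to every base it covers;
#' overlapping lines are summed. 4-column bedGraph, space- or tab-separated,
#' is accepted on read; [write_bedgraph_pair()] writes tab-separated.
#'
#' @param path_plus,path_minus Paths to the plus- and minus-strand bedGraph
#'   files (the convention for 5'-end and nascent coverage computed per
#'   strand separately).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
read_bedgraph_pair <- function(path_plus, path_minus, chrom_sizes) {
  track <- coverage_track(chrom_sizes)
  track$plus  <- .bedgraph_to_rle(parse_bedgraph(path_plus, chrom_sizes), chrom_sizes)
  track$minus <- .bedgraph_to_rle(parse_bedgraph(path_minus, chrom_sizes), chrom_sizes)
  track
}

.rle_to_bedgraph <- function(rle_list, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(rle_list)) {
    r <- rle_list[[chrom]]
    vals <- S4Vectors::runValue(r)
    lens <- S4Vectors::runLength(r)
    ends <- cumsum(lens)
    starts <- ends - lens           # 0-based
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(paste(chrom, starts[keep], ends[keep],
                     format(vals[keep], trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a coverage track as a strand-separated bedGraph pair
#'
#' Zero-coverage runs are omitted. Round-trip through
#' [read_bedgraph_pair()] conserves total signal exactly.
#'
#' @param track A `coverage_track`.
#' @param path_plus,path_minus Output paths.
#' @return The two paths, invisibly.
#' @export
write_bedgraph_pair <- function(track, path_plus, path_minus) {
  .rle_to_bedgraph(track$plus, path_plus)
  .rle_to_bedgraph(track$minus, path_minus)
  invisible(c(path_plus, path_minus))
}

#' Read density (reads per bp) of a coverage track over an interval
#'
#' Sums counts on the interval's strand within its 0-based half-open span
#' and divides by the interval length. Unstranded intervals sum both
#' strands.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @param strand `"+"`, `"-"`, or `"*"` (both strands).
#' @return Reads per bp (double).
#' @export
window_density <- function(track, chrom, start, end, strand = "+") {
  if (end <= start) stop("zero- or negative-length window [", start, ", ", end, ")")
  if (!chrom %in% names(track$chrom_sizes)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > track$chrom_sizes[[chrom]])
    stop("window outside chromosome bounds")
  idx <- (start + 1L):end
  total <- if (strand == "*") {
    sum(track$plus[[chrom]][idx]) + sum(track$minus[[chrom]][idx])
  } else {
    sum(track[[.strand_slot(strand)]][[chrom]][idx])
  }
  total / (end - start)
}

#' Add counts to a coverage track at single positions
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name (scalar).
#' @param positions 0-based positions; may repeat.
#' @param strand `"+"` or `"-"` (scalar).
#' @param counts Count to add at each position (recycled).
#' @return The updated `coverage_track`.
#' @export
add_sites <- function(track, chrom, positions, strand, counts = 1) {
  if (length(positions) == 0L) return(track)
  if (!chrom %in% names(track$chrom_sizes)) stop("unknown chromosome: ", chrom)
  if (any(positions < 0L) || any(positions >= track$chrom_sizes[[chrom]]))
    stop("position outside chromosome bounds")
  counts <- rep_len(counts, length(positions))
  slot <- .strand_slot(strand)
  add <- IRanges::coverage(
    IRanges::IRanges(start = positions + 1L, width = 1L),
    weight = counts, width = track$chrom_sizes[[chrom]]
  )
  track[[slot]][[chrom]] <- track[[slot]][[chrom]] + add
  track
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper over \pkg{Biostrings} returning plain named character
#' strings (RNA alphabet: T is converted to U), the form the sequence
#' statistics consume.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @param as_rna Convert T to U (default `TRUE`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, as_rna = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(toupper(as.character(set)), names(set))
  if (as_rna) seqs <- chartr("T", "U", seqs)
  seqs
}

#' Multiply a coverage track by a scale factor
#'
#' All analyses in the package operate on raw counts; where a normalised
#' display scale is wanted (e.g. reads per genomic content), apply it here.
#' Density ratios such as the pausing index are invariant under this
#' rescaling.
#'
#' @param track A `coverage_track`.
#' @param factor Positive multiplier.
#' @return The rescaled `coverage_track`.
#' @export
scale_track <- function(track, factor) {
  if (factor <= 0) stop("scale factor must be positive")
  for (chrom in names(track$chrom_sizes)) {
    track$plus[[chrom]] <- track$plus[[chrom]] * factor
    track$minus[[chrom]] <- track$minus[[chrom]] * factor
  }
  track
}

#' Read a site table (BED6 with score = count) into a data frame
#'
#' Site tables carry single-base records such as eCLIP crosslink sites or
#' Exo-seq 5'-end counts: one row per position with a positive count.
#'
#' @param path Path to a BED6 file whose intervals are 1 bp wide and whose
#'   score column holds the per-position read count.
#' @return A data frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `count`.
#' @export
read_site_table <- function(path) {
  gr <- read_bed(path)
  if (length(gr) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), count = numeric()))
  }
  if (any(GenomicRanges::width(gr) != 1L))
    stop("site table records must be single-base intervals")
  count <- S4Vectors::mcols(gr)$score
  if (is.null(count)) stop("site table needs a score column holding counts")
  if (any(count < 1)) stop("site counts must be >= 1")
  data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    pos    = GenomicRanges::start(gr) - 1L,
    strand = as.character(GenomicRanges::strand(gr)),
    count  = count
  )
}

#' Write a site table as BED6 with score = count
#'
#' @param sites Data frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges   = IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand   = sites$strand
  )
  S4Vectors::mcols(gr)$name <- "."
  S4Vectors::mcols(gr)$score <- sites$count
  write_bed(gr, path)
}
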