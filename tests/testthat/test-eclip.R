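# eCLIP crosslink sites: extraction, unit assignment, window distributions,
# normalised profiles, chi-squared comparison.

test_that("extract_crosslink_sites tallies reads per position", {
  reads <- data.frame(chrom = "chr1", pos = c(1000L, 1000L, 1005L),
                      strand = "+")
  sites <- extract_crosslink_sites(reads)
  expect_equal(sites$pos, c(1000L, 1005L))
  expect_equal(sites$count, c(2, 1))
  dedup <- extract_crosslink_sites(reads, dedup = TRUE)
  expect_equal(dedup$count, c(1, 1))
})

test_that("per-position totals equal a brute-force tally on 10^4 reads", {
  set.seed(88)
  reads <- data.frame(chrom = "chr1",
                      pos = sample.int(3000L, 10000L, replace = TRUE),
                      strand = sample(c("+", "-"), 10000L, replace = TRUE))
  sites <- extract_crosslink_sites(reads)
  for (i in sample.int(nrow(sites), 25L)) {
    expect_equal(sites$count[i],
                 sum(reads$pos == sites$pos[i] &
                       reads$strand == sites$strand[i]))
  }
  expect_equal(sum(sites$count), nrow(reads))
})

test_that("assign_to_units uses 1-based distances from the 5' end", {
  units <- make_units(c(1000, 5000), 600, c("+", "-"))
  sites <- data.frame(chrom = "chr1",
                      pos = c(1000L, 1149L, 5599L, 5450L),
                      strand = c("+", "+", "-", "-"),
                      count = c(1, 1, 1, 1))
  asn <- assign_to_units(sites, units)
  expect_equal(asn$distance[asn$pos == 1000L], 1L)     # at the 5' end
  expect_equal(asn$distance[asn$pos == 1149L], 150L)   # 149 nt downstream
  expect_equal(asn$distance[asn$pos == 5599L], 1L)     # minus-strand 5' end
  expect_equal(asn$distance[asn$pos == 5450L], 150L)
})

test_that("assignment matches a brute-force interval scan", {
  set.seed(15)
  units <- make_units(sort(sample.int(800000L, 50L)) ,
                      sample(300:2000, 50L, replace = TRUE),
                      sample(c("+", "-"), 50L, replace = TRUE))
  sites <- data.frame(chrom = "chr1",
                      pos = sample.int(850000L, 1000L),
                      strand = sample(c("+", "-"), 1000L, replace = TRUE),
                      count = sample(1:5, 1000L, replace = TRUE))
  asn <- assign_to_units(sites, units)
  manual <- list()
  for (i in seq_len(nrow(sites))) {
    for (j in seq_len(nrow(units))) {
      if (sites$strand[i] == units$strand[j] &&
          sites$pos[i] >= units$start[j] && sites$pos[i] < units$end[j]) {
        d <- if (units$strand[j] == "+") sites$pos[i] - units$start[j] + 1L
             else units$end[j] - sites$pos[i]
        manual[[length(manual) + 1L]] <-
          data.frame(pos = sites$pos[i], unit = units$id[j], distance = d)
      }
    }
  }
  manual <- do.call(rbind, manual)
  key <- function(d) sort(paste(d$pos, d$unit, d$distance))
  expect_equal(key(asn), key(manual))
  hit <- vapply(seq_len(nrow(sites)), function(i)
    any(sites$strand[i] == units$strand & sites$pos[i] >= units$start &
          sites$pos[i] < units$end), NA)
  expect_equal(attr(asn, "n_unassigned"), sum(sites$count[!hit]))
})

test_that("window_distribution bins 1-based distances into (prev, edge]", {
  asn <- data.frame(distance = c(50L, 150L, 250L), count = 1)
  wd <- window_distribution(asn, edges = c(200L, 400L, 600L))
  expect_equal(wd$window, c("1-200", "201-400", "401-600"))
  expect_equal(wd$proportion, c(2 / 3, 1 / 3, 0))
  # boundary: 200 belongs to the first window, 201 to the second
  edge <- window_distribution(data.frame(distance = c(200L, 201L), count = 1),
                              edges = c(200L, 400L))
  expect_equal(edge$count, c(1, 1))
  # beyond-last-edge distances are dropped with a count
  far <- window_distribution(data.frame(distance = 999L, count = 3),
                             edges = c(200L, 400L))
  expect_equal(attr(far, "n_beyond"), 3)
  expect_true(attr(far, "empty"))
  expect_true(all(is.na(far$proportion)))
})

test_that("proportions sum to 1 over retained sites for random inputs", {
  set.seed(2)
  for (rep in 1:20) {
    asn <- data.frame(distance = sample.int(2500L, 200L, replace = TRUE),
                      count = sample(1:4, 200L, replace = TRUE))
    wd <- window_distribution(asn)
    if (!attr(wd, "empty")) expect_equal(sum(wd$proportion), 1)
    expect_equal(sum(wd$count) + attr(wd, "n_beyond"), sum(asn$count))
  }
})

test_that("full pipeline recovers the generating 5'-mixture fraction", {
  units <- make_units(seq(10000L, 910000L, by = 100000L), 1000L,
                      c("+", "-"))
  cfg <- sim_config(seed = 23, crosslink_5prime_fraction = 0.7,
                    n_crosslinks = 10000L)
  sites <- simulate_crosslink_sites(cfg, units)
  asn <- assign_to_units(sites, units)
  wd <- window_distribution(asn, edges = c(200L, 400L, 600L, 800L, 1000L))
  ci <- binom_ci99(0.7, sum(wd$count))
  expect_gt(wd$proportion[1L], ci[1L])
  expect_lt(wd$proportion[1L], ci[2L])
})

test_that("normalized_profile divides by per-unit expression density", {
  units <- make_units(c(1000, 10000), 600, "+")
  asn <- data.frame(chrom = "chr1", pos = c(1009L, 10009L), strand = "+",
                    count = c(6, 6), unit = c("u01", "u02"),
                    distance = c(10L, 10L), multi_unit = FALSE)
  # equal expression: both units contribute equally
  prof_eq <- normalized_profile(asn, units,
                                c(u01 = 2, u02 = 2), span = 100L,
                                binsize = 10L)
  # doubling one unit's expression halves its contribution
  prof_2x <- normalized_profile(asn, units,
                                c(u01 = 2, u02 = 4), span = 100L,
                                binsize = 10L)
  expect_equal(prof_eq$normalized_coverage[1L], mean(c(6 / 2, 6 / 2)) / 10)
  expect_equal(prof_2x$normalized_coverage[1L], mean(c(6 / 2, 6 / 4)) / 10)
  # zero-expression units are excluded with a count
  prof_z <- normalized_profile(asn, units, c(u01 = 2, u02 = 0),
                               span = 100L, binsize = 10L)
  expect_equal(attr(prof_z, "n_excluded_zero_expression"), 1L)
  expect_equal(attr(prof_z, "n_units_used"), 1L)
})

test_that("normalized_profile equals brute-force per-unit averaging", {
  set.seed(19)
  n_units <- 20L
  units <- make_units(seq(1000L, by = 5000L, length.out = n_units), 700L, "+")
  expr <- stats::setNames(stats::runif(n_units, 0.5, 4), units$id)
  rows <- list()
  for (i in seq_len(n_units)) {
    k <- sample(3:10, 1L)
    d <- sample.int(600L, k)
    rows[[i]] <- data.frame(chrom = "chr1", pos = units$start[i] + d - 1L,
                            strand = "+", count = sample(1:5, k, replace = TRUE),
                            unit = units$id[i], distance = d,
                            multi_unit = FALSE)
  }
  asn <- do.call(rbind, rows)
  prof <- normalized_profile(asn, units, expr, span = 600L, binsize = 1L)
  manual <- matrix(0, nrow = n_units, ncol = 600L)
  for (i in seq_len(n_units)) {
    sub <- asn[asn$unit == units$id[i], ]
    manual[i, sub$distance] <- sub$count / expr[[units$id[i]]]
  }
  expect_equal(prof$normalized_coverage, colMeans(manual))
})

test_that("chi-squared comparison is Pearson without continuity correction", {
  # identical vectors: statistic 0, p 1
  same <- compare_window_distributions(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # hand-computed 2x2: [[10,0],[0,10]] -> 20
  res <- compare_window_distributions(c(10, 0), c(0, 10))
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  # random tables vs the textbook formula, and symmetry
  set.seed(4)
  for (rep in 1:20) {
    a <- sample(5:60, 3L)
    b <- sample(5:60, 3L)
    res <- compare_window_distributions(a, b)
    expect_equal(res$statistic, oracle_pearson(rbind(a, b)), tolerance = 1e-12)
    expect_equal(res$statistic,
                 compare_window_distributions(b, a)$statistic)
    expect_equal(res$df, 2L)
  }
})
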