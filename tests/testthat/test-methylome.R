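test_that("cytosine reports parse with Bismark conventions", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t6\t+\t7\t3\tCG\tCGA",
               "chr1\t7\t-\t5\t5\tCG\tCGT",
               "chr1\t20\t+\t1\t9\tCHH\tCTT"), f)
  x <- parse_cytosine_report(f, merge_strands = FALSE)
  expect_equal(nrow(x), 2)  # CHH excluded
  expect_equal(x$pos, c(5, 6))
  expect_equal(x$n_reads, c(10, 10))
  expect_equal(x$n_unconverted, c(7, 5))
  merged <- parse_cytosine_report(f, merge_strands = TRUE)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$pos, 5)
  expect_equal(merged$n_reads, 20)
  expect_equal(merged$n_unconverted, 12)
  expect_equal(parse_cytosine_report(f, chemistry = "BS")$chemistry, "BS")
})

test_that("malformed cytosine reports fail with a line number", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t6\t+\t7\t3\tCG\tCGA",
               "chr1\t9\t+\t-2\t3\tCG\tCGA"), f)
  expect_error(parse_cytosine_report(f), "line 2")
  writeLines(c("chr1\t6\t+\t7\t3\tZZ\tCGA"), f)
  expect_error(parse_cytosine_report(f), "unknown context")
})

test_that("cytosine reports round-trip through the writer", {
  sim <- shared_sim()
  bs <- simulate_bisulfite(sim, region = interval_tbl("chr1", 0, 20000),
                           chemistries = "BS", seed = 61)$counts$BS
  f <- withr::local_tempfile(fileext = ".txt")
  write_cytosine_report(bs, f)
  back <- parse_cytosine_report(f, chemistry = "BS", merge_strands = FALSE)
  expect_equal(back$pos, bs$pos)
  expect_equal(back$n_reads, bs$n_reads)
  expect_equal(back$n_unconverted, bs$n_unconverted)
})

test_that("BS/oxBS subtraction and clamping follow their definitions", {
  bs <- tibble::tibble(chrom = "amp", pos = c(10, 20),
                       n_reads = c(100, 100), n_unconverted = c(80, 20))
  ox <- tibble::tibble(chrom = "amp", pos = c(10, 20),
                       n_reads = c(100, 100), n_unconverted = c(60, 25))
  est <- estimate_from_bs_oxbs(bs, ox)
  expect_equal(est$level_5mC, c(0.60, 0.25))
  expect_equal(est$level_5hmC, c(0.20, 0.00))
  expect_equal(est$level_5hmC_raw, c(0.20, -0.05))
  expect_equal(est$level_modified, c(0.80, 0.20))
  expect_true(all(est$ci_5mC_low <= est$level_5mC &
                    est$level_5mC <= est$ci_5mC_high))
  # zero-coverage sites yield no estimate
  bs0 <- tibble::tibble(chrom = "amp", pos = 30, n_reads = 0, n_unconverted = 0)
  ox0 <- tibble::tibble(chrom = "amp", pos = 30, n_reads = 50, n_unconverted = 10)
  expect_equal(nrow(estimate_from_bs_oxbs(bs0, ox0)), 0)
})

test_that("TAB estimates read 5hmC directly, optionally with paired BS", {
  tab <- tibble::tibble(chrom = "amp", pos = c(10, 20),
                        n_reads = c(100, 100), n_unconverted = c(20, 0))
  est <- estimate_from_tab(tab)
  expect_equal(est$level_5hmC, c(0.2, 0))
  bs <- tibble::tibble(chrom = "amp", pos = 10, n_reads = 100,
                       n_unconverted = 80)
  est2 <- estimate_from_tab(tab, bs = bs)
  expect_equal(est2$level_5mC, 0.6)
  expect_equal(est2$level_modified, 0.8)
})

test_that("estimation is asymptotically unbiased under ideal chemistry", {
  truth <- tibble::tibble(chrom = "amp", pos = seq(0, 2 * 299, 2),
                          p_5mC = 0.6, p_5hmC = 0.2)
  ideal <- list(conversion = 1, fail = c(BS = 0, oxBS = 0, TAB = 0))
  bias <- vapply(c(100, 1000, 10000), function(d) {
    cc <- simulate_cpg_counts(truth, ideal, mean_depth = d, seed = d + 1)
    est <- estimate_from_bs_oxbs(cc$BS, cc$oxBS)
    c(abs(mean(est$level_5mC) - 0.6), abs(mean(est$level_5hmC) - 0.2))
  }, numeric(2))
  # mean absolute bias shrinks roughly like 1/sqrt(depth)
  expect_lt(bias[1, 3], 0.005)
  expect_lt(bias[2, 3], 0.005)
  expect_lt(bias[1, 3], bias[1, 1] + 0.005)
})

test_that("conversion-error correction removes leaky-chemistry bias", {
  leaky <- list(conversion = 0.95, fail = c(BS = 0.03, oxBS = 0.03, TAB = 0.05))
  truth <- tibble::tibble(chrom = "amp", pos = seq(0, 2 * 299, 2),
                          p_5mC = 0.6, p_5hmC = 0.2)
  cc <- simulate_cpg_counts(truth, leaky, mean_depth = 2000, seed = 68)
  est <- estimate_from_bs_oxbs(cc$BS, cc$oxBS, chemistry = leaky)
  # the naive subtraction is visibly biased by the leaky chemistry...
  expect_gt(abs(mean(est$level_5hmC) - 0.2), 0.01)
  # ...and the inverted-chemistry estimates are not
  expect_lt(abs(mean(est$level_5mC_corrected) - 0.6), 0.01)
  expect_lt(abs(mean(est$level_5hmC_corrected) - 0.2), 0.01)
  expect_true(all(est$level_5hmC_corrected >= 0))
  # with ideal chemistry the correction is the identity
  ideal <- list(conversion = 1, fail = c(BS = 0, oxBS = 0, TAB = 0))
  cc2 <- simulate_cpg_counts(truth, ideal, mean_depth = 500, seed = 69)
  est2 <- estimate_from_bs_oxbs(cc2$BS, cc2$oxBS, chemistry = ideal)
  expect_equal(est2$level_5mC_corrected, est2$level_5mC)
})

test_that("coverage filtering is joint, boundary-inclusive and idempotent", {
  counts <- dplyr::bind_rows(
    tibble::tibble(chrom = "amp", pos = 1, n_reads = 99, n_unconverted = 1,
                   chemistry = "BS"),
    tibble::tibble(chrom = "amp", pos = 1, n_reads = 150, n_unconverted = 1,
                   chemistry = "oxBS"),
    tibble::tibble(chrom = "amp", pos = 2, n_reads = 100, n_unconverted = 1,
                   chemistry = "BS"),
    tibble::tibble(chrom = "amp", pos = 2, n_reads = 100, n_unconverted = 1,
                   chemistry = "oxBS")
  )
  kept <- filter_min_coverage(counts, min_reads = 100)
  expect_equal(unique(kept$pos), 2)  # joint rule drops the 99x site
  expect_equal(filter_min_coverage(kept, 100), kept)  # idempotent
  per <- filter_min_coverage(counts, 100, joint = FALSE)
  expect_equal(nrow(per), 3)
})

test_that("surviving sites equal a brute-force recount at threshold 100", {
  set.seed(62)
  for (rep in 1:25) {
    n <- 150
    counts <- dplyr::bind_rows(lapply(c("BS", "oxBS"), function(ch) {
      tibble::tibble(chrom = "amp", pos = seq_len(n) * 2,
                     n_reads = rpois(n, 120), n_unconverted = 0,
                     chemistry = ch)
    }))
    kept <- filter_min_coverage(counts, 100)
    manual <- vapply(seq_len(n) * 2, function(p) {
      all(counts$n_reads[counts$pos == p] >= 100)
    }, logical(1))
    expect_setequal(unique(kept$pos), (seq_len(n) * 2)[manual])
  }
})

test_that("replicate averaging is an unweighted mean over present replicates", {
  reps <- list(
    tibble::tibble(chrom = "amp", pos = c(1, 2), level_5mC = c(0.1, 0.4)),
    tibble::tibble(chrom = "amp", pos = c(1, 2), level_5mC = c(0.2, 0.6)),
    tibble::tibble(chrom = "amp", pos = 1, level_5mC = 0.3)
  )
  avg <- replicate_average(reps)
  expect_equal(avg$level_5mC[avg$pos == 1], 0.2)
  expect_equal(avg$level_5mC[avg$pos == 2], 0.5)
  expect_equal(avg$n_replicates, c(3L, 2L))
  one <- replicate_average(reps[1])
  expect_equal(one$level_5mC, reps[[1]]$level_5mC)
})

test_that("region aggregation is coverage-weighted with NA empty regions", {
  sites <- tibble::tibble(chrom = "chr1", pos = c(150, 180, 900),
                          level_5mC = c(0.5, 0.7, 0.9),
                          n_reads = c(100, 300, 50))
  regions <- interval_tbl("chr1", c(100, 500), c(200, 600))
  agg <- aggregate_by_region(sites, regions)
  expect_equal(agg$level_5mC, c(0.65, NA))
  expect_equal(agg$n_cpgs, c(2L, 0L))
  # random instances vs the loop oracle
  set.seed(63)
  for (rep in 1:20) {
    s <- tibble::tibble(chrom = "chr1", pos = sample(0:999, 60),
                        level_5mC = runif(60), n_reads = rpois(60, 50) + 1)
    r <- rand_intervals(8, max_pos = 1000, max_len = 200)
    got <- aggregate_by_region(s, r)
    expect_equal(got$level_5mC, bf_aggregate(s, r, "level_5mC", "n_reads"))
  }
})

test_that("the exact rank-sum test matches enumeration and known cases", {
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$method, "wilcoxon_exact")
  expect_equal(out$p_value, 0.1)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
  set.seed(64)
  for (rep in 1:60) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(1:6, na + nb, replace = TRUE)  # ties likely
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(compare_groups(a, b)$p_value, bf_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with wilcox.test; large n uses the normal", {
  set.seed(65)
  for (rep in 1:20) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(compare_groups(a, b)$p_value,
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
  }
  a <- rnorm(50); b <- rnorm(60) + 0.3
  got <- compare_groups(a, b)
  expect_equal(got$method, "wilcoxon_normal")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_equal(got$p_value, ref, tolerance = 1e-9)
})

test_that("the rank-sum normal approximation has near-nominal power", {
  set.seed(66)
  n <- 100
  rej <- mean(vapply(1:200, function(i) {
    compare_groups(rnorm(n), rnorm(n) + 1)$p_value < 0.05
  }, logical(1)))
  # power for a 1-SD shift at n = 100 is essentially 1
  expect_gt(rej, 0.99)
  rej0 <- mean(vapply(1:200, function(i) {
    compare_groups(rnorm(n), rnorm(n))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej0 - 0.05), 0.05)
})

test_that("welch t mode delegates to the standard test", {
  a <- c(1, 2, 3); b <- c(2, 3, 7)
  got <- compare_groups(a, b, test = "t")
  ref <- t.test(a, b)
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value)
})

test_that("estimated levels always satisfy the ordering invariant", {
  set.seed(67)
  n <- 5000
  bs <- tibble::tibble(chrom = "x", pos = seq_len(n),
                       n_reads = rpois(n, 50) + 1)
  bs$n_unconverted <- rbinom(n, bs$n_reads, runif(n))
  ox <- tibble::tibble(chrom = "x", pos = seq_len(n),
                       n_reads = rpois(n, 50) + 1)
  ox$n_unconverted <- rbinom(n, ox$n_reads, runif(n))
  est <- estimate_from_bs_oxbs(bs, ox)
  expect_true(all(est$level_5hmC >= 0))
  expect_true(all(est$level_5hmC <= est$level_modified + 1e-9))
  expect_true(all(est$level_5mC >= 0 & est$level_5mC <= 1))
  expect_true(all(est$level_modified <= 1))
})
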