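#' Bisulfite-family chemistry
#'
#' Three conversion chemistries read out cytosine modification states:
#' plain bisulfite (BS; unconverted C signal = 5mC + 5hmC), oxidative
#' bisulfite (oxBS; KRuO4 first oxidises 5hmC so the unconverted signal
#' is 5mC only) and TET-assisted bisulfite (TAB; unconverted signal is
#' 5hmC only).  5hmC is obtained by subtracting oxBS from BS at matched
#' CpGs, or read directly from TAB.
#'
#' @name methylome
NULL

#' Parse a Bismark-style cytosine report
#'
#' Expects the seven-column dialect `chrom, pos (1-based), strand,
#' count_methylated, count_unmethylated, context, trinucleotide`.  Only
#' CG-context rows are retained; positions become 0-based.  With
#' `merge_strands = TRUE` the two strands of a CpG dyad (plus strand at
#' `p`, minus strand at `p + 1`) are summed and reported at the
#' plus-strand position — the default for genome-wide data; amplicon
#' data sequenced from a designed strand should keep strands separate.
#'
#' @param path path to the report.
#' @param chemistry optional label (`"BS"`, `"oxBS"`, `"TAB"`) stored in
#'   a `chemistry` column.
#' @param merge_strands sum CpG-dyad counts across strands (default
#'   `TRUE`).
#' @return Tibble (`chrom`, `pos`, `strand`, `n_reads`, `n_unconverted`
#'   and optionally `chemistry`), one row per retained CpG.
#' @export
parse_cytosine_report <- function(path, chemistry = NULL,
                                  merge_strands = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    out <- tibble(chrom = character(), pos = numeric(), strand = character(),
                  n_reads = numeric(), n_unconverted = numeric())
    if (!is.null(chemistry)) out$chemistry <- character()
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6)) {
    abort(sprintf("malformed cytosine report at line %d of %s",
                  which(nf < 6)[1], path))
  }
  m <- matrix(unlist(lapply(f, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 4]))
  unmeth <- suppressWarnings(as.numeric(m[, 5]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth) | meth < 0 | unmeth < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative or non-numeric counts at line %d of %s", bad[1], path))
  }
  ok_ctx <- m[, 6] %in% c("CG", "CHG", "CHH", "CN", "Unknown")
  if (!all(ok_ctx)) {
    abort(sprintf("unknown context token '%s' at line %d of %s",
                  m[which(!ok_ctx)[1], 6], which(!ok_ctx)[1], path))
  }
  keep <- m[, 6] == "CG"
  out <- tibble(chrom = m[keep, 1], pos = pos[keep] - 1,
                strand = m[keep, 3],
                n_reads = meth[keep] + unmeth[keep],
                n_unconverted = meth[keep])
  if (merge_strands) out <- merge_cpg_dyads(out)
  if (!is.null(chemistry)) out$chemistry <- chemistry
  out
}

# minus-strand call at p belongs to the dyad whose plus-strand C is p - 1
merge_cpg_dyads <- function(x) {
  dyad_pos <- ifelse(x$strand == "-", x$pos - 1, x$pos)
  out <- summarise(group_by(tibble(chrom = x$chrom, pos = dyad_pos,
                                   n_reads = x$n_reads,
                                   n_unconverted = x$n_unconverted),
                            .data$chrom, .data$pos),
                   n_reads = sum(.data$n_reads),
                   n_unconverted = sum(.data$n_unconverted),
                   .groups = "drop")
  mutate(arrange(out, .data$chrom, .data$pos), strand = "+", .after = "pos")
}

#' Write CpG counts as a Bismark-style cytosine report
#'
#' @param counts tibble from [parse_cytosine_report()] or
#'   [simulate_bisulfite()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(counts, path) {
  strand <- if ("strand" %in% names(counts)) counts$strand else "+"
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\tCG\tCGN",
                  counts$chrom, as.integer(counts$pos) + 1L, strand,
                  as.integer(counts$n_unconverted),
                  as.integer(counts$n_reads - counts$n_unconverted))
  writeLines(recs, path)
  invisible(path)
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Estimate 5mC and 5hmC from paired BS and oxBS counts
#'
#' At each CpG present in both chemistries: total modification
#' (5mC + 5hmC) is the BS unconverted fraction, 5mC is the oxBS
#' unconverted fraction, and 5hmC their difference, clamped at zero
#' (sampling noise can make the raw subtraction negative; the unclamped
#' value is kept in `level_5hmC_raw` as a diagnostic).  Wilson score
#' intervals are attached to the directly measured levels and a
#' normal-approximation interval to the 5hmC difference.
#'
#' Optionally, a `chemistry` list (see [default_chemistry()]) inverts the
#' conversion chemistry: with conversion rate `c` and protection-failure
#' rate `f`, an observed unconverted fraction `p` estimates a true
#' protected fraction `(p - (1 - c)) / ((1 - f) - (1 - c))`, clamped to
#' `[0, 1]`.  The corrected levels are added as `*_corrected` columns;
#' the naive proportions (standard practice) remain the primary output.
#'
#' @param bs,oxbs count tibbles (`chrom`, `pos`, `n_reads`,
#'   `n_unconverted`) for the two chemistries; sites are matched on
#'   (`chrom`, `pos`).  Sites with zero reads in either chemistry are
#'   dropped.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @param chemistry optional chemistry list enabling conversion-error
#'   correction (off by default).
#' @return Tibble with per-site `level_modified`, `level_5mC`,
#'   `level_5hmC`, `level_5hmC_raw`, depths (`n_reads_bs`,
#'   `n_reads_oxbs`, `n_reads_min`) and `ci_*` columns.
#' @examples
#' bs <- tibble::tibble(chrom = "amp", pos = 10, n_reads = 100, n_unconverted = 80)
#' ox <- tibble::tibble(chrom = "amp", pos = 10, n_reads = 100, n_unconverted = 60)
#' estimate_from_bs_oxbs(bs, ox)  # 5mC 0.6, 5hmC 0.2
#' @export
estimate_from_bs_oxbs <- function(bs, oxbs, conf_level = 0.95,
                                  chemistry = NULL) {
  j <- inner_join(
    select(bs, "chrom", "pos", bs_reads = "n_reads", bs_c = "n_unconverted"),
    select(oxbs, "chrom", "pos", ox_reads = "n_reads", ox_c = "n_unconverted"),
    by = c("chrom", "pos")
  )
  j <- filter(j, .data$bs_reads > 0, .data$ox_reads > 0)
  mod <- j$bs_c / j$bs_reads
  m5 <- j$ox_c / j$ox_reads
  raw <- mod - m5
  ci_mod <- wilson_ci(j$bs_c, j$bs_reads, conf_level)
  ci_m5 <- wilson_ci(j$ox_c, j$ox_reads, conf_level)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_h <- sqrt(mod * (1 - mod) / j$bs_reads + m5 * (1 - m5) / j$ox_reads)
  out <- tibble(
    chrom = j$chrom, pos = j$pos,
    level_modified = mod, level_5mC = m5,
    level_5hmC = pmax(0, raw), level_5hmC_raw = raw,
    n_reads_bs = j$bs_reads, n_reads_oxbs = j$ox_reads,
    n_reads_min = pmin(j$bs_reads, j$ox_reads),
    ci_modified_low = ci_mod$low, ci_modified_high = ci_mod$high,
    ci_5mC_low = ci_m5$low, ci_5mC_high = ci_m5$high,
    ci_5hmC_low = pmax(0, raw - z * se_h),
    ci_5hmC_high = pmin(1, raw + z * se_h)
  )
  if (!is.null(chemistry)) {
    mod_c <- invert_chemistry(mod, chemistry$conversion,
                              chemistry$fail[["BS"]])
    m5_c <- invert_chemistry(m5, chemistry$conversion,
                             chemistry$fail[["oxBS"]])
    out$level_modified_corrected <- mod_c
    out$level_5mC_corrected <- m5_c
    out$level_5hmC_corrected <- pmax(0, mod_c - m5_c)
  }
  out
}

# observed unconverted fraction -> true protected fraction under the
# stated conversion chemistry, clamped to [0, 1]
invert_chemistry <- function(p_hat, conversion, fail) {
  den <- (1 - fail) - (1 - conversion)
  stopifnot(den > 0)
  pmin(1, pmax(0, (p_hat - (1 - conversion)) / den))
}

#' Estimate 5hmC from TAB counts (optionally 5mC from paired BS)
#'
#' TAB-seq reads 5hmC directly as its unconverted fraction.  When a
#' paired BS table is supplied, total modification and
#' `5mC = BS - TAB` (clamped at 0) are also reported at matched sites.
#'
#' @param tab count tibble for the TAB chemistry.
#' @param bs optional matched BS count tibble.
#' @param conf_level confidence level for the Wilson intervals.
#' @return Per-site tibble with `level_5hmC` (and `level_modified`,
#'   `level_5mC` when `bs` is given); zero-coverage sites are dropped.
#' @export
estimate_from_tab <- function(tab, bs = NULL, conf_level = 0.95) {
  t2 <- filter(tab, .data$n_reads > 0)
  h <- t2$n_unconverted / t2$n_reads
  ci <- wilson_ci(t2$n_unconverted, t2$n_reads, conf_level)
  out <- tibble(chrom = t2$chrom, pos = t2$pos, level_5hmC = h,
                n_reads_tab = t2$n_reads, n_reads_min = t2$n_reads,
                ci_5hmC_low = ci$low, ci_5hmC_high = ci$high)
  if (is.null(bs)) return(out)
  j <- inner_join(out,
                  select(filter(bs, .data$n_reads > 0),
                         "chrom", "pos", bs_reads = "n_reads",
                         bs_c = "n_unconverted"),
                  by = c("chrom", "pos"))
  mod <- j$bs_c / j$bs_reads
  mutate(select(j, -"bs_reads", -"bs_c"),
         level_modified = mod,
         level_5mC = pmax(0, mod - .data$level_5hmC),
         n_reads_min = pmin(.data$n_reads_min, j$bs_reads),
         .after = "pos")
}

#' Drop CpGs below a read-depth threshold
#'
#' Amplicon-style filtering: a CpG is kept only when its depth reaches
#' `min_reads`.  With `joint = TRUE` (the default) and a `chemistry`
#' column present, the threshold must hold in *every* chemistry at the
#' site — a subtraction estimate needs adequate depth on both of its
#' inputs; with `joint = FALSE` rows are filtered individually.
#'
#' @param counts count tibble (`chrom`, `pos`, `n_reads`, ...),
#'   optionally with a `chemistry` column.
#' @param min_reads depth threshold (default 100, the usual amplicon
#'   cut); kept sites satisfy `n_reads >= min_reads`.
#' @param joint apply the threshold jointly across chemistries at each
#'   site (default `TRUE`).
#' @return The filtered tibble (idempotent; never adds sites).
#' @export
filter_min_coverage <- function(counts, min_reads = 100, joint = TRUE) {
  stopifnot(min_reads >= 1)
  # raw count tables carry n_reads; estimate tables carry n_reads_min,
  # which is already the joint (minimum-across-chemistries) depth
  dcol <- intersect(c("n_reads", "n_reads_min"), names(counts))[1]
  if (is.na(dcol)) abort("`counts` has no n_reads / n_reads_min column")
  if (joint && dcol == "n_reads" && "chemistry" %in% names(counts)) {
    g <- group_by(counts, .data$chrom, .data$pos)
    ungroup(filter(g, all(.data$n_reads >= min_reads)))
  } else {
    filter(counts, .data[[dcol]] >= min_reads)
  }
}

#' Average per-CpG estimates across replicates
#'
#' Unweighted mean of each level column across the replicates in which a
#' CpG is observed, the convention for amplicon data where each point is
#' the average of the biological replicates at that CpG.
#'
#' @param estimates either a list of per-replicate estimate tibbles or a
#'   single tibble with a `replicate` column.
#' @return Per-CpG tibble with the mean of every `level_*` column and
#'   `n_replicates`.
#' @export
replicate_average <- function(estimates) {
  if (is.data.frame(estimates)) {
    stopifnot("replicate" %in% names(estimates))
    x <- estimates
  } else {
    x <- bind_rows(estimates, .id = "replicate")
  }
  levels <- grep("^level_", names(x), value = TRUE)
  if (length(levels) == 0) abort("no level_* columns to average")
  summarise(group_by(x, .data$chrom, .data$pos),
            across(all_of(levels), mean),
            n_replicates = n(), .groups = "drop")
}

#' Aggregate per-CpG estimates over regions
#'
#' Coverage-weighted mean of each level over the CpGs contained in each
#' region (e.g. individual TE copies); regions containing no estimated
#' CpG get `NA`, not 0.
#'
#' @param sites per-CpG estimate tibble (`chrom`, `pos`, `level_*`
#'   columns, and a depth column `n_reads_min` or `n_reads` used as the
#'   weight; absent depth means unweighted).
#' @param regions interval tibble (e.g. TE copies).
#' @return `regions` with `region_id`, `n_cpgs` and one
#'   coverage-weighted mean column per level.
#' @export
aggregate_by_region <- function(sites, regions) {
  check_intervals(regions, "regions")
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  levels <- grep("^level_", names(sites), value = TRUE)
  if (length(levels) == 0) abort("`sites` has no level_* columns")
  wcol <- intersect(c("n_reads_min", "n_reads"), names(sites))[1]
  w <- if (is.na(wcol)) rep(1, nrow(sites)) else sites[[wcol]]
  out <- mutate(regions, region_id = row_number(), .before = 1)
  out$n_cpgs <- 0L
  for (lev in levels) out[[lev]] <- NA_real_
  if (nrow(sites) > 0 && nrow(regions) > 0) {
    lv <- union(sites$chrom, regions$chrom)
    sgr <- GenomicRanges::GRanges(factor(sites$chrom, levels = lv),
                                  IRanges::IRanges(sites$pos + 1, width = 1))
    hits <- GenomicRanges::findOverlaps(sgr, as_gr(regions, lv),
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    for (r in unique(si)) {
      ii <- qi[si == r]
      out$n_cpgs[r] <- length(ii)
      for (lev in levels) {
        out[[lev]][r] <- sum(sites[[lev]][ii] * w[ii]) / sum(w[ii])
      }
    }
  }
  out
}

#' Compare two groups of levels (rank-sum or Welch t)
#'
#' The default two-sided Wilcoxon rank-sum test uses exact enumeration
#' of the rank-sum null distribution (ties handled by mid-ranks) when
#' `n_a + n_b <= exact_limit`, via a subset-sum dynamic programme over
#' the combined ranks, and the tie-corrected normal approximation with
#' continuity correction otherwise.  `test = "t"` gives Welch's t-test.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param exact_limit largest `n_a + n_b` for exact enumeration
#'   (default 12).
#' @return One-row tibble (`method`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`).  For the rank-sum test `statistic` is
#'   the rank sum of `a`.
#' @examples
#' compare_groups(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
compare_groups <- function(a, b, test = c("wilcoxon", "t"), exact_limit = 12) {
  test <- match.arg(test)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  base <- tibble(n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b))
  if (test == "t") {
    tt <- t.test(a, b)
    return(bind_cols(tibble(method = "welch_t",
                            statistic = unname(tt$statistic),
                            p_value = tt$p.value), base))
  }
  r <- rank(c(a, b))
  w <- sum(r[seq_along(a)])
  n <- length(r); na <- length(a)
  if (n <= exact_limit) {
    p <- ranksum_exact_p(r, na, w)
    method <- "wilcoxon_exact"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / ((n) * (n - 1))
    sigma2 <- na * length(b) / 12 * ((n + 1) - tie_term)
    cc <- if (w == mu) 0 else 0.5
    z <- (w - mu - sign(w - mu) * cc) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "wilcoxon_normal"
  }
  bind_cols(tibble(method = method, statistic = w, p_value = p), base)
}

# exact two-sided rank-sum p by DP over subsets of size na;
# ranks are doubled so mid-ranks become integers
ranksum_exact_p <- function(r, na, w) {
  r2 <- as.integer(round(2 * r))
  w2 <- as.integer(round(2 * w))
  S <- sum(r2)
  # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  dp <- matrix(0, nrow = na + 1, ncol = S + 1)
  dp[1, 1] <- 1
  for (x in r2) {
    for (k in na:1) {
      shifted <- c(rep(0, x), dp[k, 1:(S + 1 - x)])
      dp[k + 1, ] <- dp[k + 1, ] + shifted
    }
  }
  counts <- dp[na + 1, ]
  total <- sum(counts)
  sums <- 0:S
  p_le <- sum(counts[sums <= w2]) / total
  p_ge <- sum(counts[sums >= w2]) / total
  min(1, 2 * min(p_le, p_ge))
}
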