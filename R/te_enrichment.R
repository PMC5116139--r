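#' Sample length-matched random intervals
#'
#' Draws a control interval set with exactly the same multiset of lengths
#' as `peaks`, each interval placed uniformly at random among all valid
#' placements.  A placement is valid when the interval lies fully inside
#' one chromosome, or — when `mappability` is supplied — fully inside one
#' uniquely mappable block.  This is the null model against which peak /
#' TE-class overlaps are judged: random placement "anywhere in the
#' genome" for inclusive-mapping peaks, or restricted to the uniqueome
#' for uniquely mapped peaks.
#'
#' @param peaks interval tibble of peaks.
#' @param chrom_sizes named numeric vector or tibble (`chrom`, `length`).
#' @param mappability optional mappability tibble (see
#'   [build_mappability()]); when given, intervals are placed fully
#'   inside single mappable blocks.
#' @param n_sets number of independent matched sets to draw.
#' @param seed optional integer seed; the draw is reproducible given the
#'   seed.
#' @return Interval tibble with columns `.set` (1..`n_sets`), `peak_id`
#'   (row of `peaks` the length was matched to), `chrom`, `start`, `end`.
#' @export
sample_matched_random <- function(peaks, chrom_sizes, mappability = NULL,
                                  n_sets = 1, seed = NULL) {
  check_intervals(peaks, "peaks")
  stopifnot(n_sets >= 1)
  blocks <- if (is.null(mappability)) {
    cs <- chrom_sizes_tbl(chrom_sizes)
    tibble(chrom = cs$chrom, bstart = 0, bend = cs$length)
  } else {
    check_intervals(mappability, "mappability")
    tibble(chrom = mappability$chrom, bstart = mappability$start,
           bend = mappability$end)
  }
  if (nrow(peaks) == 0) {
    return(tibble(.set = integer(), peak_id = integer(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character()))
  }
  bw <- blocks$bend - blocks$bstart
  lens <- peaks$end - peaks$start
  # placements are i.i.d. across peaks and sets, so all n * n_sets draws
  # are made in one vectorised pass per unique peak length
  lens_full <- rep(lens, times = n_sets)
  run <- function() {
    out_chrom <- character(length(lens_full))
    out_start <- numeric(length(lens_full))
    for (L in unique(lens)) {
      idx <- which(lens_full == L)
      w <- pmax(bw - L + 1, 0)
      if (sum(w) == 0) {
        abort(sprintf(
          "peak %d (length %d bp) does not fit in any %s",
          which(lens == L)[1], L,
          if (is.null(mappability)) "chromosome" else "mappable block"))
      }
      b <- sample.int(nrow(blocks), length(idx), replace = TRUE, prob = w)
      off <- floor(runif(length(idx)) * w[b])
      out_chrom[idx] <- blocks$chrom[b]
      out_start[idx] <- blocks$bstart[b] + off
    }
    tibble(.set = rep(seq_len(n_sets), each = length(lens)),
           peak_id = rep(seq_along(lens), times = n_sets),
           chrom = out_chrom, start = out_start,
           end = out_start + lens_full, strand = ".")
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Permutation enrichment of peaks over TE classes
#'
#' For each TE class, counts the peaks overlapping at least one annotated
#' copy and compares the count with `n_reps` random draws of
#' length-matched intervals ([sample_matched_random()]).  The one-sided
#' (enrichment) empirical p-value uses the add-one estimator
#' `p = (1 + #[null >= observed]) / (n_reps + 1)`, so it is never zero,
#' and is corrected across classes by Benjamini-Hochberg.
#'
#' @param peaks interval tibble of peaks.
#' @param te_copies TE-copy tibble (see [read_repeatmasker()]).
#' @param chrom_sizes named numeric vector or tibble (`chrom`, `length`).
#' @param by name of the `te_copies` column defining the classes tested
#'   (default `"te_class"`; use `"family"` or `"repeat_name"` for finer
#'   groupings).
#' @param n_reps number of random matched sets (default 1000).
#' @param mappability optional mappability tibble restricting the null.
#' @param min_overlap minimum shared bp for an overlap (default 1).
#' @param seed optional integer seed for the null draws.
#' @return A `te_enrichment` object.  `tidy()` returns the per-class
#'   table (`class`, `n_copies`, `observed`, `n_copies_hit`,
#'   `expected_mean`, `expected_sd`, `fold`, `p_value`, `q_value`);
#'   `glance()` a one-row summary; `autoplot()` a fold-change bar chart.
#'   `fold` is `NA` when the class has no annotated copies (rather than
#'   an infinite ratio).
#' @export
enrichment_test <- function(peaks, te_copies, chrom_sizes, by = "te_class",
                            n_reps = 1000, mappability = NULL,
                            min_overlap = 1, seed = NULL) {
  check_intervals(peaks, "peaks")
  check_intervals(te_copies, "te_copies")
  stopifnot(n_reps >= 1, by %in% names(te_copies))
  # a factor column may carry unused levels: classes with zero annotated
  # copies, reported with missing fold rather than an infinite ratio
  classes <- if (is.factor(te_copies[[by]])) {
    levels(te_copies[[by]])
  } else {
    sort(unique(te_copies[[by]]))
  }
  rand <- sample_matched_random(peaks, chrom_sizes, mappability = mappability,
                                n_sets = n_reps, seed = seed)
  lv <- Reduce(union, list(peaks$chrom, te_copies$chrom, rand$chrom))
  rand_gr <- if (nrow(rand) > 0) as_gr(rand, lv) else NULL
  peaks_gr <- if (nrow(peaks) > 0) as_gr(peaks, lv) else NULL
  null_counts <- matrix(0, nrow = n_reps, ncol = length(classes),
                        dimnames = list(NULL, classes))
  rows <- purrr::map_dfr(classes, function(cl) {
    copies <- te_copies[te_copies[[by]] == cl, , drop = FALSE]
    cgr <- as_gr(copies, lv)
    obs <- if (is.null(peaks_gr)) 0L else {
      sum(IRanges::overlapsAny(peaks_gr, cgr, minoverlap = min_overlap,
                               ignore.strand = TRUE))
    }
    n_hit <- if (is.null(peaks_gr)) 0L else {
      sum(IRanges::overlapsAny(cgr, peaks_gr, minoverlap = min_overlap,
                               ignore.strand = TRUE))
    }
    counts <- if (is.null(rand_gr)) rep(0, n_reps) else {
      hit <- IRanges::overlapsAny(rand_gr, cgr, minoverlap = min_overlap,
                                  ignore.strand = TRUE)
      tabulate(rand$.set[hit], nbins = n_reps)
    }
    null_counts[, cl] <<- counts
    em <- mean(counts)
    tibble(
      class = cl,
      n_copies = nrow(copies),
      observed = as.integer(obs),
      n_copies_hit = as.integer(n_hit),
      expected_mean = em,
      expected_sd = stats::sd(counts),
      fold = if (em > 0) obs / em else NA_real_,
      p_value = (1 + sum(counts >= obs)) / (n_reps + 1)
    )
  })
  rows$q_value <- bh_adjust(rows$p_value)
  structure(
    list(results = rows, n_reps = n_reps, by = by, seed = seed,
         restricted = !is.null(mappability), n_peaks = nrow(peaks),
         null_counts = null_counts),
    class = "te_enrichment"
  )
}

#' @export
print.te_enrichment <- function(x, ...) {
  cat(sprintf(
    "Peak/TE-class enrichment: %d peaks, %d classes (by %s), %d matched random sets%s\n",
    x$n_peaks, nrow(x$results), x$by, x$n_reps,
    if (x$restricted) ", mappability-restricted null" else ""))
  print(x$results)
  invisible(x)
}

#' @rdname enrichment_test
#' @param x a `te_enrichment` object.
#' @param ... unused.
#' @export
tidy.te_enrichment <- function(x, ...) x$results

#' @rdname enrichment_test
#' @export
glance.te_enrichment <- function(x, ...) {
  tibble(n_peaks = x$n_peaks, n_classes = nrow(x$results),
         n_reps = x$n_reps,
         n_significant = sum(x$results$q_value < 0.05, na.rm = TRUE),
         restricted_null = x$restricted)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`:
#' step-up q-values `q_(i) = min_{j >= i} p_(j) m / j`, capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Per-family peak-overlap fractions in evolutionary-age order
#'
#' For each TE family, computes the fraction of (optionally full-length)
#' copies overlapped by at least one peak from each mapping mode:
#' `frac_unique` for uniquely mapped peaks and `frac_ambiguous` for
#' inclusive-mapping ("ambiguous") peaks.  Rows are emitted in
#' evolutionary-age order: the explicit `age_order` when given (youngest
#' first), otherwise families ranked by mean percent divergence from
#' consensus (lower divergence = younger).
#'
#' @param te_copies TE-copy tibble with `family` (and `divergence` for
#'   the fallback ordering).
#' @param unique_peaks,ambiguous_peaks interval tibbles of peaks from
#'   unique and inclusive mapping; either may be `NULL` (fraction 0).
#' @param age_order optional character vector of family names, youngest
#'   first; must cover every family present.
#' @param full_length_only restrict to copies longer than
#'   `full_length_threshold` bp (default `TRUE`).
#' @param full_length_threshold strict length threshold in bp (default
#'   5000).
#' @param min_overlap minimum shared bp for an overlap.
#' @return Tibble (`family`, `age_rank`, `n_copies`, `frac_unique`,
#'   `frac_ambiguous`), one row per family in age order; fractions are
#'   `NA` for families with no copies after the length filter.
#' @export
family_age_summary <- function(te_copies, unique_peaks = NULL,
                               ambiguous_peaks = NULL, age_order = NULL,
                               full_length_only = TRUE,
                               full_length_threshold = 5000,
                               min_overlap = 1) {
  check_intervals(te_copies, "te_copies")
  stopifnot("family" %in% names(te_copies))
  all_families <- unique(te_copies$family)
  if (is.null(age_order)) {
    if (!"divergence" %in% names(te_copies)) {
      abort("need `age_order` or a `divergence` column to order families by age")
    }
    mdiv <- summarise(group_by(te_copies, .data$family),
                      mdiv = mean(.data$divergence), .groups = "drop")
    age_order <- mdiv$family[order(mdiv$mdiv)]
  } else if (!all(all_families %in% age_order)) {
    abort(sprintf("`age_order` is missing families: %s",
                  paste(setdiff(all_families, age_order), collapse = ", ")))
  }
  copies <- if (full_length_only) {
    filter(classify_full_length(te_copies, full_length_threshold),
           .data$full_length)
  } else te_copies
  frac_hit <- function(fam_copies, peaks) {
    if (nrow(fam_copies) == 0) return(NA_real_)
    if (is.null(peaks) || nrow(peaks) == 0) return(0)
    mean(flag_overlaps(fam_copies, peaks, min_overlap = min_overlap)$hit)
  }
  purrr::imap_dfr(age_order, function(fam, rank) {
    fc <- copies[copies$family == fam, , drop = FALSE]
    tibble(family = fam, age_rank = as.integer(rank), n_copies = nrow(fc),
           frac_unique = frac_hit(fc, unique_peaks),
           frac_ambiguous = frac_hit(fc, ambiguous_peaks))
  })
}
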