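#' Genomic interval tables
#'
#' Every interval-shaped object in retroepi is an ordinary tibble with at
#' least the columns `chrom` (character), `start` and `end` (0-based
#' half-open, so `end` is exclusive) and optionally `strand` (`"+"`, `"-"`
#' or `"."`).  1-based inputs (RepeatMasker, Bismark) are converted at the
#' I/O boundary so that a single convention holds internally.
#'
#' @param chrom,start,end,strand vectors of equal length (or length 1,
#'   recycled) describing the intervals.
#' @param ... further columns passed to [tibble::tibble()].
#' @return A tibble with one row per interval.
#' @examples
#' interval_tbl("chr1", c(0, 500), c(100, 900))
#' @export
interval_tbl <- function(chrom, start, end, strand = ".", ...) {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = as.character(strand),
    ...
  )
  check_intervals(x)
  x
}

# validate the interval contract; `what` names the offending argument in
# error messages
check_intervals <- function(x, what = "intervals", allow_empty = TRUE) {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("`%s` must have columns %s (missing: %s)", what,
                  paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  if (nrow(x) == 0) {
    if (!allow_empty) abort(sprintf("`%s` must contain at least one interval", what))
    return(invisible(x))
  }
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom))) {
    abort(sprintf("`%s` has empty chromosome names", what))
  }
  bad <- which(!(x$start >= 0 & x$end > x$start))
  if (length(bad) > 0) {
    abort(sprintf("`%s` row %d violates 0 <= start < end (start=%s, end=%s)",
                  what, bad[1], x$start[bad[1]], x$end[bad[1]]))
  }
  invisible(x)
}

# tibble (0-based half-open) -> GRanges (1-based closed); passing shared
# `seqlevels` avoids seqlevel-mismatch warnings between disjoint sets
as_gr <- function(x, seqlevels = NULL) {
  s <- if ("strand" %in% names(x)) {
    ifelse(is.na(x$strand) | x$strand == ".", "*", x$strand)
  } else "*"
  sq <- if (is.null(seqlevels)) {
    x$chrom
  } else {
    factor(x$chrom, levels = seqlevels)
  }
  GenomicRanges::GRanges(
    seqnames = sq,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = s
  )
}

#' Flag query intervals that overlap a target set
#'
#' Overlap is defined on half-open intervals: two intervals overlap when
#' they share at least `min_overlap` base pairs.  Strand is ignored.
#'
#' @param queries,targets interval tibbles (see [interval_tbl()]).
#' @param min_overlap minimum number of shared base pairs (default 1).
#' @return `queries` with a logical column `hit`.
#' @export
flag_overlaps <- function(queries, targets, min_overlap = 1) {
  check_intervals(queries, "queries")
  check_intervals(targets, "targets")
  if (nrow(queries) == 0) return(mutate(queries, hit = logical(0)))
  hit <- if (nrow(targets) == 0) {
    rep(FALSE, nrow(queries))
  } else {
    lv <- union(queries$chrom, targets$chrom)
    IRanges::overlapsAny(as_gr(queries, lv), as_gr(targets, lv),
                         minoverlap = min_overlap, ignore.strand = TRUE)
  }
  mutate(queries, hit = hit)
}

#' Count query intervals overlapping at least one target
#'
#' @inheritParams flag_overlaps
#' @return A single integer.
#' @examples
#' q <- interval_tbl("chr1", 100, 200)
#' overlap_count(q, interval_tbl("chr1", 199, 300))  # 1 (shares one bp)
#' overlap_count(q, interval_tbl("chr1", 200, 300))  # 0 (half-open)
#' @export
overlap_count <- function(queries, targets, min_overlap = 1) {
  sum(flag_overlaps(queries, targets, min_overlap = min_overlap)$hit)
}

#' Classify TE copies as full length
#'
#' A copy is full length when its genomic span is strictly greater than
#' `threshold` base pairs.  The strict inequality mirrors the conventional
#' "> 5 kb" cut used for young LINE-1 elements, whose intact copies run
#' 6-7 kb while 5'-truncated fragments are shorter.
#'
#' @param copies an interval tibble of TE copies.
#' @param threshold length threshold in bp (default 5000).
#' @return `copies` with a logical `full_length` column (replaced if
#'   already present).
#' @export
classify_full_length <- function(copies, threshold = 5000) {
  stopifnot(threshold > 0)
  check_intervals(copies, "copies")
  copies$full_length <- (copies$end - copies$start) > threshold
  copies
}

# normalise chrom sizes input: named numeric vector or tibble(chrom, length)
chrom_sizes_tbl <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
    tibble(chrom = as.character(chrom_sizes$chrom),
           length = as.numeric(chrom_sizes$length))
  } else {
    stopifnot(!is.null(names(chrom_sizes)))
    tibble(chrom = names(chrom_sizes), length = as.numeric(chrom_sizes))
  }
}
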