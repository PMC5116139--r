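#' Signal tracks and meta-profiles
#'
#' A signal track is a bedGraph-shaped tibble (`chrom`, `start`, `end`,
#' `score`) with a constant bin width; [reads_to_coverage()] produces
#' one.  Profiles average such tracks around anchor points (peak summits
#' or midpoints), along consensus elements, or over individual TE
#' copies.
#'
#' @name meta_profiles
NULL

track_binsize <- function(track) {
  w <- track$end - track$start
  bs <- max(w)
  if (any(w > bs) || any(w <= 0)) abort("track bins must have constant width")
  bs
}

# dense per-chromosome value vectors from a (possibly sparse) track
track_vectors <- function(track) {
  bs <- track_binsize(track)
  vecs <- lapply(split(track, track$chrom), function(tr) {
    nb <- max(tr$start %/% bs) + 1
    v <- numeric(nb)
    v[tr$start %/% bs + 1] <- tr$score
    v
  })
  list(binsize = bs, vectors = vecs)
}

#' Average signal in a window around anchor points
#'
#' Computes the mean of a binned signal track in a fixed window centred
#' on each anchor; minus-strand anchors contribute their window reversed
#' so every profile reads 5' to 3'.  Anchors whose extended window falls
#' outside the track are dropped and counted.
#'
#' @param track signal-track tibble.
#' @param anchors tibble with columns `chrom`, `pos` (0-based anchor
#'   position) and optionally `strand`; see [peaks_to_anchors()].
#' @param window bp flanking the anchor on each side (default 4000).
#' @return A `meta_profile` tibble (`offset` = bp of bin start relative
#'   to the anchor, `mean_signal`), with attributes `n_anchors`,
#'   `n_dropped`, `window`, `binsize`.  Errors if no anchor is usable.
#' @export
anchor_profile <- function(track, anchors, window = 4000) {
  stopifnot(all(c("chrom", "pos") %in% names(anchors)))
  tv <- track_vectors(track)
  bs <- tv$binsize
  if (window %% bs != 0) abort("`window` must be a multiple of the track bin size")
  nb <- window %/% bs
  strand <- if ("strand" %in% names(anchors)) anchors$strand else "."
  rows <- matrix(NA_real_, nrow = nrow(anchors), ncol = 2 * nb)
  usable <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    v <- tv$vectors[[anchors$chrom[i]]]
    if (is.null(v)) next
    b0 <- anchors$pos[i] %/% bs
    idx <- b0 + seq(-nb, nb - 1)
    if (idx[1] < 0 || idx[length(idx)] >= length(v)) next
    vals <- v[idx + 1]
    if (identical(strand[i], "-")) vals <- rev(vals)
    rows[i, ] <- vals
    usable[i] <- TRUE
  }
  if (!any(usable)) abort("no usable anchors (all out of bounds)")
  out <- tibble(
    offset = seq(-nb, nb - 1) * bs,
    mean_signal = colMeans(rows[usable, , drop = FALSE])
  )
  structure(out, class = c("meta_profile", class(out)),
            n_anchors = sum(usable), n_dropped = sum(!usable),
            window = window, binsize = bs)
}

#' Convert peaks to profile anchors
#'
#' Uses the summit (when a `summit_offset` column is present and
#' non-missing) or the interval midpoint as the anchor position.
#'
#' @param peaks interval tibble, optionally with `summit_offset`.
#' @return Anchor tibble (`chrom`, `pos`, `strand`).
#' @export
peaks_to_anchors <- function(peaks) {
  check_intervals(peaks, "peaks")
  mid <- floor((peaks$start + peaks$end) / 2)
  pos <- if ("summit_offset" %in% names(peaks)) {
    ifelse(is.na(peaks$summit_offset), mid, peaks$start + peaks$summit_offset)
  } else mid
  tibble(chrom = peaks$chrom, pos = pos,
         strand = if ("strand" %in% names(peaks)) peaks$strand else ".")
}

#' Binned coverage along a consensus element
#'
#' Bins IP (and optionally input) reads along a consensus sequence, each
#' read counted once at its midpoint bin, and forms a per-bin IP/input
#' enrichment ratio.  Input counts are first scaled to the IP library
#' size; a pseudocount is added to both numerator and denominator so the
#' ratio is defined in empty bins.
#'
#' @param ip_reads interval tibble of reads in consensus coordinates
#'   (only `start`/`end` are used).
#' @param consensus_length length of the consensus element in bp (> 0).
#' @param input_reads optional interval tibble of input/control reads.
#' @param binsize bin width in bp (default 100).
#' @param pseudocount reads added to each bin of both libraries when
#'   forming the ratio (default 0.5).
#' @param scale_input scale input counts by total-read ratio before the
#'   division (default `TRUE`).
#' @return Tibble (`bin_start`, `bin_end`, `ip`, `input`, `ratio`);
#'   `input`/`ratio` are `NA` when no input is supplied.  `sum(ip)`
#'   always equals the number of IP reads.
#' @export
consensus_profile <- function(ip_reads, consensus_length, input_reads = NULL,
                              binsize = 100, pseudocount = 0.5,
                              scale_input = TRUE) {
  if (consensus_length <= 0) abort("`consensus_length` must be positive")
  nb <- ceiling(consensus_length / binsize)
  bin_counts <- function(reads) {
    if (is.null(reads) || nrow(reads) == 0) return(numeric(nb))
    mid <- floor((reads$start + reads$end) / 2)
    if (any(mid < 0 | mid >= consensus_length)) {
      abort("read midpoints outside the consensus element")
    }
    tabulate(mid %/% binsize + 1, nbins = nb)
  }
  ip <- bin_counts(ip_reads)
  out <- tibble(
    bin_start = (seq_len(nb) - 1) * binsize,
    bin_end = pmin(seq_len(nb) * binsize, consensus_length),
    ip = ip
  )
  if (is.null(input_reads)) {
    out$input <- NA_real_
    out$ratio <- NA_real_
  } else {
    inp <- bin_counts(input_reads)
    scaled <- if (scale_input && sum(inp) > 0) inp * sum(ip) / sum(inp) else inp
    out$input <- inp
    out$ratio <- (ip + pseudocount) / (scaled + pseudocount)
  }
  out
}

#' Mean signal of several tracks over individual TE copies
#'
#' Entry (i, j) is the length-normalised mean of track j over copy i's
#' interval (so copies of different lengths are comparable); copies
#' extending beyond a track get `NA`, not 0.  Rows are sorted by the
#' primary track, descending (stable on ties).
#'
#' @param tracks a named list of signal-track tibbles (names become
#'   columns) or a single track.
#' @param copies non-empty TE-copy (or any interval) tibble.
#' @param primary name of the track used for sorting (default: first).
#' @return Tibble with `copy_id` (input row), the copies' annotation
#'   columns, and one mean-signal column per track.
#' @export
per_copy_signal <- function(tracks, copies, primary = NULL) {
  check_intervals(copies, "copies", allow_empty = FALSE)
  if (is.data.frame(tracks)) tracks <- list(signal = tracks)
  stopifnot(length(tracks) >= 1, !is.null(names(tracks)))
  if (is.null(primary)) primary <- names(tracks)[1]
  stopifnot(primary %in% names(tracks))
  out <- mutate(copies, copy_id = row_number(), .before = 1)
  for (lab in names(tracks)) {
    tv <- track_vectors(tracks[[lab]])
    bs <- tv$binsize
    out[[lab]] <- vapply(seq_len(nrow(copies)), function(i) {
      v <- tv$vectors[[copies$chrom[i]]]
      s <- copies$start[i]; e <- copies$end[i]
      if (is.null(v) || e > length(v) * bs) return(NA_real_)
      b <- (s %/% bs):((e - 1) %/% bs)
      w <- pmin(e, (b + 1) * bs) - pmax(s, b * bs)
      sum(v[b + 1] * w) / sum(w)
    }, numeric(1))
  }
  arrange(out, desc(.data[[primary]]))
}

#' Bin per-CpG methylation estimates along a consensus element
#'
#' Coverage-weighted mean 5mC and 5hmC per bin; bins containing no
#' covered CpG are reported as `NA`, not 0.
#'
#' @param sites tibble of per-CpG estimates in consensus coordinates:
#'   column `pos` plus any of `level_5mC`, `level_5hmC`,
#'   `level_modified`, and a read-depth column (`n_reads_min` or
#'   `n_reads`) used as the weight.
#' @param consensus_length length of the consensus element in bp.
#' @param binsize bin width in bp (default 100).
#' @return Tibble (`bin_start`, `bin_end`, `n_cpgs`, one mean column per
#'   level present), one row per bin.
#' @export
methylation_profile <- function(sites, consensus_length, binsize = 100) {
  stopifnot("pos" %in% names(sites), consensus_length > 0)
  levels <- intersect(c("level_5mC", "level_5hmC", "level_modified"),
                      names(sites))
  if (length(levels) == 0) abort("`sites` has no level_* columns")
  wcol <- intersect(c("n_reads_min", "n_reads"), names(sites))[1]
  w <- if (is.na(wcol)) rep(1, nrow(sites)) else sites[[wcol]]
  nb <- ceiling(consensus_length / binsize)
  bin <- sites$pos %/% binsize + 1
  out <- tibble(bin_start = (seq_len(nb) - 1) * binsize,
                bin_end = pmin(seq_len(nb) * binsize, consensus_length),
                n_cpgs = tabulate(bin, nbins = nb))
  for (lev in levels) {
    num <- tapply(sites[[lev]] * w, factor(bin, levels = seq_len(nb)), sum)
    den <- tapply(w, factor(bin, levels = seq_len(nb)), sum)
    m <- as.numeric(num) / as.numeric(den)
    m[out$n_cpgs == 0] <- NA_real_
    out[[lev]] <- m
  }
  out
}
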