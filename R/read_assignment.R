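#' Multi-mapping read policies
#'
#' Repetitive DNA makes short reads ambiguous: a read from a young, highly
#' uniform TE family aligns equally well to many copies.  Two policies are
#' implemented on tables of candidate alignments ("hits"):
#'
#' * **unique** ([filter_unique()]): keep a read only when exactly one hit
#'   attains its best score; everything else is discarded.
#' * **inclusive** ([assign_inclusive()]): keep every read, assigning reads
#'   with several tied-best hits to one of them uniformly at random.
#'
#' A hit table has one row per candidate alignment, with columns
#' `read_id`, `chrom`, `start`, `end`, optionally `strand`, and scoring
#' columns `score` (alignment score, preferred) and/or `mapq`.  "Tied
#' best" means tied maximal `score`; when `score` is absent ties are on
#' `mapq`; when both are absent every hit of a multi-hit read is treated
#' as tied.
#'
#' @name read_assignment
NULL

# per-read best-hit subset, in deterministic (read_id, chrom, start) order
best_hits <- function(hits) {
  check_intervals(hits, "hits")
  stopifnot("read_id" %in% names(hits))
  key <- if ("score" %in% names(hits) && any(!is.na(hits$score))) {
    hits$score
  } else if ("mapq" %in% names(hits) && any(!is.na(hits$mapq))) {
    hits$mapq
  } else {
    rep(0, nrow(hits))
  }
  hits$.key <- ifelse(is.na(key), -Inf, key)
  hits <- arrange(hits, .data$read_id, .data$chrom, .data$start)
  hits <- group_by(hits, .data$read_id)
  hits <- filter(hits, .data$.key == max(.data$.key))
  hits <- ungroup(hits)
  select(hits, -".key")
}

#' Keep uniquely best-mapping reads
#'
#' @param hits a hit table (see [read_assignment]).
#' @return An assigned-read tibble (`read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mode = "unique"`): one row per read whose best score is
#'   attained by exactly one hit.
#' @examples
#' h <- tibble::tibble(read_id = c("r1", "r1", "r2"),
#'                     chrom = "chr1", start = c(0, 500, 100),
#'                     end = c(50, 550, 150), score = c(60, 60, 60))
#' filter_unique(h)  # r1 is tied at two loci and dropped; r2 kept
#' @export
filter_unique <- function(hits) {
  b <- best_hits(hits)
  b <- group_by(b, .data$read_id)
  b <- filter(b, n() == 1)
  b <- ungroup(b)
  finish_assigned(b, "unique")
}

#' Assign every read to one best-scoring hit at random
#'
#' Tied-best hits are chosen uniformly at random from a single seeded
#' generator consumed in read-id-sorted order, so reruns with the same
#' seed are identical.  Single-hit reads keep their hit regardless of the
#' seed.
#'
#' @param hits a hit table (see [read_assignment]).
#' @param seed integer seed (mandatory, for reproducibility).
#' @return An assigned-read tibble with `mode = "inclusive"`, one row per
#'   read.
#' @export
assign_inclusive <- function(hits, seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  b <- best_hits(hits)
  sizes <- dplyr::count(b, .data$read_id, name = ".n_best")
  # rows of b are grouped contiguously by read_id in sorted order
  grp_start <- cumsum(c(1, head(sizes$.n_best, -1)))
  offset <- withr::with_seed(as.integer(seed), {
    floor(runif(nrow(sizes)) * sizes$.n_best)
  })
  chosen <- b[grp_start + offset, ]
  finish_assigned(chosen, "inclusive")
}

finish_assigned <- function(b, mode) {
  if (!"strand" %in% names(b)) b$strand <- "."
  out <- select(b, "read_id", "chrom", "start", "end", "strand")
  out$mode <- mode
  out
}

#' Bin assigned reads into a coverage track
#'
#' Each read is counted once, at the bin containing its midpoint, so the
#' track total always equals the number of reads.
#'
#' @param assigned assigned-read tibble ([filter_unique()] /
#'   [assign_inclusive()] output, or any interval tibble).
#' @param chrom_sizes named numeric vector or tibble (`chrom`, `length`).
#' @param binsize bin width in bp (>= 1).
#' @return A dense signal-track tibble (`chrom`, `start`, `end`, `score`)
#'   covering every bin of every chromosome.
#' @export
reads_to_coverage <- function(assigned, chrom_sizes, binsize = 100) {
  stopifnot(binsize >= 1)
  cs <- chrom_sizes_tbl(chrom_sizes)
  track <- purrr::pmap_dfr(cs, function(chrom, length) {
    nb <- ceiling(length / binsize)
    tibble(chrom = chrom,
           start = (seq_len(nb) - 1) * binsize,
           end = pmin(seq_len(nb) * binsize, length),
           score = 0)
  })
  if (nrow(assigned) > 0) {
    check_intervals(assigned, "assigned")
    mid <- floor((assigned$start + assigned$end) / 2)
    key <- paste(assigned$chrom, mid %/% binsize)
    tkey <- paste(track$chrom, track$start %/% binsize)
    cnt <- table(key)
    idx <- match(names(cnt), tkey)
    if (anyNA(idx)) abort("assigned reads fall outside `chrom_sizes`")
    track$score[idx] <- track$score[idx] + as.numeric(cnt)
  }
  track
}

#' Read candidate alignments from a SAM/BAM file
#'
#' Reconstructs each read's hit set from primary plus secondary alignment
#' records grouped by read name, taking the alignment score from the `AS`
#' tag when present.  Requires the Rsamtools package.
#'
#' @param path path to a SAM or BAM file (SAM is converted on the fly).
#' @return A hit table (see [read_assignment]).
#' @export
read_sam_hits <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("read_sam_hits() requires the Rsamtools package")
  }
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "mapq", "qwidth"),
    tag = "AS"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  tibble(
    read_id = x$qname[keep],
    chrom = as.character(x$rname)[keep],
    start = x$pos[keep] - 1,
    end = x$pos[keep] - 1 + x$qwidth[keep],
    strand = as.character(x$strand)[keep],
    mapq = x$mapq[keep],
    score = if (!is.null(x$tag$AS)) x$tag$AS[keep] else NA_real_
  )
}

#' Write a hit table as a minimal SAM file
#'
#' The first hit of each read is written as the primary record and the
#' rest as secondary (flag 256/272) records; sequences are omitted
#' (`*`), which is sufficient for exchanging simulated alignments.
#'
#' @param hits a hit table (see [read_assignment]).
#' @param chrom_sizes named numeric vector or tibble (`chrom`, `length`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam_hits <- function(hits, chrom_sizes, path) {
  check_intervals(hits, "hits")
  cs <- chrom_sizes_tbl(chrom_sizes)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", cs$chrom, as.integer(cs$length)))
  h <- arrange(hits, .data$read_id, .data$chrom, .data$start)
  h <- group_by(h, .data$read_id)
  h <- mutate(h, .secondary = row_number() > 1)
  h <- ungroup(h)
  strand <- if ("strand" %in% names(h)) h$strand else "+"
  flag <- ifelse(h$.secondary, 256L, 0L) + ifelse(strand == "-", 16L, 0L)
  score <- if ("score" %in% names(h)) h$score else NA_real_
  mapq <- if ("mapq" %in% names(h)) h$mapq else 255
  len <- as.integer(h$end - h$start)
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*%s",
                  h$read_id, flag, h$chrom, as.integer(h$start) + 1L,
                  as.integer(ifelse(is.na(mapq), 255, mapq)), len,
                  ifelse(is.na(score), "", sprintf("\tAS:i:%d", as.integer(score))))
  writeLines(c(hdr, recs), path)
  invisible(path)
}
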