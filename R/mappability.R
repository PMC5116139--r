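#' Compute a uniqueness ("uniqueome") mappability track
#'
#' A genome position `p` is considered uniquely mappable for read length
#' `k` when the k-mer starting at `p` occurs exactly once in the union of
#' the genome and its reverse complement.  Runs of adjacent mappable
#' start positions are merged into intervals.  This is the exact,
#' desk-scale analogue of published uniqueome tracks, intended for
#' genomes small enough (tens of Mb) for in-memory k-mer counting.
#'
#' @param genome named character vector of chromosome sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param k read length in bp.
#' @return Mappability tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open intervals of mappable k-mer start positions) and
#'   attribute `read_length = k`.  Chromosomes shorter than `k`
#'   contribute nothing.
#' @export
build_mappability <- function(genome, k) {
  stopifnot(k >= 1)
  genome <- as_genome_chr(genome)
  kmers_of <- function(seq) {
    n <- nchar(seq)
    if (n < k) return(character(0))
    substring(seq, 1:(n - k + 1), k:n)
  }
  fwd <- lapply(genome, kmers_of)
  rc <- lapply(genome, function(s) kmers_of(revcomp(s)))
  all_kmers <- c(unlist(fwd, use.names = FALSE), unlist(rc, use.names = FALSE))
  out <- tibble(chrom = character(), start = numeric(), end = numeric())
  if (length(all_kmers) == 0) {
    attr(out, "read_length") <- k
    return(out)
  }
  u <- unique(all_kmers)
  occ <- tabulate(match(all_kmers, u), nbins = length(u))
  pieces <- purrr::imap(fwd, function(km, chrom) {
    if (length(km) == 0) return(NULL)
    ok <- occ[match(km, u)] == 1
    runs_to_intervals(ok, chrom)
  })
  out <- bind_rows(purrr::compact(pieces))
  attr(out, "read_length") <- k
  out
}

# logical run-length encoding of mappable start positions -> intervals
runs_to_intervals <- function(ok, chrom) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble(chrom = chrom, start = as.numeric(starts[keep]),
         end = as.numeric(ends[keep]))
}

as_genome_chr <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)) || length(genome) == 0)
  toupper(genome)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
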