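#' Read a RepeatMasker annotation
#'
#' Parses the classic RepeatMasker `.out` dialect: up to three header
#' lines followed by whitespace-delimited records with 1-based inclusive
#' genomic coordinates and strand `C` for the minus strand.  Coordinates
#' are converted to the package's 0-based half-open convention and the
#' records sorted by `(chrom, start)`.
#'
#' The "matching repeat" column becomes `repeat_name`; the "class/family"
#' column is split at the first `/` into `te_class` and `family` (records
#' without a `/` use the whole token for both).  Percent divergence from
#' the consensus is taken from the second column and kept as an age proxy.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @param full_length_threshold bp threshold passed to
#'   [classify_full_length()].
#' @return A TE-copy tibble with columns `chrom`, `start`, `end`,
#'   `strand`, `repeat_name`, `family`, `te_class`, `divergence`,
#'   `full_length`.
#' @export
read_repeatmasker <- function(path, full_length_threshold = 5000) {
  lines <- readLines(path)
  # header: lines before the first record whose leading field is numeric
  is_record <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    length(f) >= 11 && !is.na(suppressWarnings(as.numeric(f[1])))
  }
  body_idx <- which(nzchar(trimws(lines)) & vapply(lines, is_record, logical(1)))
  header_idx <- setdiff(which(nzchar(trimws(lines))), body_idx)
  if (length(header_idx) > 0 && any(header_idx > min(c(body_idx, Inf)))) {
    abort("unknown RepeatMasker dialect: non-record lines inside the body")
  }
  if (length(body_idx) == 0) {
    empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                    strand = character(), repeat_name = character(),
                    family = character(), te_class = character(),
                    divergence = numeric(), full_length = logical())
    return(empty)
  }
  parse_one <- function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    begin <- suppressWarnings(as.numeric(f[6]))
    end <- suppressWarnings(as.numeric(f[7]))
    div <- suppressWarnings(as.numeric(f[2]))
    if (is.na(begin) || is.na(end) || begin < 1 || end < begin) {
      abort(sprintf("malformed RepeatMasker record at line %d of %s", i, path))
    }
    strand <- f[9]
    if (!strand %in% c("+", "C", "-")) {
      abort(sprintf("malformed strand at line %d of %s", i, path))
    }
    cf <- strsplit(f[11], "/", fixed = TRUE)[[1]]
    tibble(
      chrom = f[5], start = begin - 1, end = end,
      strand = if (strand == "+") "+" else "-",
      repeat_name = f[10],
      family = if (length(cf) >= 2) cf[2] else cf[1],
      te_class = cf[1],
      divergence = if (is.na(div)) 0 else div
    )
  }
  out <- purrr::map_dfr(body_idx, parse_one)
  out <- arrange(out, .data$chrom, .data$start)
  classify_full_length(out, threshold = full_length_threshold)
}

#' Write TE copies as a RepeatMasker .out file
#'
#' Inverse of [read_repeatmasker()] for the fields the package models;
#' placeholder values are emitted for the alignment-score and
#' repeat-coordinate columns.
#'
#' @param copies TE-copy tibble (see [read_repeatmasker()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(copies, path) {
  check_intervals(copies, "copies")
  hdr <- c(
    "   SW  perc perc perc  query     position in query    matching    repeat         position in repeat",
    "score  div. del. ins.  sequence  begin  end   (left)  repeat      class/family   begin  end  (left)  ID",
    ""
  )
  fam <- if ("family" %in% names(copies)) copies$family else copies$repeat_name
  cls <- if ("te_class" %in% names(copies)) copies$te_class else "Unknown"
  div <- if ("divergence" %in% names(copies)) copies$divergence else 0
  recs <- sprintf(
    "%5d %5.1f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
    1000L, div, copies$chrom, copies$start + 1, copies$end,
    ifelse(copies$strand == "-", "C", "+"),
    copies$repeat_name,
    ifelse(cls == fam, cls, paste0(cls, "/", fam)),
    as.integer(copies$end - copies$start), seq_len(nrow(copies))
  )
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read intervals from a BED or narrowPeak file
#'
#' BED coordinates are already 0-based half-open.  Files with ten columns
#' are treated as MACS-style narrowPeak and the tenth column (summit
#' offset from the interval start, -1 for "not reported") becomes
#' `summit_offset`.
#'
#' @param path path to a BED3+/narrowPeak file.
#' @return An interval tibble; extra columns `name`, `score`,
#'   `summit_offset` when present in the file.
#' @export
read_bed <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$score <- as.numeric(raw[[5]])
  out$strand <- if (ncol(raw) >= 6) as.character(raw[[6]]) else "."
  if (ncol(raw) >= 10) {
    so <- as.numeric(raw[[10]])
    out$summit_offset <- ifelse(so < 0, NA_real_, so)
  }
  check_intervals(out, path)
  out
}

#' Write intervals to a BED file
#'
#' @param x interval tibble.
#' @param path output path.
#' @param name optional column name to use for the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name = NULL) {
  check_intervals(x)
  nm <- if (!is.null(name) && name %in% names(x)) x[[name]] else "."
  sc <- if ("score" %in% names(x)) x$score else 0
  st <- if ("strand" %in% names(x)) x$strand else "."
  df <- data.frame(x$chrom, as.integer(x$start), as.integer(x$end), nm, sc, st)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*", "", names(x)))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(!is.null(names(genome)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write a binned signal track as bedGraph
#'
#' @param track signal-track tibble (`chrom`, `start`, `end`, `score`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  check_intervals(track, "track")
  df <- data.frame(track$chrom, as.integer(track$start),
                   as.integer(track$end), track$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path.
#' @param label optional track label stored in the `label` attribute.
#' @return Signal-track tibble with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path, label = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- tibble(chrom = as.character(raw[[1]]), start = as.numeric(raw[[2]]),
                end = as.numeric(raw[[3]]), score = as.numeric(raw[[4]]))
  if (!is.null(label)) attr(out, "label") <- label
  out
}
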