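#' Pool assigned reads into per-repeat-class counts
#'
#' Reads from repeats belonging to the same class are pooled: a read
#' overlapping one or more TE copies increments the classes it touches,
#' a read overlapping copies of `k > 1` distinct classes contributing
#' weight `1/k` to each (`multi = "fractional"`, the default) or being
#' set aside in an `"ambiguous"` row (`multi = "drop"`).  Reads touching
#' no annotated copy are tallied as `"unassigned"`, so class counts plus
#' `unassigned` (plus `ambiguous`) always conserve the read total.
#'
#' @param assigned assigned-read interval tibble, optionally with a
#'   `sample` column (one count column is emitted per sample).
#' @param te_copies TE-copy tibble.
#' @param by column of `te_copies` defining the pooled classes (default
#'   `"te_class"`).
#' @param multi policy for reads spanning several classes:
#'   `"fractional"` or `"drop"`.
#' @param min_overlap minimum shared bp for an overlap.
#' @return A count tibble: `feature` column (class names, `unassigned`,
#'   and `ambiguous` under `multi = "drop"`) plus one numeric column per
#'   sample (named `count` when there is no `sample` column).
#' @export
pool_repeat_counts <- function(assigned, te_copies, by = "te_class",
                               multi = c("fractional", "drop"),
                               min_overlap = 1) {
  multi <- match.arg(multi)
  check_intervals(te_copies, "te_copies")
  stopifnot(by %in% names(te_copies))
  classes <- sort(unique(te_copies[[by]]))
  samples <- if ("sample" %in% names(assigned)) {
    sort(unique(assigned$sample))
  } else "count"
  features <- c(classes, "unassigned", if (multi == "drop") "ambiguous")
  out <- tibble(feature = features)
  for (s in samples) out[[s]] <- 0
  if (nrow(assigned) > 0) {
    check_intervals(assigned, "assigned")
    smp <- if ("sample" %in% names(assigned)) {
      assigned$sample
    } else {
      rep("count", nrow(assigned))
    }
    lv <- union(assigned$chrom, te_copies$chrom)
    hits <- GenomicRanges::findOverlaps(as_gr(assigned, lv),
                                        as_gr(te_copies, lv),
                                        minoverlap = min_overlap,
                                        ignore.strand = TRUE)
    per_read <- distinct(tibble(
      read = S4Vectors::queryHits(hits),
      class = te_copies[[by]][S4Vectors::subjectHits(hits)]
    ))
    k <- table(factor(per_read$read, levels = seq_len(nrow(assigned))))
    k <- as.numeric(k)
    for (s in samples) {
      in_s <- which(smp == s)
      tot <- numeric(length(features))
      names(tot) <- features
      tot["unassigned"] <- sum(k[in_s] == 0)
      pr <- per_read[per_read$read %in% in_s, , drop = FALSE]
      if (nrow(pr) > 0) {
        kk <- k[pr$read]
        if (multi == "fractional") {
          add <- tapply(1 / kk, pr$class, sum)
        } else {
          tot["ambiguous"] <- sum(k[in_s] > 1)
          keep <- kk == 1
          add <- tapply(rep(1, sum(keep)), pr$class[keep], sum)
        }
        add <- add[!is.na(add)]
        tot[names(add)] <- tot[names(add)] + add
      }
      out[[s]] <- as.numeric(tot[features])
    }
  }
  out
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalisation: each sample's factor is the median,
#' over features with all-positive counts, of that sample's count
#' divided by the feature's geometric mean across samples.  Dividing
#' counts by the factors makes samples comparable without assuming equal
#' library composition.
#'
#' @param counts a count tibble whose first character column names the
#'   features and whose numeric columns are samples, or a numeric
#'   matrix.
#' @return Named numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- count_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  logs <- log(m)
  loggeo <- rowMeans(logs)
  use <- is.finite(loggeo)
  if (!any(use)) {
    abort("no feature has positive counts in every sample; consider pseudo-counts")
  }
  apply(logs, 2, function(col) exp(median(col[use] - loggeo[use])))
}

#' Divide a count table by per-sample size factors
#'
#' @param counts count tibble or matrix (see [size_factors()]).
#' @param factors size factors; computed from `counts` when omitted.
#' @return The table with each sample column divided by its factor.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  if (is.matrix(counts)) return(sweep(counts, 2, factors, "/"))
  num <- names(counts)[vapply(counts, is.numeric, logical(1))]
  stopifnot(setequal(num, names(factors)) || length(num) == length(factors))
  if (is.null(names(factors))) names(factors) <- num
  for (s in num) counts[[s]] <- counts[[s]] / factors[[s]]
  counts
}

count_matrix <- function(counts) {
  if (is.matrix(counts)) return(counts)
  num <- vapply(counts, is.numeric, logical(1))
  m <- as.matrix(counts[, num, drop = FALSE])
  chr <- which(!num)
  if (length(chr) > 0) rownames(m) <- counts[[chr[1]]]
  m
}

#' Read / write a promoter-interaction table
#'
#' The package's interaction dialect is a 10-column TSV with 0-based
#' half-open coordinates: promoter (`bait`) `chrom`, `start`, `end`,
#' `gene_id`; other end `chrom`, `start`, `end`; `score`; and two
#' reserved columns.  [read_bedpe_interactions()] converts a generic
#' 7-column BED-pair (`chrom1 start1 end1 chrom2 start2 end2 name`)
#' where the name carries the gene id.
#'
#' @param path file path.
#' @return Interaction tibble (`bait_chrom`, `bait_start`, `bait_end`,
#'   `gene_id`, `oe_chrom`, `oe_start`, `oe_end`, `score`).
#' @export
read_interactions <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 8) abort("interaction files need at least 8 columns")
  tibble(bait_chrom = as.character(raw[[1]]), bait_start = as.numeric(raw[[2]]),
         bait_end = as.numeric(raw[[3]]), gene_id = as.character(raw[[4]]),
         oe_chrom = as.character(raw[[5]]), oe_start = as.numeric(raw[[6]]),
         oe_end = as.numeric(raw[[7]]), score = as.numeric(raw[[8]]))
}

#' @rdname read_interactions
#' @param interactions interaction tibble.
#' @export
write_interactions <- function(interactions, path) {
  df <- data.frame(interactions$bait_chrom, as.integer(interactions$bait_start),
                   as.integer(interactions$bait_end), interactions$gene_id,
                   interactions$oe_chrom, as.integer(interactions$oe_start),
                   as.integer(interactions$oe_end), interactions$score,
                   ".", ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname read_interactions
#' @export
read_bedpe_interactions <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 7) abort("BED-pair files need at least 7 columns")
  tibble(bait_chrom = as.character(raw[[1]]), bait_start = as.numeric(raw[[2]]),
         bait_end = as.numeric(raw[[3]]), gene_id = as.character(raw[[7]]),
         oe_chrom = as.character(raw[[4]]), oe_start = as.numeric(raw[[5]]),
         oe_end = as.numeric(raw[[6]]), score = NA_real_)
}

#' Link TE copies to genes through promoter interactions
#'
#' A copy is linked to gene `g` when it overlaps the "other end" of an
#' interaction whose promoter (bait) belongs to `g` — the interval-join
#' reading of capture Hi-C interaction lists.  Deterministic; adding
#' interaction pairs can only add links.
#'
#' @param interactions interaction tibble (see [read_interactions()]).
#' @param copies TE-copy tibble.
#' @param min_overlap minimum shared bp for an overlap.
#' @return Tibble (`copy_id` = row of `copies`, `gene_id`), one row per
#'   distinct link.
#' @export
link_tes_to_genes <- function(interactions, copies, min_overlap = 1) {
  check_intervals(copies, "copies")
  if (nrow(interactions) == 0 || nrow(copies) == 0) {
    return(tibble(copy_id = integer(), gene_id = character()))
  }
  oe <- tibble(chrom = interactions$oe_chrom, start = interactions$oe_start,
               end = interactions$oe_end)
  lv <- union(copies$chrom, oe$chrom)
  hits <- GenomicRanges::findOverlaps(as_gr(copies, lv), as_gr(oe, lv),
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  arrange(distinct(tibble(
    copy_id = S4Vectors::queryHits(hits),
    gene_id = interactions$gene_id[S4Vectors::subjectHits(hits)]
  )), .data$copy_id, .data$gene_id)
}

#' Compare expression of two linked gene sets
#'
#' Fig.-2-style comparison of normalised expression between genes linked
#' to one TE group (e.g. NOS-bound copies) and genes linked to another.
#' Genes appearing in both sets are, by default, kept in `genes_a` and
#' removed from `genes_b` (`overlap = "a_wins"`); `overlap =
#' "exclusive"` drops shared genes from both sets.
#'
#' @param expression tibble with `gene_id` and one numeric expression
#'   column (`value_col`), typically normalised counts averaged over
#'   samples.
#' @param genes_a,genes_b character vectors of gene ids.
#' @param value_col name of the expression column (default: the first
#'   numeric column).
#' @param test `"t"` (default, Welch) or `"wilcoxon"`; see
#'   [compare_groups()].
#' @param overlap `"a_wins"` or `"exclusive"` handling of shared genes.
#' @return One-row tibble from [compare_groups()].
#' @export
grouped_expression_compare <- function(expression, genes_a, genes_b,
                                       value_col = NULL,
                                       test = c("t", "wilcoxon"),
                                       overlap = c("a_wins", "exclusive")) {
  test <- match.arg(test)
  overlap <- match.arg(overlap)
  stopifnot("gene_id" %in% names(expression))
  if (is.null(value_col)) {
    value_col <- names(expression)[vapply(expression, is.numeric, logical(1))][1]
  }
  shared <- intersect(genes_a, genes_b)
  if (overlap == "a_wins") {
    genes_b <- setdiff(genes_b, shared)
  } else {
    genes_a <- setdiff(genes_a, shared)
    genes_b <- setdiff(genes_b, shared)
  }
  va <- expression[[value_col]][expression$gene_id %in% genes_a]
  vb <- expression[[value_col]][expression$gene_id %in% genes_b]
  if (length(va) == 0 || length(vb) == 0) {
    abort("both gene groups must be non-empty after overlap handling")
  }
  compare_groups(va, vb, test = test)
}
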