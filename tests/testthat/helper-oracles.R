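# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain loops and closed forms only.

bf_overlap_count <- function(queries, targets, min_overlap = 1) {
  if (nrow(queries) == 0) return(0L)
  hit <- logical(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    ov <- pmin(queries$end[i], targets$end) -
      pmax(queries$start[i], targets$start)
    hit[i] <- any(targets$chrom == queries$chrom[i] & ov >= min_overlap)
  }
  sum(hit)
}

# step-up BH as a literal "minimum over the tail" evaluation
bf_bh <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    cand <- p[p >= pi]
    min(1, min(vapply(cand, function(t) t * m / sum(p <= t), numeric(1))))
  }, numeric(1))
}

# exact two-sided rank-sum p by full enumeration of label assignments
bf_ranksum_p <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  sums <- combn(r, na, sum)
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

bf_size_factors <- function(mat) {
  geo <- apply(mat, 1, function(x) prod(x)^(1 / length(x)))
  ok <- apply(mat, 1, function(x) all(x > 0))
  # median taken in log space (geometric interpolation between the two
  # central ratios when the count is even), the DESeq convention
  apply(mat, 2, function(col) exp(median(log((col / geo)[ok]))))
}

bf_aggregate <- function(sites, regions, level, weight) {
  out <- rep(NA_real_, nrow(regions))
  for (r in seq_len(nrow(regions))) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(sites))) {
      if (sites$chrom[i] == regions$chrom[r] &&
          sites$pos[i] >= regions$start[r] && sites$pos[i] < regions$end[r]) {
        num <- num + sites[[level]][i] * sites[[weight]][i]
        den <- den + sites[[weight]][i]
      }
    }
    if (den > 0) out[r] <- num / den
  }
  out
}

bf_pool <- function(assigned, copies, by) {
  classes <- sort(unique(copies[[by]]))
  tot <- setNames(numeric(length(classes) + 1), c(classes, "unassigned"))
  for (i in seq_len(nrow(assigned))) {
    touched <- character(0)
    for (j in seq_len(nrow(copies))) {
      if (assigned$chrom[i] == copies$chrom[j] &&
          min(assigned$end[i], copies$end[j]) >
          max(assigned$start[i], copies$start[j])) {
        touched <- union(touched, copies[[by]][j])
      }
    }
    if (length(touched) == 0) {
      tot["unassigned"] <- tot["unassigned"] + 1
    } else {
      for (cl in touched) tot[cl] <- tot[cl] + 1 / length(touched)
    }
  }
  tot
}

bf_link <- function(interactions, copies) {
  out <- NULL
  for (i in seq_len(nrow(copies))) {
    for (j in seq_len(nrow(interactions))) {
      if (copies$chrom[i] == interactions$oe_chrom[j] &&
          min(copies$end[i], interactions$oe_end[j]) >
          max(copies$start[i], interactions$oe_start[j])) {
        out <- rbind(out, data.frame(copy_id = i,
                                     gene_id = interactions$gene_id[j]))
      }
    }
  }
  if (is.null(out)) return(tibble::tibble(copy_id = integer(),
                                          gene_id = character()))
  tibble::as_tibble(unique(out[order(out$copy_id, out$gene_id), ]))
}

# random interval tibble on a toy chromosome set
rand_intervals <- function(n, chroms = "chr1", max_pos = 10000,
                           max_len = 300) {
  start <- floor(runif(n) * (max_pos - max_len))
  len <- 1 + floor(runif(n) * max_len)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len, strand = ".")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small shared simulated genome (built once per test run)
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fams <- tibble::tibble(
        name = c("L1y", "L1o", "RLTR1", "B1"),
        te_class = c("LINE", "LINE", "LTR", "SINE"),
        consensus_length = c(3000, 3000, 500, 150),
        n_copies = c(12, 12, 30, 60),
        divergence = c(1, 12, 5, 8),
        p_truncated = c(0.4, 0.5, 0, 0))
      cache <<- simulate_genome(sim_config(seed = 404, genome_length = 4e5,
                                           te_families = fams))
    }
    cache
  }
})
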