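test_that("genome simulation is a pure function of config and seed", {
  cfg <- sim_config(seed = 91, genome_length = 1e5,
                    te_families = tibble::tibble(
                      name = c("A", "B"), te_class = c("LINE", "LTR"),
                      consensus_length = c(2000, 400), n_copies = c(5, 10),
                      divergence = c(0, 5), p_truncated = c(0.5, 0)))
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$te_copies, s2$te_copies)
  s3 <- simulate_genome(sim_config(seed = 92, genome_length = 1e5,
                                   te_families = cfg$te_families))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("zero divergence and truncation reproduce the consensus exactly", {
  cfg <- sim_config(seed = 93, genome_length = 1e5,
                    te_families = tibble::tibble(
                      name = "A", te_class = "LINE", consensus_length = 1500,
                      n_copies = 8, divergence = 0, p_truncated = 0))
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$te_copies), 8)
  for (i in seq_len(8)) {
    cp <- sim$te_copies[i, ]
    s <- substring(sim$genome["chr1"], cp$start + 1, cp$end)
    if (cp$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_equal(unname(s), unname(sim$consensi["A"]))
  }
})

test_that("realised divergence tracks the configured rate", {
  cfg <- sim_config(seed = 94, genome_length = 8e5,
                    te_families = tibble::tibble(
                      name = "A", te_class = "LINE", consensus_length = 2000,
                      n_copies = 60, divergence = 8, p_truncated = 0))
  sim <- simulate_genome(cfg)
  cons <- strsplit(unname(sim$consensi["A"]), "")[[1]]
  mm <- vapply(seq_len(nrow(sim$te_copies)), function(i) {
    cp <- sim$te_copies[i, ]
    s <- substring(sim$genome["chr1"], cp$start + 1, cp$end)
    if (cp$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    mean(strsplit(s, "")[[1]] != cons)
  }, numeric(1))
  expect_lt(abs(mean(mm) * 100 - 8), 1)
})

test_that("truncation creates a length dichotomy and over-dense configs fail", {
  sim <- shared_sim()
  l1y <- sim$te_copies[sim$te_copies$family == "L1y", ]
  expect_true(all(l1y$full_length == (l1y$end - l1y$start > 5000)))
  expect_true(any(l1y$truncated_bp > 0))
  expect_error(simulate_genome(sim_config(seed = 1, genome_length = 1e4,
    te_families = tibble::tibble(name = "A", te_class = "LINE",
      consensus_length = 3000, n_copies = 10, divergence = 0,
      p_truncated = 0))), "80%")
})

test_that("the chemistry matrix evaluates to the stated read-as-C rates", {
  ideal <- list(conversion = 1, fail = c(BS = 0, oxBS = 0, TAB = 0))
  expect_equal(read_as_c_prob(ideal, 0.6, 0.2, "BS"), 0.8)
  expect_equal(read_as_c_prob(ideal, 0.6, 0.2, "oxBS"), 0.6)
  expect_equal(read_as_c_prob(ideal, 0.6, 0.2, "TAB"), 0.2)
  leaky <- list(conversion = 0.99, fail = c(BS = 0, oxBS = 0, TAB = 0))
  expect_equal(read_as_c_prob(leaky, 0, 0, "BS"), 0.01)
  expect_equal(read_as_c_prob(leaky, 0, 0, "oxBS"), 0.01)
  expect_error(read_as_c_prob(ideal, 0.8, 0.4, "BS"), "exceeds 1")
  expect_error(read_as_c_prob(ideal, 0.5, 0.2, "BS-seq"), "unknown chemistry")
})

test_that("bisulfite simulation covers genome CpGs with model levels", {
  sim <- shared_sim()
  out <- simulate_bisulfite(sim, region = interval_tbl("chr1", 0, 50000),
                            seed = 95)
  expect_setequal(names(out$counts), c("BS", "oxBS", "TAB"))
  tr <- out$truth
  expect_true(all(substring(sim$genome["chr1"], tr$pos + 1, tr$pos + 2) == "CG"))
  bg <- is.na(tr$family)
  expect_true(all(tr$p_5mC[bg] == 0.75))
  expect_true(all(out$counts$BS$n_unconverted <= out$counts$BS$n_reads))
  out2 <- simulate_bisulfite(sim, region = interval_tbl("chr1", 0, 50000),
                             seed = 95)
  expect_identical(out$counts, out2$counts)
})

test_that("end-to-end recovery of planted methylation through the chemistry", {
  truth <- tibble::tibble(chrom = "amp", pos = seq(0, 2 * 199, 2),
                          p_5mC = 0.6, p_5hmC = 0.2)
  ideal <- list(conversion = 1, fail = c(BS = 0, oxBS = 0, TAB = 0))
  cc <- simulate_cpg_counts(truth, ideal, mean_depth = 1000, seed = 96)
  est <- estimate_from_bs_oxbs(cc$BS, cc$oxBS)
  expect_lt(abs(mean(est$level_5mC) - 0.6), 0.01)
  expect_lt(abs(mean(est$level_5hmC) - 0.2), 0.01)
  tab <- estimate_from_tab(cc$TAB)
  expect_lt(abs(mean(tab$level_5hmC) - 0.2), 0.01)
})

test_that("chip simulation honours per-family binding probabilities", {
  sim <- shared_sim()
  chip <- simulate_chip(sim, p_bound = c(L1y = 1, L1o = 0), n_background = 0,
                        seed = 97)
  tr <- chip$truth
  expect_true(all(tr$bound[tr$family == "L1y"]))
  expect_false(any(tr$bound[tr$family == "L1o"]))
  expect_equal(nrow(chip$peaks_ambiguous), sum(tr$bound))
  expect_true(nrow(chip$peaks_unique) <= nrow(chip$peaks_ambiguous))
  # every planted peak overlaps its origin copy
  ov <- flag_overlaps(chip$peaks_ambiguous, sim$te_copies)
  expect_true(all(ov$hit))
  # determinism
  chip2 <- simulate_chip(sim, p_bound = c(L1y = 1, L1o = 0), n_background = 0,
                         seed = 97)
  expect_identical(chip$peaks_ambiguous, chip2$peaks_ambiguous)
})

test_that("a null binding model yields folds near 1", {
  sim <- shared_sim()
  chip <- simulate_chip(sim, p_bound = c(L1y = 0, L1o = 0, RLTR1 = 0, B1 = 0),
                        n_background = 60, seed = 98)
  et <- enrichment_test(chip$peaks_ambiguous, sim$te_copies, sim$chrom_sizes,
                        n_reps = 300, seed = 99)
  expect_true(all(tidy(et)$q_value > 0.05 | abs(tidy(et)$fold - 1) < 0.9,
                  na.rm = TRUE))
})

test_that("simulated reads carry multi-hits exactly at duplicated sequence", {
  set.seed(100)
  blk <- random_seq(600)
  g <- c(chr1 = paste0(random_seq(1000), blk, random_seq(300), blk,
                       random_seq(1000)))
  rr <- simulate_reads(g, 500, 50, seed = 101)
  expect_equal(nrow(rr$truth), 500)
  # every read has at least its true origin among the hits
  j <- dplyr::inner_join(rr$truth, rr$hits,
                         by = c("read_id", "chrom", "start"))
  expect_equal(nrow(j), 500)
  n_hits <- table(rr$hits$read_id)
  dup_origin <- rr$truth$read_id[
    (rr$truth$start >= 1000 & rr$truth$start <= 1550) |
      (rr$truth$start >= 1900 & rr$truth$start <= 2450)]
  expect_true(all(n_hits[dup_origin] >= 2))
})

test_that("interaction/count simulation plants a clean expression contrast", {
  sim <- shared_sim()
  bound <- sim$te_copies$copy_id[sim$te_copies$family == "L1y"]
  out <- simulate_interactions_and_counts(sim, bound, n_genes = 100,
                                          frac_linked = 0.8, fold = 4,
                                          seed = 102)
  expect_true(all(c("nos_pos", "nos_neg") %in% out$truth$group))
  links <- link_tes_to_genes(out$interactions, sim$te_copies)
  expect_gt(nrow(links), 0)
  pos_genes <- out$truth$gene_id[out$truth$group == "nos_pos"]
  neg_genes <- out$truth$gene_id[out$truth$group == "nos_neg"]
  norm <- normalize_counts(out$counts)
  expr <- tibble::tibble(gene_id = norm$gene_id,
                         value = rowMeans(norm[, -1]))
  cmp <- grouped_expression_compare(expr, pos_genes, neg_genes)
  expect_lt(cmp$p_value, 0.05)
  expect_gt(cmp$mean_a, cmp$mean_b)
  out2 <- simulate_interactions_and_counts(sim, bound, n_genes = 100,
                                           frac_linked = 0.8, fold = 4,
                                           seed = 102)
  expect_identical(out$counts, out2$counts)
})

test_that("target-fold mode reports its exact planting parameters", {
  sim <- shared_sim()
  chip <- simulate_chip(sim, fold = 2.5, fold_class = "LTR", n_peaks = 300,
                        peak_width = 200, seed = 103)
  expect_equal(chip$truth$planted_fold, 2.5)
  expect_true(chip$truth$p_null > 0 && chip$truth$p_null < 1)
  expect_equal(nrow(chip$peaks), 300)
  expect_error(simulate_chip(sim, fold = 100, fold_class = "LTR",
                             n_peaks = 10, seed = 1), "not attainable")
})
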