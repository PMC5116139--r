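#' Simulation configuration
#'
#' Builds the configuration driving every simulator in the package.  The
#' defaults describe a desk-scale caricature of a mouse ESC genome: a
#' 2 Mb i.i.d. background carrying four TE families — a young, lowly
#' diverged full-length-capable LINE-1 family, an old heavily diverged
#' LINE-1 family, a short LTR family and a SINE family — with 5'
#' truncation so that full-length and fragmentary copies coexist.
#'
#' @param seed mandatory integer seed; every simulator is a pure
#'   function of (config, seed).
#' @param genome_length background genome length in bp (default 2e6).
#' @param te_families tibble with columns `name`, `te_class`,
#'   `consensus_length`, `n_copies`, `divergence` (% substitutions from
#'   consensus), `p_truncated` (probability a copy is 5'-truncated).
#' @param chemistry list with `conversion` (probability an unmodified C
#'   reads as T) and `fail` (named per-chemistry probabilities that a
#'   protected base nonetheless reads as T).
#' @param mean_depth mean per-CpG read depth for bisulfite simulations.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       genome_length = 2e6,
                       te_families = default_te_families(),
                       chemistry = default_chemistry(),
                       mean_depth = 100) {
  stopifnot(is.numeric(seed), length(seed) == 1, genome_length >= 1000)
  need <- c("name", "te_class", "consensus_length", "n_copies",
            "divergence", "p_truncated")
  stopifnot(all(need %in% names(te_families)))
  stopifnot(all(te_families$divergence >= 0),
            all(te_families$n_copies >= 0),
            all(te_families$p_truncated >= 0 & te_families$p_truncated <= 1))
  stopifnot(chemistry$conversion >= 0, chemistry$conversion <= 1,
            all(chemistry$fail >= 0 & chemistry$fail <= 1))
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 te_families = te_families, chemistry = chemistry,
                 mean_depth = mean_depth),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_te_families <- function() {
  tibble(
    name = c("L1Md_T", "L1Md_F", "RLTR13D6", "B1_Mm"),
    te_class = c("LINE", "LINE", "LTR", "SINE"),
    consensus_length = c(6200, 6200, 600, 150),
    n_copies = c(40, 40, 100, 200),
    divergence = c(1, 12, 5, 8),
    p_truncated = c(0.5, 0.7, 0, 0)
  )
}

#' @rdname sim_config
#' @export
default_chemistry <- function() {
  list(conversion = 0.995,
       fail = c(BS = 0.005, oxBS = 0.005, TAB = 0.03))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base substitution at rate `div` percent, never to the same base
mutate_seq <- function(seq, div) {
  if (div <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < div / 100)
  if (length(hit) > 0) {
    alt <- c("A", "C", "G", "T")
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1), "")
  }
  paste(ch, collapse = "")
}

#' Simulate a genome with planted TE copies
#'
#' Generates an i.i.d. background sequence and inserts TE copies at
#' uniform random non-overlapping positions.  Each copy is derived from
#' its family's (simulated) consensus by per-base substitution at the
#' family divergence rate, 5' truncation drawn from a geometric
#' start-offset distribution (mean half the consensus) with the family's
#' truncation probability, and a random strand (minus-strand copies are
#' inserted reverse-complemented).  The returned truth table doubles as
#' the RepeatMasker-style annotation.
#'
#' @param config a [sim_config()].
#' @return A `te_sim` list: `genome` (named character), `chrom_sizes`,
#'   `te_copies` (truth tibble with `copy_id`, coordinates, family,
#'   class, divergence, `truncated_bp`, `full_length`), `consensi`
#'   (named character of family consensus sequences) and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fams <- config$te_families
  G <- config$genome_length
  if (sum(fams$consensus_length * fams$n_copies) > 0.8 * G) {
    abort("requested TE bp exceed 80% of the genome length")
  }
  withr::with_seed(config$seed, {
    consensi <- setNames(
      vapply(fams$consensus_length, random_dna, ""), fams$name)
    plan <- purrr::pmap_dfr(fams, function(name, te_class, consensus_length,
                                           n_copies, divergence, p_truncated) {
      if (n_copies == 0) return(NULL)
      trunc <- ifelse(runif(n_copies) < p_truncated,
                      pmin(rgeom(n_copies, 1 / (consensus_length / 2)),
                           consensus_length - 200L),
                      0L)
      tibble(repeat_name = name, family = name, te_class = te_class,
             divergence = divergence, truncated_bp = as.numeric(trunc),
             len = consensus_length - trunc)
    })
    plan <- arrange(plan, desc(.data$len))
    # rejection-sample non-overlapping placements, longest first
    placed <- IRanges::IRanges()
    starts <- numeric(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      L <- plan$len[i]
      ok <- FALSE
      for (try in 1:500) {
        s <- floor(runif(1) * (G - L + 1))
        cand <- IRanges::IRanges(s + 1, s + L)
        if (length(placed) == 0 ||
            !any(IRanges::overlapsAny(cand, placed))) {
          placed <- c(placed, cand)
          starts[i] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not place all TE copies without overlap; lower copy numbers")
    }
    plan$start <- starts
    plan$strand <- ifelse(runif(nrow(plan)) < 0.5, "+", "-")
    genome_ch <- sample(c("A", "C", "G", "T"), G, replace = TRUE)
    seqs <- character(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      cons <- consensi[[plan$repeat_name[i]]]
      s <- substring(cons, plan$truncated_bp[i] + 1, nchar(cons))
      s <- mutate_seq(s, plan$divergence[i])
      if (plan$strand[i] == "-") s <- revcomp(s)
      seqs[i] <- s
      genome_ch[(plan$start[i] + 1):(plan$start[i] + plan$len[i])] <-
        strsplit(s, "", fixed = TRUE)[[1]]
    }
    copies <- tibble(
      chrom = "chr1", start = plan$start, end = plan$start + plan$len,
      strand = plan$strand, repeat_name = plan$repeat_name,
      family = plan$family, te_class = plan$te_class,
      divergence = plan$divergence, truncated_bp = plan$truncated_bp
    )
    copies <- classify_full_length(arrange(copies, .data$chrom, .data$start))
    copies <- mutate(copies, copy_id = row_number(), .before = 1)
    structure(
      list(genome = c(chr1 = paste(genome_ch, collapse = "")),
           chrom_sizes = c(chr1 = G),
           te_copies = copies, consensi = consensi, config = config),
      class = "te_sim")
  })
}

#' @export
print.te_sim <- function(x, ...) {
  cat(sprintf("Simulated genome: %d bp, %d TE copies in %d families (seed %d)\n",
              sum(nchar(x$genome)), nrow(x$te_copies),
              length(unique(x$te_copies$family)), x$config$seed))
  invisible(x)
}

#' Simulate ChIP peaks over a simulated genome
#'
#' Two planting modes:
#'
#' * **per-copy binding** (`p_bound` given): each copy of family `f` is
#'   bound with probability `p_bound[f]`; bound copies receive one peak
#'   centred in the copy's 5' window (`pref`, as fractions of copy
#'   length, strand-aware).  Each planted peak enters the inclusive
#'   ("ambiguous") peak set; it also enters the unique peak set with
#'   probability `p_unique` — by default `min(1, divergence / 10)`, so
#'   peaks at young, near-identical copies are mostly lost to unique
#'   mapping while old diverged copies keep theirs, the mappability
#'   pattern the two policies are designed to expose.
#' * **target fold** (`fold` and `fold_class` given): `n_peaks` peaks of
#'   width `peak_width` are placed so that the expected observed /
#'   expected overlap ratio with `fold_class` equals `fold` exactly:
#'   with probability `q = p0 (fold - 1) / (1 - p0)` a peak is placed
#'   uniformly among all placements overlapping the class (whose null
#'   probability `p0` is computed by exact placement counting), and
#'   uniformly anywhere otherwise.
#'
#' @param sim a `te_sim` from [simulate_genome()].
#' @param p_bound named vector of per-family binding probabilities.
#' @param peak_width peak width in bp (default 300).
#' @param pref 5'-preference window as fractions of copy length
#'   (default `c(0, 0.3)`).
#' @param n_background number of background peaks placed uniformly
#'   (present in both peak sets; default 50).
#' @param p_unique probability a planted peak survives unique mapping;
#'   default the divergence rule above.
#' @param fold,fold_class target fold mode (see above).
#' @param n_peaks number of peaks in target-fold mode.
#' @param by class column used by target-fold mode.
#' @param seed integer seed.
#' @return Per-copy mode: list with `peaks_unique`, `peaks_ambiguous`
#'   (interval tibbles with `origin_copy` and `mode`) and `truth`
#'   (copies with `bound`, `in_unique`).  Target-fold mode: list with
#'   `peaks` plus attributes `planted_fold` and `p_null` in `truth`.
#' @export
simulate_chip <- function(sim, p_bound = NULL, peak_width = 300,
                          pref = c(0, 0.3), n_background = 50,
                          p_unique = NULL, fold = NULL, fold_class = NULL,
                          n_peaks = 200, by = "te_class", seed) {
  stopifnot(inherits(sim, "te_sim"))
  if (is.null(p_bound) == is.null(fold)) {
    abort("supply exactly one of `p_bound` (per-copy mode) or `fold` (target-fold mode)")
  }
  G <- unname(sim$chrom_sizes["chr1"])
  withr::with_seed(as.integer(seed), {
    if (!is.null(fold)) {
      return(simulate_chip_fold(sim, fold, fold_class, n_peaks, peak_width,
                                by, G))
    }
    copies <- sim$te_copies
    stopifnot(!is.null(names(p_bound)),
              all(names(p_bound) %in% copies$family))
    cop <- filter(copies, .data$family %in% names(p_bound))
    bound <- runif(nrow(cop)) < p_bound[cop$family]
    pu <- if (is.null(p_unique)) pmin(1, cop$divergence / 10) else
      rep(p_unique, length.out = nrow(cop))
    in_unique <- bound & (runif(nrow(cop)) < pu)
    len <- cop$end - cop$start
    u <- pref[1] + runif(nrow(cop)) * (pref[2] - pref[1])
    centre <- ifelse(cop$strand == "-",
                     cop$end - u * len, cop$start + u * len)
    pk_start <- pmax(0, pmin(round(centre - peak_width / 2), G - peak_width))
    planted <- tibble(chrom = "chr1", start = pk_start,
                      end = pk_start + peak_width, strand = ".",
                      origin_copy = cop$copy_id)[bound, , drop = FALSE]
    bg_start <- floor(runif(n_background) * (G - peak_width + 1))
    background <- tibble(chrom = character(0), start = numeric(0),
                         end = numeric(0), strand = character(0),
                         origin_copy = integer(0))
    if (n_background > 0) {
      background <- tibble(chrom = "chr1", start = bg_start,
                           end = bg_start + peak_width, strand = ".",
                           origin_copy = NA_integer_)
    }
    truth <- mutate(cop, bound = bound, in_unique = in_unique)
    list(
      peaks_ambiguous = mutate(bind_rows(planted, background),
                               mode = "inclusive"),
      peaks_unique = mutate(bind_rows(planted[in_unique[bound], , drop = FALSE],
                                      background), mode = "unique"),
      truth = truth
    )
  })
}

simulate_chip_fold <- function(sim, fold, fold_class, n_peaks, peak_width,
                               by, G) {
  stopifnot(!is.null(fold_class), fold >= 1)
  copies <- sim$te_copies
  stopifnot(by %in% names(copies), fold_class %in% copies[[by]])
  cls <- filter(copies, .data[[by]] == fold_class)
  L <- peak_width
  n_valid <- G - L + 1
  # starts whose peak [s, s+L) overlaps >= 1 class copy
  ov <- IRanges::reduce(IRanges::IRanges(
    start = pmax(1, cls$start - L + 2), end = pmin(n_valid, cls$end)))
  p0 <- sum(IRanges::width(ov)) / n_valid
  q <- p0 * (fold - 1) / (1 - p0)
  if (q > 1) abort(sprintf("fold %.2f not attainable (max %.2f)", fold, 1 / p0 ))
  in_class <- runif(n_peaks) < q
  w <- IRanges::width(ov)
  blk <- sample.int(length(ov), n_peaks, replace = TRUE, prob = w)
  s_class <- IRanges::start(ov)[blk] - 1 + floor(runif(n_peaks) * w[blk])
  s_unif <- floor(runif(n_peaks) * n_valid)
  s <- ifelse(in_class, s_class, s_unif)
  list(
    peaks = tibble(chrom = "chr1", start = s, end = s + L, strand = ".",
                   planted = in_class),
    truth = tibble(planted_fold = fold, p_null = p0, q = q,
                   n_peaks = n_peaks, fold_class = fold_class)
  )
}

#' Simulate reads with exact-match multi-hit discovery
#'
#' Draws fixed-length reads from the forward strand of the genome —
#' uniformly, or uniformly within supplied origin regions — and then
#' finds *every* exact occurrence of each read sequence in the genome
#' and its reverse complement.  Reads originating in duplicated or
#' near-identical sequence therefore come back with several tied-best
#' hits, a transparent stand-in for aligner ambiguity at repeats
#' (default edit distance 0).
#'
#' @param genome named character vector of chromosome sequences.
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param origins optional interval tibble restricting read start
#'   positions (reads start uniformly inside the origins).
#' @param seed integer seed.
#' @return List with `truth` (`read_id`, `chrom`, `start` of the true
#'   origin) and `hits` (hit table for [filter_unique()] /
#'   [assign_inclusive()]; all hits carry equal `score`).
#' @export
simulate_reads <- function(genome, n_reads, read_length = 50,
                           origins = NULL, seed) {
  genome <- as_genome_chr(genome)
  withr::with_seed(as.integer(seed), {
    if (is.null(origins)) {
      origins <- tibble(chrom = names(genome), start = 0,
                        end = nchar(genome))
    }
    avail <- pmax(0, (origins$end - origins$start) - read_length + 1)
    if (sum(avail) == 0) abort("no origin region can hold a read")
    oi <- sample.int(nrow(origins), n_reads, replace = TRUE, prob = avail)
    off <- floor(runif(n_reads) * avail[oi])
    truth <- tibble(read_id = sprintf("read_%06d", seq_len(n_reads)),
                    chrom = origins$chrom[oi],
                    start = origins$start[oi] + off)
    seqs <- substring(genome[truth$chrom], truth$start + 1,
                      truth$start + read_length)
    list(truth = mutate(truth, seq = unname(seqs)),
         hits = find_exact_hits(genome, truth$read_id, seqs, read_length))
  })
}

# every exact occurrence of each read on either strand of the genome
find_exact_hits <- function(genome, read_ids, seqs, read_length) {
  reads <- Biostrings::DNAStringSet(unname(seqs))
  pd_f <- Biostrings::PDict(reads)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(reads))
  pieces <- purrr::imap(genome, function(seq, chrom) {
    subj <- Biostrings::DNAString(seq)
    fwd <- Biostrings::matchPDict(pd_f, subj)
    rev <- Biostrings::matchPDict(pd_r, subj)
    n_f <- lengths(fwd); n_r <- lengths(rev)
    tibble(
      read_id = c(rep(read_ids, n_f), rep(read_ids, n_r)),
      chrom = chrom,
      start = c(unlist(lapply(fwd, IRanges::start), use.names = FALSE),
                unlist(lapply(rev, IRanges::start), use.names = FALSE)) - 1,
      strand = c(rep("+", sum(n_f)), rep("-", sum(n_r)))
    )
  })
  hits <- bind_rows(pieces)
  hits$end <- hits$start + read_length
  hits$score <- read_length
  select(hits, "read_id", "chrom", "start", "end", "strand", "score")
}

#' Simulate ChIP reads around peaks
#'
#' A fraction of reads starts inside peaks (peak chosen uniformly, start
#' uniform within it) and the rest uniformly on the genome; multi-hits
#' are discovered by exact matching as in [simulate_reads()].
#'
#' @param sim a `te_sim`.
#' @param peaks interval tibble of peaks.
#' @param n_reads total reads.
#' @param read_length read length in bp.
#' @param frac_signal fraction of reads drawn from peaks.
#' @param seed integer seed.
#' @return As [simulate_reads()], with a `from_peak` flag in `truth`.
#' @export
simulate_chip_reads <- function(sim, peaks, n_reads = 10000,
                                read_length = 50, frac_signal = 0.5, seed) {
  stopifnot(inherits(sim, "te_sim"))
  withr::with_seed(as.integer(seed), {
    n_sig <- rbinom(1, n_reads, frac_signal)
    sub_seed <- sample.int(2^30, 2)
    sig <- if (n_sig > 0) {
      simulate_reads(sim$genome, n_sig, read_length, origins = peaks,
                     seed = sub_seed[1])
    }
    bg <- if (n_reads - n_sig > 0) {
      simulate_reads(sim$genome, n_reads - n_sig, read_length,
                     seed = sub_seed[2])
    }
    fix_ids <- function(x, prefix, flag) {
      if (is.null(x)) return(NULL)
      map <- setNames(paste0(prefix, x$truth$read_id), x$truth$read_id)
      x$truth$read_id <- unname(map[x$truth$read_id])
      x$truth$from_peak <- flag
      x$hits$read_id <- unname(map[x$hits$read_id])
      x
    }
    sig <- fix_ids(sig, "sig_", TRUE)
    bg <- fix_ids(bg, "bg_", FALSE)
    list(truth = bind_rows(sig$truth, bg$truth),
         hits = bind_rows(sig$hits, bg$hits))
  })
}

# read-as-C probability under each conversion chemistry
read_as_c_prob <- function(chemistry, p_5mC, p_5hmC, chem) {
  if (!chem %in% c("BS", "oxBS", "TAB")) {
    abort(sprintf("unknown chemistry '%s'", chem))
  }
  p_c <- 1 - p_5mC - p_5hmC
  if (any(p_c < -1e-9)) abort("p_5mC + p_5hmC exceeds 1 at some site")
  p_c <- pmax(0, p_c)
  conv <- chemistry$conversion
  fail <- chemistry$fail[[chem]]
  switch(chem,
    BS = (p_5mC + p_5hmC) * (1 - fail) + p_c * (1 - conv),
    oxBS = p_5mC * (1 - fail) + (p_c + p_5hmC) * (1 - conv),
    TAB = p_5hmC * (1 - fail) + (p_c + p_5mC) * (1 - conv),
    abort(sprintf("unknown chemistry '%s'", chem))
  )
}

#' Simulate per-CpG bisulfite counts at given true levels
#'
#' The sampling core shared by [simulate_bisulfite()]: per-site read
#' depth is Poisson around `mean_depth` (or exactly `mean_depth` with
#' `fixed_depth = TRUE`) and the unconverted-C count binomial with the
#' chemistry-specific read-as-C probability.
#'
#' @param truth_sites tibble (`chrom`, `pos`, `p_5mC`, `p_5hmC`).
#' @param chemistry chemistry list (see [default_chemistry()]; use
#'   `conversion = 1` and zero failures for ideal chemistry).
#' @param mean_depth mean per-site depth.
#' @param chemistries subset of `c("BS", "oxBS", "TAB")`.
#' @param fixed_depth use `mean_depth` exactly at every site.
#' @param seed integer seed.
#' @return Named list of count tibbles (`chrom`, `pos`, `strand`,
#'   `n_reads`, `n_unconverted`, `chemistry`), one per chemistry.
#' @export
simulate_cpg_counts <- function(truth_sites, chemistry = default_chemistry(),
                                mean_depth = 100,
                                chemistries = c("BS", "oxBS", "TAB"),
                                fixed_depth = FALSE, seed) {
  stopifnot(all(c("chrom", "pos", "p_5mC", "p_5hmC") %in% names(truth_sites)))
  withr::with_seed(as.integer(seed), {
    n <- nrow(truth_sites)
    setNames(lapply(chemistries, function(chem) {
      p <- read_as_c_prob(chemistry, truth_sites$p_5mC, truth_sites$p_5hmC,
                          chem)
      stopifnot(all(p >= 0 & p <= 1))
      depth <- if (fixed_depth) rep(mean_depth, n) else rpois(n, mean_depth)
      tibble(chrom = truth_sites$chrom, pos = truth_sites$pos, strand = "+",
             n_reads = depth, n_unconverted = rbinom(n, depth, p),
             chemistry = chem)
    }), chemistries)
  })
}

#' Simulate genome-wide bisulfite cytosine reports
#'
#' Locates every CpG on the simulated genome (optionally within a
#' region), assigns each a true (5mC, 5hmC) level from the methylome
#' model — per-family levels inside TE copies, background elsewhere —
#' and samples BS/oxBS/TAB counts via [simulate_cpg_counts()].
#'
#' @param sim a `te_sim`.
#' @param methylome_model list with `background = c(level_5mC, level_5hmC)`
#'   and `families` (tibble `family`, `level_5mC`, `level_5hmC`);
#'   default [default_methylome_model()].
#' @param chemistry chemistry list (default: the config's).
#' @param mean_depth mean per-CpG depth (default: the config's).
#' @param chemistries chemistries to emit.
#' @param region optional interval tibble restricting the simulated CpGs
#'   (amplicon mode).
#' @param seed integer seed.
#' @return List with `counts` (named list of per-chemistry tibbles) and
#'   `truth` (per-CpG `chrom`, `pos`, `p_5mC`, `p_5hmC`, `family`).
#' @export
simulate_bisulfite <- function(sim, methylome_model = default_methylome_model(),
                               chemistry = NULL, mean_depth = NULL,
                               chemistries = c("BS", "oxBS", "TAB"),
                               region = NULL, seed) {
  stopifnot(inherits(sim, "te_sim"))
  if (is.null(chemistry)) chemistry <- sim$config$chemistry
  if (is.null(mean_depth)) mean_depth <- sim$config$mean_depth
  sites <- purrr::imap_dfr(sim$genome, function(seq, chrom) {
    m <- Biostrings::matchPattern("CG", Biostrings::DNAString(seq))
    tibble(chrom = chrom, pos = IRanges::start(m) - 1)
  })
  if (!is.null(region)) {
    lv <- union(sites$chrom, region$chrom)
    keep <- IRanges::overlapsAny(
      GenomicRanges::GRanges(factor(sites$chrom, levels = lv),
                             IRanges::IRanges(sites$pos + 1, width = 2)),
      as_gr(region, lv), ignore.strand = TRUE)
    sites <- sites[keep, , drop = FALSE]
  }
  bg <- methylome_model$background
  sites$p_5mC <- unname(bg["level_5mC"])
  sites$p_5hmC <- unname(bg["level_5hmC"])
  sites$family <- NA_character_
  lv <- union(sites$chrom, sim$te_copies$chrom)
  sgr <- GenomicRanges::GRanges(factor(sites$chrom, levels = lv),
                                IRanges::IRanges(sites$pos + 1, width = 1))
  hits <- GenomicRanges::findOverlaps(sgr, as_gr(sim$te_copies, lv),
                                      ignore.strand = TRUE, select = "first")
  inside <- !is.na(hits)
  sites$family[inside] <- sim$te_copies$family[hits[inside]]
  fm <- methylome_model$families
  idx <- match(sites$family, fm$family)
  got <- !is.na(idx)
  sites$p_5mC[got] <- fm$level_5mC[idx[got]]
  sites$p_5hmC[got] <- fm$level_5hmC[idx[got]]
  counts <- simulate_cpg_counts(sites, chemistry = chemistry,
                                mean_depth = mean_depth,
                                chemistries = chemistries, seed = seed)
  list(counts = counts, truth = sites)
}

#' @rdname simulate_bisulfite
#' @export
default_methylome_model <- function() {
  list(
    background = c(level_5mC = 0.75, level_5hmC = 0.05),
    families = tibble(
      family = c("L1Md_T", "L1Md_F", "RLTR13D6", "B1_Mm"),
      level_5mC = c(0.60, 0.85, 0.50, 0.80),
      level_5hmC = c(0.15, 0.02, 0.10, 0.03)
    )
  )
}

#' Simulate promoter interactions and gene expression counts
#'
#' Places gene promoters on the genome, links a configurable fraction of
#' the supplied "NOS-bound" TE copies (and, separately, unbound copies)
#' to genes via capture-Hi-C-style interaction records, and draws
#' negative-binomial gene counts with a fold difference between genes
#' linked to bound copies and all other genes.
#'
#' @param sim a `te_sim`.
#' @param bound_copy_ids `copy_id`s of the NOS/TET-bound copies.
#' @param n_genes number of genes.
#' @param frac_linked fraction of copies (each group) linked to a gene.
#' @param fold expression fold for genes linked to bound copies.
#' @param base_mean negative-binomial mean for unlinked genes.
#' @param nb_size negative-binomial size (dispersion = 1/size).
#' @param n_samples number of expression samples.
#' @param seed integer seed.
#' @return List with `interactions` (see [read_interactions()]),
#'   `counts` (wide count tibble `gene_id` x samples) and `truth`
#'   (`gene_id`, `group` in `nos_pos` / `nos_neg` / `none`).
#' @export
simulate_interactions_and_counts <- function(sim, bound_copy_ids,
                                             n_genes = 200,
                                             frac_linked = 0.6, fold = 2,
                                             base_mean = 100, nb_size = 10,
                                             n_samples = 2, seed) {
  stopifnot(inherits(sim, "te_sim"))
  G <- unname(sim$chrom_sizes["chr1"])
  copies <- sim$te_copies
  withr::with_seed(as.integer(seed), {
    prom_start <- floor(runif(n_genes) * (G - 1000))
    genes <- tibble(gene_id = sprintf("gene_%04d", seq_len(n_genes)),
                    chrom = "chr1", start = prom_start,
                    end = prom_start + 1000)
    pos_ids <- intersect(bound_copy_ids, copies$copy_id)
    neg_ids <- setdiff(copies$copy_id, pos_ids)
    pick <- function(ids) {
      if (length(ids) == 0) return(integer(0))
      ids[runif(length(ids)) < frac_linked]
    }
    link <- function(ids, pool) {
      if (length(ids) == 0) return(NULL)
      g <- sample(pool, length(ids), replace = length(ids) > length(pool))
      cp <- copies[match(ids, copies$copy_id), ]
      tibble(bait_chrom = "chr1",
             bait_start = genes$start[match(g, genes$gene_id)],
             bait_end = genes$end[match(g, genes$gene_id)],
             gene_id = g, oe_chrom = cp$chrom, oe_start = cp$start,
             oe_end = cp$end, score = round(runif(length(ids), 5, 15), 2))
    }
    # disjoint candidate gene pools so the planted groups are clean
    half <- sample(genes$gene_id, floor(n_genes / 2))
    ints <- bind_rows(link(pick(pos_ids), half),
                      link(pick(neg_ids), setdiff(genes$gene_id, half)))
    group <- rep("none", n_genes)
    group[genes$gene_id %in% ints$gene_id[ints$oe_start %in%
            copies$start[match(pos_ids, copies$copy_id)]]] <- "nos_pos"
    linked_neg <- ints$gene_id[!ints$gene_id %in% genes$gene_id[group == "nos_pos"]]
    group[genes$gene_id %in% linked_neg] <- "nos_neg"
    mu <- ifelse(group == "nos_pos", base_mean * fold, base_mean)
    counts <- tibble(gene_id = genes$gene_id)
    for (s in seq_len(n_samples)) {
      counts[[sprintf("sample_%d", s)]] <- rnbinom(n_genes, mu = mu,
                                                   size = nb_size)
    }
    list(interactions = ints, counts = counts,
         truth = tibble(gene_id = genes$gene_id, group = group,
                        promoter_start = genes$start))
  })
}
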