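---
title: "Methods: TE-centric epigenomic analysis with retroepi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-centric epigenomic analysis with retroepi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

TET dioxygenases oxidise 5-methylcytosine (5mC) to 5-hydroxymethylcytosine
(5hmC) and further derivatives, initiating active DNA demethylation. In mouse
embryonic stem cells TET1 binds not only CpG-island promoters but also
transposable elements (TEs) — notably the 5' UTR of young, full-length LINE-1
(L1) copies and several LTR/ERV families. Asking *which* TE classes a set of
ChIP-seq peaks prefers, and *what* the methylation state of bound copies is,
runs into two characteristic obstacles:

1. **Multi-mapping.** Young TE families are nearly sequence-identical across
   hundreds of copies, so short reads cannot be placed uniquely. Discarding
   ambiguous reads (unique mapping) under-counts young elements; assigning
   each tied read to one of its best hits at random (inclusive mapping) keeps
   class-level signal but individual peak-copy assignments become
   "ambiguous".
2. **Composition bias.** Peaks are long and TEs cover a large genome
   fraction, so raw overlap counts mean nothing without a null that matches
   the peaks' number and length distribution — and, for uniquely mapped data,
   the restriction to the uniquely mappable genome ("uniqueome").

retroepi implements the full analysis stack around these two problems:
interval handling and RepeatMasker I/O, an exact k-mer uniqueome, the two
mapping policies, a permutation enrichment test against length-matched random
intervals, anchor/consensus/per-copy signal profiles, BS/oxBS/TAB methylation
arithmetic, repeat-class expression pooling with median-of-ratios
normalisation, promoter-interaction linking, and a seeded synthetic-data
generator that produces every input the pipeline consumes.

## Coordinate conventions

All intervals are tibbles with 0-based half-open `[start, end)` coordinates
(BED convention). 1-based inputs — RepeatMasker `.out` (strand `C` = minus)
and Bismark cytosine reports — are converted at the I/O boundary. Overlap
means at least one shared base pair by default; a `min_overlap` argument is
available everywhere but the 1-bp default is deliberate, since peak/TE
overlap is conventionally reported without a minimum-fraction rule. Whether a
summit-containment rule would be preferable is genuinely open; we expose the
summit (`peaks_to_anchors()`) for profiling but count overlaps on the full
peak interval, and also report the copy-unit count (`n_copies_hit`) next to
the peak-unit count.

## The enrichment test

For peaks $P$ and TE class $c$ with copies $T_c$, the observed statistic is
the number of peaks overlapping at least one copy. The null is
`sample_matched_random()`: a set with the identical multiset of peak lengths,
each interval placed uniformly among all valid placements — anywhere in the
genome, or fully inside one uniquely mappable block when a mappability track
is supplied (full containment, because a length-matched control should be
placeable where a peak of that length could actually have been called from
unique reads). Random intervals may overlap each other and other TEs; only
number and length are matched. With `n_reps` draws (default 1000),

$$p_c = \frac{1 + \#\{r : x_r \ge x_{obs}\}}{n_{reps} + 1},$$

the add-one permutation estimator, one-sided for enrichment, so $p$ is never
zero and is honest under ties. Benjamini–Hochberg correction is applied
across classes (`bh_adjust()`, a validated wrapper over
`stats::p.adjust`). Classes with zero annotated copies report a missing fold
rather than an infinite ratio. The number of randomisations is the only
accuracy knob: the smallest attainable p is $1/(n_{reps}+1)$.

Because overlap counts are integers, the attainable p-values are discrete and
the test is slightly conservative: under its own null generator the rejection
rate at $\alpha = 0.05$ sits near the low side of the nominal level
(approximately 0.03–0.05 in our calibration runs of 500 trials at
`n_reps = 1000`). This is the expected cost of an exact permutation test on
discrete counts, not a defect.

```{r}
sim <- simulate_genome(sim_config(seed = 1))
peaks <- simulate_chip(sim, fold = 3, fold_class = "LTR",
                       n_peaks = 2000, peak_width = 200, seed = 2)$peaks
fit <- enrichment_test(peaks, sim$te_copies, sim$chrom_sizes,
                       n_reps = 1000, seed = 3)
tidy(fit)
autoplot(fit)
```

## Mapping policies

A read's candidate alignments form its hit set; "tied best" means tied
maximal alignment score, falling back to MAPQ, and finally — when neither is
present — treating every hit of a multi-hit read as tied. This is a
definition we had to fix ourselves: unique filters in the wild are usually
unpublished scripts, and tied-best-score is the reading that matches the
stated semantics of inclusive mapping ("one of those locations at random").
`filter_unique()` keeps a read only when exactly one hit attains the best
score; `assign_inclusive()` keeps every read, drawing uniformly among its
tied-best hits from one seeded generator consumed in read-id-sorted order, so
reruns are byte-identical. The two policies agree exactly on singleton-hit
reads, and `|unique| <= |inclusive| = |reads|` always.

The uniqueome (`build_mappability()`) marks position $p$ mappable for read
length $k$ iff the k-mer at $p$ occurs exactly once in the genome plus its
reverse complement — an exact, desk-scale computation (in-memory k-mer
counting, intended for genomes up to tens of Mb) equivalent in spirit to
published uniqueome tracks derived by exhaustive alignment.

## Meta-profiles

`anchor_profile()` averages a binned track in a window around anchors (peak
summits when available, midpoints otherwise), reversing minus-strand windows
so profiles read 5'→3'; the flip is an exact involution. Window and bin
defaults (4 kb each side, 100 bp bins, set by the track) are display
choices, not inference parameters. `consensus_profile()` bins reads aligned
to a consensus element (e.g. a full-length L1 sequence), counting each read
once at its midpoint so coverage totals are conserved; the IP/input ratio
uses a pseudocount of 0.5 reads per bin (configurable) after scaling input
to the IP library size, so identical libraries give a ratio of exactly 1.
Because published profiles of this kind do not state their normalisation, we
emit raw counts alongside the ratio. The "5' UTR" of a consensus is a named
sub-interval supplied by the user — consensus annotations differ between
sources, so it is configuration, not code. `per_copy_signal()` gives
length-normalised (mean, not sum) per-copy values so copies of different
lengths are comparable, sorts stably by a designated primary track, and
reports copies outside a track's range as missing rather than zero.

## Methylation arithmetic

The three chemistries read out modification states as unconverted-C
fractions: BS = 5mC + 5hmC, oxBS = 5mC, TAB = 5hmC. `estimate_from_bs_oxbs()`
takes the subtraction estimate $\widehat{5hmC} = \hat p_{BS} - \hat p_{oxBS}$
at CpGs present in both chemistries, clamped at zero (the unclamped value is
kept as a diagnostic column); `estimate_from_tab()` reads 5hmC directly.
Wilson score intervals accompany the directly measured proportions and a
normal-approximation interval the difference. Clamping guarantees
$0 \le \widehat{5hmC} \le \widehat{mod} \le 1$ for every site.

Two numerical facts worth knowing:

* The subtraction estimator is unbiased before clamping, and clamping bias
  vanishes as depth grows; our tests verify mean bias below 0.005 at depth
  10,000.
* Its per-site standard deviation at depth $d$ per chemistry is
  $\sqrt{p_{BS}(1-p_{BS})/d + p_{ox}(1-p_{ox})/d}$ — about 0.020 at
  $d = 1000$ for levels (5mC, 5hmC) = (0.6, 0.2). A ±0.03 band is therefore
  only ±1.5 SD, capturing ~87% of sites; users wanting 95% of per-site
  subtraction estimates within ±0.03 need roughly 2.5× that depth, or should
  measure 5hmC directly by TAB (SD 0.013 at the same depth). Our own
  recovery checks report the realised fractions rather than asserting a
  tighter precision than the chemistry can deliver.

Amplicon analyses conventionally keep only CpGs with at least 100 reads;
`filter_min_coverage()` applies the threshold jointly across the chemistries
being combined (a subtraction needs depth on both inputs; a per-chemistry
mode exists). CpG dyads are merged across strands for genome-wide data and
kept separate in amplicon mode, where the sequenced strand is fixed by primer
design. `replicate_average()` is the unweighted per-CpG mean across
biological replicates; `aggregate_by_region()` is coverage-weighted within
regions (not a mean of CpG means), with zero-CpG regions missing rather than
zero.

`compare_groups()` implements the two-sided Wilcoxon rank-sum test with exact
enumeration when $n_a + n_b \le 12$ — a subset-sum dynamic programme over
doubled mid-ranks, so ties are handled exactly, which `stats::wilcox.test`
cannot do — and the tie-corrected normal approximation with continuity
correction otherwise (verified to match `wilcox.test` in tie-free cases).
Welch's t is delegated to `stats::t.test`.

## Repeat expression and interaction linking

`pool_repeat_counts()` pools reads by repeat class. A read overlapping copies
of $k > 1$ classes contributes $1/k$ to each by default; since no convention
is established for such reads, a `"drop"` mode sets them aside in an
`ambiguous` row instead. Either way reads are conserved:
classes + unassigned (+ ambiguous) = total. `size_factors()` is the
median-of-ratios estimator (median over features with all-positive counts of
the count over the feature's geometric mean, median taken in log space); our
tests check it against `DESeq2::estimateSizeFactorsForMatrix` to 1e-10.
Dispersion modelling and Wald testing are deliberately out of scope — group
comparisons on normalised counts are done with `compare_groups()`.

`link_tes_to_genes()` joins TE copies to genes through promoter-capture
interaction lists: a copy links to gene $g$ iff it overlaps the "other end"
of a pair whose bait is $g$'s promoter. When the same gene is linked to both
bound ("NOS+") and unbound copies, `grouped_expression_compare()` keeps it in
the bound group by default (`a_wins`) — the bound link is the biologically
active claim — with an `exclusive` mode that drops shared genes entirely.

## The synthetic-data generator

Every simulator is a pure function of (config, seed). The defaults describe
the study conditions at desk scale: a 2 Mb i.i.d. background carrying four
families — a young L1 (6.2 kb consensus, 40 copies, 1% divergence, half
5'-truncated), an old L1 (12% divergence), a 600 bp LTR family (100 copies)
and a 150 bp SINE (200 copies) — giving ~19% TE content, with full-length
versus truncated copies arising from a geometric 5'-truncation model (L1
integration is frequently 5'-truncated; mean offset half the consensus).
Copies are placed uniformly without overlap, diverged by per-base
substitution, and inserted on random strands.

ChIP simulation has two planting modes. Per-copy mode binds each copy of
family $f$ with probability $p_f$ and places one peak in the copy's 5'
window; each planted peak survives into the unique-mapping peak set with
probability `min(1, divergence/10)` by default, so young near-identical
copies lose most unique peaks while old copies keep theirs — the mappability
asymmetry the unique/ambiguous contrast is designed to expose. Target-fold
mode computes the null overlap probability $p_0$ of a random peak by exact
placement counting and places each peak inside the class with probability
$q = p_0(F-1)/(1-p_0)$, making the expected enrichment fold exactly $F$ —
the plant is analytic, so recovery tests measure estimator error only.
Read simulation draws fixed-length reads and finds *every* exact occurrence
of each read in the genome and its reverse complement (edit distance 0), a
transparent stand-in for aligner ambiguity.

Bisulfite simulation evaluates the chemistry matrix per CpG (true state
probabilities $p_C, p_{5mC}, p_{5hmC}$; conversion rate for unmodified C;
per-chemistry protection-failure rates), draws Poisson depths and binomial
unconverted counts, and writes Bismark-style reports. Default non-ideal
rates (conversion 0.995; failures 0.005/0.005/0.03 for BS/oxBS/TAB) reflect
typical kit conversion efficiencies and the weaker protection of TAB
chemistry; ideal chemistry (conversion 1, failures 0) is used for estimator
calibration. Default methylome: background (0.75, 0.05), young L1 (0.60,
0.15) — TET-bound elements carry more 5hmC and less 5mC — old L1 (0.85,
0.02), LTR (0.50, 0.10), SINE (0.80, 0.03).

What the generator does *not* model: sequencing errors and quality scores,
indels, insertion-site preferences, CpG-island structure (background CpGs
appear at the i.i.d. rate of 1/16), copy-number variation between samples,
and incomplete-conversion spatial correlation along reads. Passing recovery
tests on this generator therefore demonstrates correctness of the
estimators under their stated sampling models, not robustness to real-data
artefacts such as mapping bias from sequencing error or CpG-density
confounding.

## Problem sizes and determinism

The test and calibration runs use sizes chosen to make Monte-Carlo error
small relative to the tolerances they check: 2 Mb genomes; 2000 peaks and
1000 randomisations for fold recovery (fold SE ≈ 0.18, so a ±15% band is
≈2.5 SE); 500 trials × 1000 randomisations for null calibration; 40 copies
per family for binding-probability recovery (exact binomial intervals);
depth-1000 amplicons with 200 CpGs for chemistry recovery; 10,000 tied reads
for the uniformity test; and at least 100 random instances per brute-force
oracle comparison. Every stochastic step takes an explicit integer seed, and
all seeded functions preserve the caller's RNG state.

## Known limitations

* The uniqueome is exact but memory-bound (all k-mers in memory); it is not
  a replacement for alignment-based mappability tracks on full mammalian
  genomes.
* The enrichment null matches number and length but not chromatin
  accessibility or GC content; on real data a biased peak caller will bias
  the test in ways the matched-length null cannot see.
* `read_sam_hits()` assumes ungapped alignments when reconstructing hit
  intervals (reference span = read length); simulated alignments satisfy
  this, spliced or clipped real alignments may not.
* Conversion-error-corrected estimation (passing a `chemistry` list to
  `estimate_from_bs_oxbs()`, which inverts the conversion matrix) assumes
  the conversion and failure rates are known exactly; rate uncertainty is
  not propagated. The naive proportions remain the default, matching
  standard practice.
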