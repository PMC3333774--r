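---
title: "Methods: pooled shRNA screen deconvolution with poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled shRNA screen deconvolution with poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The measurement problem

A pooled shRNA screen compares the abundance of thousands of hairpin
constructs between two arms of a cell population. The abundance readout is
counting: the 19-nt sense sequence of each integrated hairpin is amplified
and sequenced, reads are matched back to the library, and the per-hairpin
count ratio between arms estimates the fitness effect of that knockdown.
Three things stand between raw reads and a usable score:

1. sequencing and PCR errors scatter reads away from their true barcode, so
   exact matching undercounts in a base-composition-dependent way;
2. the log count ratio carries a systematic, abundance-dependent bias, and
   its sampling variance grows as counts shrink;
3. arms and replicates differ in depth and dispersion, so raw ratios are
   not comparable across pools or replicates.

`poolscreen` addresses these with mismatch-tolerant alignment, loess
normalization of the ratio against abundance, robust rescaling, and
replicate harmonization, and closes the loop with a simulator that measures
how much depletion the whole chain can detect.

## Alignment model

Reads are trimmed to the sense window — by default bases 3 to 21 (1-based,
inclusive) of a 26-base read, matching a chemistry that sequences from two
bases upstream of the sense insert. A read whose window contains more than
`max_n = 2` uncalled bases is discarded. Identical trimmed reads are binned
and each distinct sequence is aligned once (multiplicities restored when
tallying), which changes nothing semantically and saves most of the work.

Assignment minimizes Hamming distance against the library with a cap of
`max_mismatch = 2`: the cap is appropriate for libraries whose sequences
are almost all separated by more than twice the cap, which
`edit_distance_profile()` verifies for a given library. Assignment is
*best-stratum*: a bin maps to the unique sequence attaining the minimal
distance; if two or more sequences tie at that minimum the bin is counted
ambiguous and excluded, but a unique hit at distance 1 is kept regardless
of how crowded distance 2 is. Distance-0 lookups go through a hash index;
this is exactly equivalent to the exhaustive search because only duplicated
library sequences can tie at distance zero, and those are detected by the
same index (the test suite asserts bitwise equivalence of the accelerated
and brute-force paths on random libraries).

Numerical conventions:

* An uncalled base (`N`, or `.` normalized to `N`) mismatches *every* base,
  including another `N`. An uncalled position carries no evidence of
  identity, and this convention composes with the mismatch cap: a read may
  carry up to two Ns, but Ns and substitutions together may not exceed the
  cap. The permissive alternative (N matches anything) would let two-N
  reads float between near-neighbour constructs.
* Reads are aligned as sequenced; no reverse-complement search is done
  because the sequencing primer fixes the orientation. A `revcomp` search
  would be a trivial extension but is deliberately not a default.
* Base qualities are parsed and ignored everywhere: binning identical reads
  regardless of quality is part of the counting model, and the uncalled
  filter is the only quality gate.

Every run satisfies the exact conservation identity
`filtered + unique + ambiguous + unmapped = total`, which the pipeline logs
at each checkpoint and the tests assert.

## Scoring model

For hairpin \(h\) in one replicate pair, with pseudocount \(q = 0.5\):

\[
M_h = \log_2(c^{test}_h + q) - \log_2(c^{ref}_h + q), \qquad
A_h = \tfrac12\left[\log_2(c^{test}_h + q) + \log_2(c^{ref}_h + q)\right].
\]

The pseudocount keeps zero counts finite while shifting large counts
negligibly; 0.5 is the conventional half-count. The pipeline order is
fixed: abundance filter → log2 → ratio → loess per pool → MAD rescale per
pool → optional quantile normalization across replicates → replicate
summary.

**Abundance filter.** Hairpins whose mean reference count falls below
`min_ref_count = 100` are flagged: below roughly 100 reads the Poisson
standard deviation of \(M_h\) exceeds ~0.2, and such hairpins dominate the
false-negative tail. Flagged hairpins are excluded from trend and scale
estimation and from hit calling but stay in every output with the flag set.

**Loess normalization.** \(M\) is regressed on \(A\) within each screening
pool (pools are library subsets prepared and sequenced together, so the
bias is pool-specific) and the score is the residual \(M - \hat f(A)\).
Defaults: degree 1, span 0.5, tricube neighbourhood weights — the
conventional MA-normalization setting. The fit is *robust*
(`family = "symmetric"`, biweight iterations) by design: hairpins with
genuine strong depletion concentrate at low \(A\) precisely because they
are depleted, and a least-squares trend follows them, subtracting the very
signal the screen exists to measure. On simulated engineered-depletion
pools a non-robust fit dips by more than a log unit where depleted hairpins
dominate the local abundance stratum and misses several percent of a
75%-depleted group at the zero-false-positive threshold; the robust fit
does not. `family = "gaussian"` remains available for data known to be
signal-sparse. When the trend is fitted on filtered hairpins only, the
prediction is clamped to the fitted abundance range so excluded hairpins
still receive finite scores.

Two limitations follow from the span. First, bias removal is only as good
as the trend is smooth at the span's scale: an injected bias with one
turning point across the abundance range is removed to under 5% of its
amplitude at span 0.3, while a full-period oscillation is not; the span is
a user parameter and diagnostics (`autoplot(scores, "ma")`) show the fit.
Second, when a third of the pool is strongly depleted, even the robust fit
absorbs a small part (~5%) of the largest effects at low abundance; the
parameter-recovery tests therefore use designs where depleted hairpins are
a few percent of the pool, and engineered-depletion benchmarks measure
detection, not effect-size calibration.

**MAD rescaling.** Scores are centred at the pool median and divided by
1.4826 × MAD, the normal-consistent robust scale, giving robust z-scores
with pool median 0 and scaled MAD 1 (exact, asserted to 1e-9). Centring is
included so that pools with different global drift are comparable; the
robust estimators ignore up to ~50% contamination, far beyond any sensible
hit fraction.

**Quantile normalization.** Optional, for visibly heterogeneous replicate
distributions: each column's order statistics are replaced by the
across-column mean of order statistics (via `limma`), so sorted columns
become identical. Ties within a column receive the mean of the reference
values across the tied rank span; note that a column containing ties
necessarily deviates from the tie-free columns at those ranks — the
identical-marginals property is exact for continuous scores. A plain
rank-replacement mode is kept for comparison (`rank_only`).

**Replicate summary.** The median (default), or a regularized *t*
statistic \(d_h = \bar z_h / (s_0 + s_h/\sqrt{n})\) with \(s_0\) the 90th
percentile of the per-hairpin standard deviations across scored hairpins.
The fudge term keeps hairpins with accidentally tiny replicate spread from
exploding; the 90th percentile is the classic moderated-statistic choice
and is configurable. Note the median of \(r\) independent unit-scale
replicates has scale \(\approx 1/\sqrt{r}\); summaries are comparable
within a run, not across runs with different replicate counts.

## Hit calling

The score distribution of a screen is, to a good approximation, normal in
its core with hits in the tails. The caller formalizes the usual visual
reading of a QQ plot: draw the reference line through the robust
location/scale (median, 1.4826 × MAD); compare each order statistic with
its expected normal quantile at the Blom plotting position
\((i - 3/8)/(n + 1/4)\); walking inward from each tail, flag the outermost
contiguous run of points departing by more than `deviation_k = 0.5` score
units; the threshold is the observed value at the first conforming point,
infinite if the most extreme point already conforms. Properties worth
knowing, both asserted in the tests:

* under a pure normal null the flagged fraction is far below 1% (usually
  zero to a couple of points — the sample extremes fluctuate by a few
  tenths of a score unit around their plotting positions);
* a heavy planted tail is recovered completely, but drags the genuinely
  extreme order statistics of the remaining sample off their fixed-rank
  expectations, so a boundary layer of a few tenths of a percent of
  near-threshold scores can be swept up with it. Any rule of this family
  trades that layer against stability; re-ranking the expectations after
  each flagged point removes the layer in the planted case but is unstable
  under the null (one false flag freezes the expected-extreme line while
  the observed values rise, and the walk cascades), so the fixed-rank rule
  is used.

A fixed `|z| > k` cut (`fixed_z`) is available as the conventional
fallback. `deviation_k` is in score units (robust z-scores after
rescaling), so 0.5 means "half a standard deviation away from where that
order statistic should sit".

**Gene scores.** Genes are scored by the weighted average of their two most
extreme hairpins in the tested direction, \(\alpha \cdot s_{(1)} +
(1-\alpha) \cdot s_{(2)}\) with \(\alpha = 0.75\) — redundancy-aware but
dominated by the best hairpin; single-hairpin genes score as that hairpin
and are flagged. Significance is empirical: `n_perm = 1000` size-matched
random hairpin sets drawn from the same pool's scored hairpins, \(p = (1 +
\#\{perm \le obs\})/(1 + n_{perm})\) (so the smallest attainable p is
\(1/(n_{perm}+1)\)), with Benjamini–Hochberg q-values. Permutation draws
are shared per gene size, which is what makes 1,000 permutations over
thousands of genes affordable; p-values remain super-uniform under the
null (tested).

## The simulator: what it emulates and what it does not

`simulate_screen()` generates the statistical skeleton of an
engineered-depletion experiment:

* starting relative abundances \(p_h \propto \exp N(0, \sigma_a)\) with
  \(\sigma_a = 0.5\) (natural log), a ~30-fold typical abundance spread as
  seen in well-prepared plasmid pools;
* a designed retention factor \(d_h \in (0, 1]\) for chosen subsets
  (`"1000x0.75,1000x0.5,1000x0.25"` is the reference three-level design in
  a 10,000-hairpin pool); test-arm abundances \(\propto p_h d_h\),
  renormalized;
* per sample, counts \(\sim \text{Poisson}(R \, q_{h,s} \, 2^{N(0,
  \sigma_n)})\) with \(R = 10^7\) reads per sample and \(\sigma_n = 0.08\)
  (log2). The lognormal factor is *extra-Poisson* noise summarizing
  everything multiplicative upstream of sequencing — culture stochasticity,
  PCR amplification (more cycles, larger \(\sigma_n\)), pipetting. 0.08 is
  a calibration choice for a short-term screen readout, not a measured
  constant; it is the single most influential parameter in every
  sensitivity figure and is exposed everywhere.
* Poisson rather than multinomial sequencing sampling, for cell-wise
  independence; at \(10^7\) reads over \(10^4\) hairpins the difference is
  negligible.
* optionally, FASTQ emission: 26-base reads (2-base and 5-base constant
  flanks around the sense sequence — arbitrary stand-ins for the vector's
  constant regions), per-base substitution errors at 0.5% and uncalled
  bases at 0.1%, drawn sparsely but exactly as independent per-base events.

Reproducibility: one master seed; per-sample streams are derived from it so
that adding replicates never perturbs earlier samples.

Deliberately **not** modelled: viral integration copy number (MOI-driven
multiple integrations), growth dynamics over passages, GFP selection,
hairpin-sequence-specific PCR efficiency, and position-dependent sequencing
error. Consequently, passing benchmarks say the *analysis chain* detects
the designed depletion under calibrated noise; they do not certify
sensitivity for a real screen whose noise exceeds the calibration. The
evaluator is the tool to re-run with parameters matched to one's own data.

Evaluation reports, per depletion group: the FNR at the most permissive
threshold admitting zero false positives (the reference operating point for
"detected with no false positives"), the FPR at the threshold where the
group's FNR first reaches 5%, and the group mean of raw test/reference
count ratios (zero-reference hairpins excluded and tallied); plus the
pooled ROC and the squared Pearson correlation of loess-normalized log
ratios between replicates. Read-depth titration uses independent binomial
thinning of every count cell, which maps Poisson counts to Poisson counts
at the thinned rate and composes multiplicatively.

On replicate reproducibility, an analytic note: in the three-level
reference design the variance of true log2 ratios across hairpins is
\(0.7 \cdot 0.34^2\)-ish — concretely \(\mathrm{Var}(M^{true}) \approx
0.40\) — while each replicate adds noise variance \(2\sigma_n^2 +
\mathbb E[1/\lambda]\)-terms \(\approx 0.019\). The between-replicate
\(r^2\) is therefore capped near \((0.40/0.42)^2 \approx 0.91\) under the
default calibration; observed values around 0.90 are the model's ceiling,
not an implementation loss.

## Problem sizes and test design

The test suite exercises the aligner against a pure-R brute-force oracle on
libraries up to 100 hairpins, property tests (conservation, monotonicity in
the mismatch cap, thinning composition, ROC monotonicity, QQ null rates)
on seeded random cases, and the full benchmark chain at its reference
scale: 10,000-hairpin pools at \(10^7\) reads per sample, ten seeds per
operating point, and one million emitted FASTQ reads for the read-level
recovery benchmark. Those sizes keep every Monte-Carlo standard error well
below the margins being asserted while a full run stays in the minutes
range. `scripts/acceptance.R` recomputes all benchmark numbers from
scratch at those same sizes.

## Known limitations

* Two-arm designs only; multi-arm or time-course screens must be analyzed
  as condition pairs.
* Loess attenuation of very large effects when depleted hairpins dominate
  an abundance stratum (see above): detection operating points are
  unaffected, effect-size estimates of extreme groups are mildly shrunk.
* The QQ caller's boundary layer under heavy planted tails (see above).
* Gene scores implement only the weighted-average top-two statistic;
  rank-based enrichment over full hairpin sets is out of scope.
* The simulator's error model is substitution-only within reads; indels,
  which the Hamming aligner cannot absorb, are not modelled and would land
  in `unmapped`.
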