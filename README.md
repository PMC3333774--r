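# poolscreen

Deconvolution and statistical analysis of pooled shRNA barcode screens read
out by next-generation sequencing.

In a pooled (barcode) screen, a cell population is transduced with thousands
of shRNA constructs, split into a reference and a test arm (e.g. vehicle vs
drug, or start vs end of a viability time course), and the 19-nt sense
sequence of each integrated hairpin is PCR-amplified and sequenced. The
per-hairpin read counts before and after selection measure each knockdown's
fitness effect. `poolscreen` is for screeners and analysts who need to turn
raw FASTQ from such screens into normalized hairpin scores, hit lists, and
gene rankings — and to quantify, by simulation, how sensitive their design is.

## What it does

**Alignment.** Reads are trimmed to the sense window (bases 3–21 of a
26-base read by default), reads with more than two uncalled bases are
discarded, identical reads are binned, and each bin is assigned to the
library sequence at minimal Hamming distance, up to 2 mismatches. Ties at
the minimal distance are excluded as ambiguous (best-stratum rule: a unique
hit at distance 1 wins even if several sequences sit at distance 2). The
bookkeeping `filtered + unique + ambiguous + unmapped = total` is exact.

**Normalization and scoring.** For each replicate pair, with counts
\(c^{\mathrm{test}}_h, c^{\mathrm{ref}}_h\) per hairpin \(h\):

    M_h = log2(c_test + 0.5) − log2(c_ref + 0.5)
    A_h = [log2(c_test + 0.5) + log2(c_ref + 0.5)] / 2

The log ratio is normalized by a robust loess fit of `M` on `A` within each
screening pool (removing abundance-dependent bias), rescaled to robust
z-scores by the pool MAD, `z = (m − median) / (1.4826 · MAD)`, optionally
quantile-normalized across replicates, and summarized by the median or a
regularized *t* statistic `d = mean / (s0 + s/√n)`. Hairpins with mean
reference count below 100 are flagged and excluded from estimation and hit
calling.

**Hit calling.** Thresholds come from the departure of the score
distribution from the normal reference line of a QQ plot (robust
location/scale, Blom plotting positions); genes are ranked by the weighted
average of their two most extreme hairpins
(`0.75·first + 0.25·second`) with permutation p-values and BH q-values.

**Simulation and evaluation.** A generative model of the screen — lognormal
starting abundance, designed multiplicative depletion of hairpin subsets,
log2-normal extra-Poisson noise, Poisson sequencing sampling, and optional
FASTQ emission with per-base substitution/uncalled errors — plus an
evaluator reporting the false negative rate at the most permissive
zero-false-positive threshold, the FPR at 5% FNR, group mean test/reference
count ratios, replicate r², ROC curves, and binomial read-depth
subsampling.

**Planning.** `plan_screen()` converts pool size, per-hairpin
representation and MOI into cells, genomic DNA mass (6 pg/cell) and
parallel PCR reactions (2 µg each).

## Worked example

Simulate a 2,000-hairpin screen in which 200 hairpins are depleted by 50%,
score it with the default pipeline, and evaluate detection:

```r
library(poolscreen)

lib <- random_hairpin_library(2000, seed = 1)
cfg <- sim_config(n_hairpins = 2000, depletion = "200x0.5",
                  reads_per_sample = 2e6, n_replicates = 2, seed = 1)
sim <- simulate_screen(cfg, lib = lib)

scores <- normalize_screen(sim$counts, sim$sheet, lib = lib, min_ref_count = 100)
glance(scores)
#> # A tibble: 1 × 5
#>   pool_id n_hairpins n_replicates n_filtered replicate_r2
#> 1 pool1         2000            2          0        0.704

evaluate_detection(scores, sim$truth, counts = sim$counts, sheet = sim$sheet)
#> <screen_eval>
#>  retention   n fnr_at_zero_fpr fpr_at_fnr5 mean_ratio n_ratio_excluded
#>        0.5 200               0           0  0.5249528                0
#> replicate r^2: 0.7039
```

Every truly depleted hairpin scores below every unmanipulated one
(`fnr_at_zero_fpr = 0`), and the group's raw count ratio (0.52) sits at its
designed value of 0.5. Hit calling and gene ranking:

```r
hits <- call_hits(scores)
dplyr::count(hits, hit)
#> 1 depleted   215
#> 2 none      1785

head(gene_scores(scores, lib = lib, n_perm = 1000, seed = 1), 3)
#>   gene_symbol n_hairpins score p_value q_value single_hairpin direction
#> 1 GENE630              3 -7.50 0.00200   0.666 FALSE          depletion
#> 2 GENE239              3 -7.40 0.00200   0.666 FALSE          depletion
#> 3 GENE443              3 -7.32 0.00300   0.666 FALSE          depletion
```

The gene scores are weighted averages of each gene's two most extreme
hairpin z-scores; `p_value` is the fraction of size-matched random hairpin
sets scoring at least as low. Planning the wet-lab side of a 10,000-shRNA
pool at 1,000 cells per hairpin and MOI 0.7:

```r
plan_screen(10000, 1000, 0.7)
#>   n_shrna representation   moi infected_cells maintained_cells dna_mass_ug n_pcr
#> 1   10000           1000   0.7       10000000        14285714.          60    30
```

Diagnostics (`autoplot(scores, "ma")`, `autoplot(scores, "density")`,
`autoplot(scores, "replicates")`, `autoplot(eval)`) draw the MA clouds with
their loess trends, score densities, replicate scatter, and ROC curve.

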