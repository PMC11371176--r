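# paskit

Toolkit for analysing **antisense (PAS-gene) transcription in the plant
cold response** — for researchers working with strand-specific nascent
transcription data (plaNET-seq/NET-seq-style coverage) alongside
steady-state RNA-seq, qPCR decay assays and electrolyte-leakage freezing
tests, and for anyone who wants those analyses reproducible on synthetic
data with known ground truth.

Many cold-induced regulators are easy to miss in RNA-seq: they are strongly
transcribed but their mRNAs turn over fast, so steady-state levels barely
move. paskit ties the pieces of that story together in one tested pipeline:

1. **PAS-gene classification.** A gene hosts *poly(A)-site-associated
   antisense transcription* if an opposite-strand unit initiates in its
   3'-half or within 20% of its length downstream of its 3' end. For a
   plus-strand gene `[s, e)` of length `L` the acceptance windows are
   `[s + ceil(L/2), e)` and `[e, e + ceil(0.2 L))`, mirrored on the minus
   strand. Units are segmented from per-base bedGraph coverage
   (`detect_units()`), genes classified with `classify_pas()` /
   `call_pas_genes()`.
2. **Nascent vs steady-state differential expression.** A self-contained
   negative-binomial Wald test with median-of-ratios normalisation and BH
   FDR (`test_differential()`), calls at FDR < 0.05 and |log2FC| >= 0.5;
   cross-assay overlap and fold-change correlation (`overlap_de()`), and a
   screen for transient "CBF2-like" induction — UP by 3 h of cold, DOWN
   again between 3 and 12 h (`match_induction_pattern()`).
3. **Decay kinetics.** The steady-state model `dM/dt = alpha − k·M` with a
   step change at cold onset has the closed form
   `M(t) = (alpha_4/k_4)(1 − exp(−k_4 t)) + M0 exp(−k_4 t)`; with induction
   fold `f = alpha_4/alpha_22` and faster cold decay `k_4 > k_22` the
   steady-state fold change is *muted* to `f·k_22/k_4` while nascent
   transcription changes by `f` (`predict_steady_state_fc()`). Half-lives
   from inhibitor time courses use `t1/2 = ln2/slope` on the log relative
   abundance (`fit_half_life()`), with Student's t comparisons of 22 °C vs
   4 °C stability and `E^(−ΔΔCq)` expression fold changes.
4. **Metagene profiles** around the +1 nucleosome (500 bp windows) and over
   scaled gene bodies, strand-aware and reflection-invariant, with 95%
   confidence bands (`anchored_matrix()`, `scaled_body_matrix()`).
5. **Freezing tolerance.** Electrolyte leakage
   (`100·cond_before/cond_after`), four-parameter logistic LT50 fits
   (`fit_lt50()`), and the extra sum-of-squares F-test between genotypes
   (`compare_curves()`): `F = ((RSS_sh − RSS_sep)/4)/(RSS_sep/(N−8))` on
   `F(4, N−8)`.
6. **A synthetic-data generator** (`simulate_genome()`, `simulate_*`,
   `simulate_dataset()`) that produces every input above — GFF3/BED gene
   models, stranded bedGraph coverage with a +1-nucleosome stall peak,
   NB count matrices at 22 °C / 3 h 4 °C / 12 h 4 °C, Cq decay series at
   0/15/30/60/120 min, and sigmoidal leakage curves — from explicit kinetic
   ground truth, so every stage is testable without sequencing data.

## Worked example

```r
library(paskit)

dir <- file.path(tempdir(), "demo")
res <- simulate_dataset(default_config(seed = 1), dir)   # writes 14 files

# 1. antisense units and PAS genes from 22 degC coverage
cov   <- res$coverage[["22C"]]
units <- detect_units(cov$plus, cov$minus)
calls <- call_pas_genes(res$genes, units)
sum(calls$is_pas)                  # 50 called; truth has 50 PAS genes

# 2. nascent vs steady-state DE after 3 h cold
de_s <- test_differential(res$counts,         "22C", "4C_3h")
de_n <- test_differential(res$counts_nascent, "22C", "4C_3h")
overlap_de(de_n, de_s)
#> $n_up_both 55  $n_down_both 30  $fc_correlation 0.973

# 3. transient (CBF2-like) induction pattern in the nascent assay
de_n312 <- test_differential(res$counts_nascent, "4C_3h", "4C_12h")
length(match_induction_pattern(de_n, de_n312))   # 25, the designed set

# 4. mRNA half-life at both temperatures for the first transient gene
fit_half_life(res$decay[[1]])
#> <decay_fit> G0002 at 22 degC [abundance]: slope 0.01022/min, t1/2 67.79 min
fit_half_life(res$decay[[2]])
#> <decay_fit> G0002 at 4 degC  [abundance]: slope 0.01873/min, t1/2 37.01 min

# 5. freezing tolerance of the two simulated genotypes
leak <- read_leakage_tsv(file.path(dir, "leakage.tsv"))
compare_curves(leak[leak$genotype == "WT", ],
               leak[leak$genotype == "mutant", ])
#> <lt50_comparison> LT50 -5.91 vs -3.60 degC (delta 2.31); F(4,52)=149, p=8.3e-28
```

The numbers mean: all 50 antisense-hosting genes are recovered from noisy
coverage; 55 genes are induced in both assays after 3 h with strongly
correlated fold changes; the 25 transiently induced regulators are
recovered exactly; the example gene's mRNA is destabilised in cold (half-life
68 → 37 min), which is what mutes its steady-state response; and the two
genotypes' LT50s (-5.91 vs -3.60 °C, versus -6.1 and -3.7 simulated) differ
decisively by the extra sum-of-squares F-test.

The same pipeline runs from the shell via the installed `exec/paskit`
script (`simulate`, `call-pas`, `de`, `compare`, `decay`, `metagene`,
`freeze` subcommands), reading and writing GFF3/BED/bedGraph/TSV/JSON.

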