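---
title: "Models and methods behind paskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paskit)
```

paskit analyses antisense (PAS-gene) transcription in the plant cold
response and the kinetics that link nascent transcription to steady-state
mRNA. This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic data can and cannot
tell you about real sequencing data.

## The kinetic model

Every simulated readout derives from one first-order model per gene,

$$\frac{dM}{dt} = \alpha(t) - k(T)\,M,$$

with synthesis rate $\alpha$ (arbitrary units/min) and decay rate $k$
(1/min). Cold exposure is modelled as a single step change at $t = 0$ from
$(\alpha_{22}, k_{22})$ to $(\alpha_4, k_4)$, giving the closed form
implemented in `solve_mrna_level()`:

$$M(t) = \frac{\alpha_4}{k_4}\left(1 - e^{-k_4 t}\right) + M_0 e^{-k_4 t},
\qquad M_0 = \frac{\alpha_{22}}{k_{22}}.$$

A step change is the richest dynamic the two cold timepoints (3 h and 12 h)
can identify; no numerical ODE solver is involved. The model formalises the
central observation the package exists to explore: when cold both induces
transcription ($f = \alpha_4/\alpha_{22} > 1$) and destabilises the
transcript ($k_4 > k_{22}$), the steady-state response is *muted*
relative to the nascent one, asymptotically by exactly $k_{22}/k_4$
(`predict_steady_state_fc()`). Highly induced but rapidly degraded
regulators can therefore look unremarkable in RNA-seq while plaNET-seq-style
nascent assays see a strong response.

Transiently induced ("CBF2-like") genes need a second event: their
synthesis reverts to $\alpha_{22}$ at `t_off` (default 180 min) while decay
stays at its cold value. This produces the UP-by-3-h, DOWN-from-3-to-12-h
signature that `match_induction_pattern()` screens for.

## The synthetic genome and its defaults

`simulate_genome()` lays genes end to end on one chromosome. Defaults are
the study conditions all tests run under:

* 200 genes of 1–3 kb, 25% hosting antisense transcription, 15% encoding
  transcription factors, 25 transient-induction genes drawn from the TF
  pool; sustained UP and DOWN classes take 15% each with induction folds of
  4–8 (6–10 for transient genes). These mirror a genome where a quarter of
  genes carry 3'-antisense units and stress TFs are the transient class.
* Antisense TSSs are drawn uniformly over the union of the host's 3'-half
  and 20%-of-length downstream window, so by construction every truth-table
  PAS gene satisfies the caller's geometric rule; units extend to 1 kb past
  the host TSS on the opposite strand. The 5' end is a draw from a window,
  not a fixed point, reflecting that antisense boundaries are diffuse in
  real data.
* Intergenic gaps are drawn from 1.8–3 kb. This is a geometric guarantee,
  fixed before any tuning: an antisense unit reaches at most
  1 kb + ceil(0.2 × 3 kb) = 1.6 kb beyond its host, so with the default
  50 bp gap bridging no unit can merge with a neighbouring gene's signal on
  the same strand. Real genomes are denser; see *Limitations*.
* 22 °C half-lives are lognormal with median 60 min (sdlog 0.4), a typical
  scale for stress-responsive plant mRNAs; cold multiplies $k$ by 1–1.6
  (sustained UP) or 1.2–2 (transient).

Noise models are the simplest matching each data type's support: Poisson
per-base nascent coverage, negative-binomial counts (dispersion 0.05),
Gaussian noise on Cq cycles and on leakage percentages. Coverage places an
RNAPII stall peak (default amplitude ×3) over a 150 bp window at the +1
nucleosome, anchored at TSS + 150 bp — a canonical Arabidopsis +1 position;
the offset is a parameter because anchor derivation from nucleosome data is
out of scope. Antisense amplitude follows the host's *warm* synthesis rate
at every condition (antisense transcription stays comparatively flat
through the cold response); the antisense:sense ratio (default 0.5) is
exposed rather than asserted, since no quantitative initiation strength is
established in the literature.

## PAS-gene classification

`classify_pas()` implements the geometric rule: a gene hosts PAS
transcription if an opposite-strand unit initiates in its 3'-half or within
20% of its length downstream of its 3' end. Window arithmetic is fixed by
convention, since no rounding rule is standard: coordinates are 0-based
half-open everywhere (converted at GFF3 I/O), half-lengths and the 20%
window take the ceiling, and for a plus-strand gene $[s, e)$ of length $L$
the windows are $[s + \lceil L/2 \rceil, e)$ and
$[e, e + \lceil 0.2L \rceil)$, mirrored exactly on the minus strand. A
one-base gene still classifies (empty 3'-half, one-base downstream window).
The 20% window is anchored at the annotated gene end; where UTR annotation
and poly(A) site disagree, that choice is the ambiguity to be aware of.
"Initiating" means the unit's 5'-most base, not its signal maximum.

`detect_units()` segments each strand into runs of coverage at or above
`min_signal` (default 1 read/base), bridging internal gaps up to 50 bp and
keeping spans of at least 100 bp. Unit count is deliberately *not*
guaranteed monotone in the threshold — a plateau with an internal dip
splits when the dip falls below threshold — but the bases covered by units
are monotone, and the suite verifies the segmentation against a brute-force
scanner. When several units match a gene, the highest mean signal wins,
ties to the leftmost TSS.

## Differential expression

`test_differential()` is a self-contained negative-binomial Wald test, not
a DESeq2 wrapper: its contract here is calibration on simulated counts, not
numerical equality with DESeq2, and the two will diverge on real data
(DESeq2 adds dispersion shrinkage across a fitted trend, fold-change
moderation and outlier handling). The pieces:

* Median-of-ratios size factors over genes expressed in all samples.
* log2 fold change from normalised group means with a 0.5 pseudocount (so
  `(10,10,10)` vs `(80,80,80)` gives `log2(80.5/10.5) = 2.939`, not 3).
* Method-of-moments dispersion; the default pools one estimate across
  genes (all simulated genes share one dispersion), `per_gene` shrinks
  gene-level estimates halfway to the pool.
* Wald $z$ = log2FC/SE with a delta-method SE, normal two-sided p-values,
  BH adjustment (`stats::p.adjust`), and calls requiring FDR < 0.05 *and*
  |log2FC| ≥ 0.5 — the fold-change rule is read as two-sided, with the sign
  giving UP versus DOWN. Under the package's NB null (2000 genes, 3 vs 3,
  counts ~500) the type-I error at $\alpha = 0.05$ sits near 0.055; at much
  lower counts it drifts anti-conservative (~0.08 at mean 50), a known
  delta-method small-count effect.

Cross-assay concordance (`overlap_de()`) counts same-direction calls and
reports the Pearson correlation of fold changes over that overlap (the
comparison is linear on the log2 scale; Spearman is an option). Class
comparisons (`compare_gene_classes()`) use the Mann–Whitney U, enumerating
the exact tie-aware null when both groups have ≤ 8 members and otherwise
the tie-corrected normal approximation with continuity correction.

## Decay kinetics

Relative abundance from qPCR is $R(t) = E^{-(Cq(t) - Cq(0))}$ with primer
efficiency $E \in (1, 2]$; replicates are averaged on the Cq (log) scale.
`fit_half_life()` offers two modes:

* **abundance** (default): regress $\ln R(t)$ on time through the origin;
  for exponential decay this recovers $k$ exactly, and
  $t_{1/2} = \ln 2 / k$ has its textbook meaning.
* **literal**: the classical transform $y(t) = \ln(Cq(t)/Cq(0)) \times
  (-10)$ fitted by ordinary least squares with intercept, slope sign-flipped.
  This operates on ratios of cycle numbers, which is dimensionally odd (and
  the −10 constant has no mechanistic origin we would defend), but it is
  retained so results computed that way are auditable. On noise-free
  exponentials it is a strictly monotone — not identity — function of the
  true half-life.

A non-positive slope yields `t_half = Inf` with a flag rather than an
error. Temperature comparisons (`compare_stability()`) use Student's
equal-variance t-test on per-replicate slopes, as assay figure legends
conventionally state (Welch via `var_equal = FALSE`); expression fold
changes follow the $E^{-\Delta\Delta Cq}$ definition.

## Metagene profiles

Anchored profiles take the bases at 5'→3' offsets $-w..w-1$ around the
anchor (total 500 bp by default, 10 bp bins). Defining the window in the
gene's frame rather than the genome's makes profiles exactly invariant
under genome reflection, which the suite asserts bit-for-bit. Genes whose
window leaves the chromosome are excluded, not zero-padded — padding biases
the mean — and listed in the output. Scaled gene-body profiles partition
each body into `nbins` near-equal runs, remainder bases going one each to
the 5'-most bins (length 10 into 3 bins → 4, 3, 3), which conserves
per-gene total signal exactly. Binning averages raw signal; per-gene
normalisation is deliberately not the default since raw nascent signal is
what the profiles are meant to show. The summary band is the plain
mean ± 1.96 SD/√n per bin.

## Freezing tolerance

Electrolyte leakage is 100 × (conductivity before flash freeze) /
(conductivity after), clamped to [0, 100] with a flag. `fit_lt50()` fits
the four-parameter logistic

$$EL(T) = bottom + \frac{top - bottom}{1 + e^{hill (T - LT_{50})}}$$

in its temperature orientation ($hill > 0$, leakage rising as temperature
falls) by Levenberg–Marquardt least squares. Initialisation is multi-start:
a data-driven guess (asymptotes from the data extremes, midpoint by nearest
mean leakage) plus an LT50 grid over −2..−10 °C; the lowest-RSS converged
fit wins, and non-convergence of every start is an explicit error. Both the
inflection (`lt50`) and the temperature where the fitted curve crosses 50%
absolute leakage (`el50_abs`, the dashed line of leakage figures) are
reported, because published ± values rarely say which was used; they
coincide only when the asymptotes are symmetric about 50%. Fits are
unconstrained by default, with optional box constraints (e.g. asymptotes in
[0, 100]) since curve-fitting software defaults differ on this.

`compare_curves()` is the extra sum-of-squares F-test: one shared curve
(N − 4 df) against separate curves (N − 8 df),
$F = \frac{(RSS_{sh} - RSS_{sep})/4}{RSS_{sep}/(N-8)}$ on $F(4, N-8)$.
Starting values are cross-seeded between the shared and separate fits so
the nesting $RSS_{sh} \ge RSS_{sep}$ holds; under the null with Gaussian
noise the test is exact, and the suite checks the p-value distribution is
uniform. The default simulated assay uses temperatures −1..−10 °C in 1 °C
steps with 3 replicates and 5% noise; the hardware ramp the assay emulates
(−1 °C per 30 min from −2 °C) is configurable.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at the scale the
package's own defaults define: 200-gene genomes (10 seeds for recovery
rates), 2000-gene null count matrices (5 seeds), 200 decay and 200 LT50
recovery simulations, 500 null curve comparisons and 100 power
comparisons. Every `simulate_*` function is bit-reproducible given the
same seed, and all randomness flows through R's default generator.

## Limitations

* The generator's chromosome is sparser than a real plant genome
  (1.8–3 kb gaps), with no overlapping genes, no intergenic background
  transcription and no other antisense classes (promoter-divergent,
  internal); the PAS caller's near-perfect precision/recall on synthetic
  data shows the geometry and segmentation are implemented correctly, not
  that real plaNET-seq coverage would be this clean.
* Cold response is a single step (plus one reversion for transient genes);
  diurnal expression, isoforms and chromatin state are out of scope.
* The DE test is calibrated for the simulated regime; on real data use it
  knowing it lacks DESeq2's shrinkage machinery.
* One chromosome per simulation; multi-chromosome input works throughout
  the analysis side but the generator does not produce it.
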