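# chromdecay

Chromatin marks predict transcription; RNA decay decides what survives.
`chromdecay` is an R package and analysis workflow for quantifying how RNA
half-life explains the discrepancy between chromatin-mark-predicted
transcription (H3K4me3 / RNA polymerase II ChIP-seq) and measured RNA
abundance (RNA-seq), using genome-wide half-lives from BrU pulse-chase
(BRIC-seq) time courses. It is aimed at transcriptomics / regulatory
genomics analysts who have per-gene expression tables, peak calls and
coverage tracks, and pulse-chase time courses — or who want a fully
synthetic, ground-truthed stand-in for all of these.

## The model

Under first-order decay at steady state, abundance is synthesis over decay:

```
RPKM ∝ k_syn / λ = k_syn · t½ / ln 2,        λ = ln 2 / t½
```

so genes with strong promoter marks (high `k_syn` proxy) but low RPKM are
candidates for fast turnover. The package implements:

- **Half-life fitting** — reference-normalized log-linear OLS of each BrU
  chase course; `λ = −slope`, `t½ = ln 2 / λ`; exact on noise-free
  exponentials.
- **Quadrant classification** — ChIP(+) = H3K4me3 > 10⁴ tags *and* a pol II
  peak within TSS ± 1.5 kb; RNA(+) = RPKM > 10; short = t½ < 4 h; plus
  ×2 / ×1.1 bands around the log–log regression of expression on H3K4me3
  intensity, whose band median is the **default half-life** (≈ 10.9 h under
  the emulated conditions).
- **Counterfactual simulation** — `predicted = RPKM · t_default / t½`
  (and `RPKM_ctrl · t_kd / t_ctrl` for knockdowns), with band/rescue counts.
- **Histone-mark linear models** — log RPKM on studentized log marks
  (H3K4me3, H3K27Ac, H3K27me3, H3K36me3), with and without the log decay
  constant as an extra regressor.
- **Decay-factor target calling** — ≥ 2-fold (UPF1/EXOSC5) or ≥ 1.5-fold
  (STAU1) increases in *both* half-life and expression under knockdown.
- **Gene-set enrichment** — hypergeometric upper tail + Benjamini–Hochberg.
- **Enhancer-RNA regions** — merged H3K4me1 ∩ H3K27Ac peak intersections
  ≥ 1.5 kb from any gene body, quantified per kb per million, with
  half-life fitting and ≥ 2-fold stabilization calls.
- **A synthetic-data generator** — a gene universe with known synthesis
  rates, half-lives and knockdown effects that emits every input file the
  pipeline reads, so each stage is testable against ground truth.

## Worked example

The `analysis/` directory is a numbered workflow over a 2,000-gene
synthetic universe (seed 42). Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_halflife.R
Rscript analysis/03_classify.R
Rscript analysis/04_model.R
Rscript analysis/05_targets.R
Rscript analysis/06_erna.R
```

writes inputs to `results/demo_inputs/` and tables to `results/`, printing
among other things:

```
control  2000 valid /   0 invalid; median t1/2  9.42 h; median |rel err| vs truth 5.0%
...
ChIP+/RNA+ regression: slope 0.69, Pearson r 0.70 (n = 679)
default half-life (x1.1 band): 10.6 h
short (<4 h) half-lives in ChIP+/RNA-: 165 of 217 (universe 470 short of 2000), p = 3.3e-69
...
linear models of log RPKM (n = 2000 genes): marks-only r = 0.75, with decay term r = 0.97
...
UPF1     47 targets (designated:  50, recovered:  47); 19 in class (12%)
UPF1/EXOSC5 overlap: 5 of 47 and 47 (Jaccard 0.06)
```

Reading: half-lives are recovered from noisy 13-point chases with ~5%
median error; chromatin signal and expression correlate (r = 0.70) but a
quadrant of marked-yet-silent genes remains, and it is strongly enriched
for short-lived transcripts (p ≈ 10⁻⁶⁹); the regression-band median
recovers the generator's 10.9 h default half-life to within a few percent;
adding the decay constant lifts the expression model from r = 0.75 to
r = 0.97; and the fold-change rules recover 47 of 50 designated UPF1
targets with near-disjoint UPF1/EXOSC5 target sets.

The same machinery is available programmatically:

```r
library(chromdecay)
u   <- generate_universe(generator_config(n_genes = 2000, seed = 1))
tc  <- simulate_bric(u, seed = 2)                 # 13-point BrU chase
hl  <- fit_all(tc, "GAPDH_ref")                   # per-gene t½, λ, R²
rep <- run_pipeline(pipeline_config(seed = 1))    # full report as a list
```

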