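# nelfkit

Quantitative analysis of enhancer-RNA-driven NELF release and RNA
polymerase II promoter-proximal pausing.

## The problem

Metazoan Pol II frequently pauses 30–60 bp downstream of the promoter,
held there by the four-subunit negative elongation factor (NELF) together
with DSIF. Enhancer RNAs (eRNAs) — unstable, non-polyadenylated long
non-coding RNAs transcribed bidirectionally from active enhancers — can
detach NELF from this paused elongation complex (PEC), promoting the
transition into productive elongation. Characterising that mechanism
quantitatively involves several distinct measurements, each with its own
estimator:

* **EMSA release titrations** — the fraction of Pol II–DSIF complex
  appearing as increasing eRNA strips NELF off the PEC, fitted with a
  quadratic (ligand-depletion) single-site binding model for an apparent
  *K*<sub>d</sub>;
* **pausing indices** from strand-specific nascent-transcription
  coverage (promoter window −100..+200 bp vs gene-body window
  +400..+800 bp around the TSS), compared across conditions by the
  Kolmogorov–Smirnov test;
* **single-nucleotide eRNA TSS calling** from 5'-end sequencing
  pileups, with extragenic filtering, one-TSS-per-enhancer assignment
  and activity-induction classification;
* **eCLIP crosslink-site positional statistics** — 1-based distances
  of protein–RNA crosslink sites (the first nucleotide of the R2 read)
  from transcript 5' ends, window distributions (1–200, 201–400, …),
  expression-normalised meta-profiles, chi-squared comparisons;
* **SHAPE-MaP reactivities** from two-channel mutation counts, with
  box-plot/percentile normalisation and median-reactivity structure
  classes;
* **crosslinking-MS aggregation** — quality filtering of
  crosslink-search tables (matched ions ≥ 7, TIC ≥ 0.15, ID score ≥ 20)
  and per-residue summation of redundant spectral counts.

`nelfkit` implements all of these as composable R functions over
standard flat formats (BED6, bedGraph pairs, TSV tables), plus a
synthetic-data module that generates inputs with known ground truth for
every stage, so the entire pipeline is testable offline.

## The core model

With PEC at total concentration *R* (0.1 µM in the standard setup) and
eRNA at total concentration *L*, the released fraction follows the
ligand-depletion form of single-site binding:

```
f(L) = A · [ (R + L + Kd) − √((R + L + Kd)² − 4·R·L) ] / (2R)
```

`fit_binding()` estimates (*K*<sub>d</sub>, *A*) by bounded
Levenberg–Marquardt least squares with multistart initialisation, and
recovers *K*<sub>d</sub> from noiseless curves to better than 1% across
0.05–20 µM at the standard six-point titration (0.15–1.8 µM).

## Worked example

Simulate a noisy release titration at the standard series and fit it:

```r
library(nelfkit)

cfg   <- sim_config(seed = 7, kd_true = 0.14, noise_sd = 0.05)
curve <- simulate_binding_curve(cfg)   # 0.15 .. 1.8 uM, R = 0.1 uM
fit   <- fit_binding(curve)
fit
#> binding_fit: apparent Kd = 0.1224 uM (SE 0.0288), amplitude = 0.951, RSS = 0.00762
```

The fitted apparent *K*<sub>d</sub> of 0.122 µM sits within one standard
error of the generating 0.14 µM; the fitted amplitude of 0.95 reflects
the noisy plateau. The per-lane data and fitted curve:

```r
round(data.frame(eRNA_uM = curve$concentrations,
                 released = curve$fractions, fitted = fit$fitted), 3)
#>   eRNA_uM released fitted
#> 1    0.15    0.463  0.437
#> 2    0.30    0.589  0.624
#> 3    0.60    0.812  0.769
#> 4    0.90    0.768  0.826
#> 5    1.20    0.868  0.856
#> 6    1.80    0.905  0.887
```

Pausing indices from synthetic nascent coverage generated at PI = 5:

```r
sim <- simulate_nascent_coverage(
  sim_config(seed = 7, n_genes = 4, pausing_index_true = 5,
             reads_per_gene = 1e5, chrom_length = 2e5))
pis <- pausing_index_table(sim$tracks[["KCl_0"]], sim$units)
round(pis$pi, 2)
#> [1] 5.02 4.97 4.96 5.00
```

Each measured PI is the promoter/body density ratio of one gene; at
10⁵ reads per gene the sampling error is below 1%.

## Layout

| Path | Contents |
| --- | --- |
| `R/core-model.R` | coverage tracks, BED/bedGraph/site-table I/O, window densities |
| `R/synthetic-data.R` | ground-truth-emitting generators for every stage |
| `R/tss-assign.R` | TSS calling, extragenic filter, enhancer assignment, induction |
| `R/pausing.R` | pausing indices, NELF tiers, KS comparison |
| `R/eclip.R` | crosslink sites, distances, window distributions, chi-squared |
| `R/emsa.R` | release fractions, quadratic model, Kd fitting, time courses |
| `R/shape.R` | SHAPE reactivities, normalisation, classes, G-content bins |
| `R/xlms.R` | crosslink-search filtering and spectral-count aggregation |
| `vignettes/nelfkit-methods.Rmd` | models, assumptions, design choices, limitations |
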